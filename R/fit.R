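#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood fitting by iteratively reweighted least squares, with
#' the bookkeeping the audit pipeline needs: the per-iteration coefficient
#' trajectory (for divergence diagnostics), a [detect_separation()]-style
#' report, event/non-event counts and the events-per-variable ratio.
#' Convergence is declared when the relative change in deviance falls below
#' `tol`. On non-convergence the *last iterate* is returned with
#' `converged = FALSE` and a populated separation report — the failure mode
#' is data, not an exception.
#'
#' Fitted probabilities are clamped to `[1e-12, 1 - 1e-12]` so that
#' log-likelihoods stay finite even when separation drives the linear
#' predictor beyond floating-point range; the clamp is far inside the
#' `1e-8` extremeness threshold used by the separation diagnostics.
#'
#' @param table A [phenotype_table()] (or plain data.frame with the modeled
#'   columns). Rows with missing or non-finite modeled values are dropped
#'   (complete-case policy) and the count is reported.
#' @param spec An [lr_model_spec()].
#' @param tol Relative-deviance convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @param quiet Suppress the dropped-row message.
#'
#' @return An object of class `lr_fit` with elements `coefficients`,
#'   `standard_errors`, `vcov`, `loglik`, `deviance`, `aic`, `converged`,
#'   `n_iterations`, `fitted_probabilities`, `linear_predictors`,
#'   `separation`, `n_event`, `n_nonevent`, `epv`, `event_level`,
#'   `standardization` (centring/scaling constants, or `NULL`), `n_dropped`,
#'   plus the design matrix, response and coefficient trace used by the
#'   diagnostics.
#' @export
#' @examples
#' pop <- simulate_latent_axis(latent_sim_config(N = 200, seed = 1))
#' fit <- fit_logistic(pop, lr_model_spec(c("t1", "t2"), event_level = "B"))
#' coef(fit)
fit_logistic <- function(table, spec, tol = 1e-8, max_iter = 100L,
                         quiet = FALSE) {
  stopifnot(is.data.frame(table), inherits(spec, "lr_model_spec"))
  mf <- model_frame(table, spec, quiet = quiet)
  frame <- mf$frame
  event_level <- resolve_event_level(frame[[spec$outcome]], spec)
  y <- as.integer(as.character(frame[[spec$outcome]]) == event_level)

  standardization <- NULL
  if (spec$standardize && length(spec$predictors)) {
    frame <- standardize_predictors(frame, spec)
    standardization <- attr(frame, "standardization")
  }

  X <- build_design(frame, spec)
  if (nrow(X) <= ncol(X)) {
    stop("need more rows (", nrow(X), ") than coefficients (", ncol(X), ")",
         call. = FALSE)
  }
  xlev <- NULL
  if (length(spec$interactions)) {
    facs <- unique(vapply(spec$interactions, `[`, character(1), 1L))
    xlev <- lapply(frame[facs], function(v) levels(factor(v)))
    names(xlev) <- facs
  }

  res <- irls_logistic(X, y, tol = tol, max_iter = max_iter)
  k <- ncol(X) - 1L
  n_event <- sum(y == 1L)
  n_nonevent <- sum(y == 0L)

  fit <- structure(list(
    coefficients = res$beta,
    standard_errors = res$se,
    vcov = res$vcov,
    loglik = res$loglik,
    deviance = res$deviance,
    aic = -2 * res$loglik + 2 * ncol(X),
    converged = res$converged,
    n_iterations = res$n_iterations,
    fitted_probabilities = res$mu,
    linear_predictors = res$eta,
    n_event = n_event,
    n_nonevent = n_nonevent,
    epv = if (k > 0L) min(n_event, n_nonevent) / k else NA_real_,
    event_level = event_level,
    spec = spec,
    standardization = standardization,
    xlev = xlev,
    n_dropped = mf$n_dropped,
    y = y,
    X = X,
    coef_trace = res$coef_trace
  ), class = "lr_fit")
  fit$separation <- separation_heuristics(fit)
  fit
}

#' @export
coef.lr_fit <- function(object, ...) object$coefficients

#' @export
vcov.lr_fit <- function(object, ...) object$vcov

#' @export
logLik.lr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
print.lr_fit <- function(x, ...) {
  cat("Logistic regression fit (event: ", x$event_level, ")\n", sep = "")
  cat("  n = ", length(x$y), " (", x$n_event, " events / ", x$n_nonevent,
      " non-events); EPV = ",
      if (is.na(x$epv)) "NA" else format(round(x$epv, 2)), "\n", sep = "")
  cat("  deviance = ", format(x$deviance), "; converged = ", x$converged,
      " in ", x$n_iterations, " iteration(s)\n", sep = "")
  print(data.frame(estimate = x$coefficients, se = x$standard_errors))
  if (x$separation$flagged) {
    cat("  ! separation: ", x$separation$kind, " (extreme fraction ",
        format(round(x$separation$extreme_fraction, 3)), ")\n", sep = "")
  }
  invisible(x)
}

clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# IRLS on a numeric design matrix. Errors (classed "phaseaudit_singular") on
# an initially rank-deficient design, naming the later-listed aliased terms;
# a rank drop during iterations (weights collapsing under separation) ends
# the loop with converged = FALSE instead.
irls_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    cond <- structure(
      class = c("phaseaudit_singular", "error", "condition"),
      list(message = paste0("rank-deficient design; aliased term(s): ",
                            paste(aliased, collapse = ", ")),
           call = NULL, aliased = aliased))
    stop(cond)
  }

  beta <- numeric(p)
  names(beta) <- colnames(X)
  if (colnames(X)[1L] == "(Intercept)") {
    beta[1L] <- stats::qlogis((sum(y) + 0.5) / (n + 1))
  }
  coef_trace <- matrix(NA_real_, nrow = 0L, ncol = p,
                       dimnames = list(NULL, colnames(X)))
  dev_old <- Inf
  converged <- FALSE
  it <- 0L
  eta <- as.vector(X %*% beta)
  mu <- clamp_prob(stats::plogis(eta))

  while (it < max_iter) {
    it <- it + 1L
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    wls <- stats::lm.wfit(X, z, w)
    if (anyNA(wls$coefficients)) {
      # weighted design lost rank (typical under separation): stop iterating
      break
    }
    beta <- wls$coefficients
    eta <- as.vector(X %*% beta)
    mu <- clamp_prob(stats::plogis(eta))
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    coef_trace <- rbind(coef_trace, beta)
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))

  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X, X * w)
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(vc)) {
    vc <- matrix(NA_real_, p, p)
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))

  list(beta = beta, se = se, vcov = vc, loglik = -dev / 2, deviance = dev,
       converged = converged, n_iterations = it, mu = mu, eta = eta,
       coef_trace = coef_trace)
}

#' Predict event probabilities from a fitted model
#'
#' Applies the fitted linear predictor to new rows, after standardizing with
#' the constants retained at fit time (never recomputed on the new data).
#' For a separated fit the probabilities sit at the clamp boundary
#' `[1e-12, 1 - 1e-12]` and a warning is issued: such a model has no finite
#' maximum-likelihood estimate and its "perfect" probabilities are a symptom
#' of failure, not accuracy.
#'
#' @param fit An `lr_fit`.
#' @param table New data containing every predictor column (and interaction
#'   factor) of the fit.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @return Numeric vector, one value per row of `table`.
#' @export
predict_prob <- function(fit, table, type = c("response", "link")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "lr_fit"), is.data.frame(table))
  spec <- fit$spec
  needed <- setdiff(spec_columns(spec), spec$outcome)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("predictor column(s) missing from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  frame <- as.data.frame(table)[, needed, drop = FALSE]
  if (!is.null(fit$standardization)) {
    frame <- standardize_predictors(frame, spec,
                                    constants = fit$standardization)
  }
  X <- build_design(frame, spec, xlev = fit$xlev)
  bad <- setdiff(colnames(X), names(fit$coefficients))
  if (length(bad)) {
    stop("design columns not present at fit time: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  eta <- as.vector(X %*% fit$coefficients[colnames(X)])
  if (type == "link") return(eta)
  p <- clamp_prob(stats::plogis(eta))
  if (isTRUE(fit$separation$flagged)) {
    warning("fit is flagged for separation (", fit$separation$kind,
            "); probabilities at the machine boundary are clamped and do ",
            "not indicate genuine predictive accuracy", call. = FALSE)
  }
  p
}

#' Slope of the fitted latent axis in a trait plane
#'
#' A binary LR projects every phenotype onto a single latent axis via its
#' linear predictor. In the plane of two traits `i` and `j`, that axis has
#' slope over `i` equal to the coefficient ratio `beta_j / beta_i`; any line
#' orthogonal to it (the attached `iso_direction`) collects phenotypes with
#' identical estimated event probability.
#'
#' @param fit An `lr_fit`.
#' @param i,j Predictor names; the slope is taken over trait `i`.
#' @return The scalar slope, with attribute `iso_direction` (unit vector in
#'   the `(i, j)` plane along which the estimated probability is constant).
#' @export
latent_axis_slope <- function(fit, i, j) {
  stopifnot(inherits(fit, "lr_fit"))
  b <- fit$coefficients
  for (nm in c(i, j)) {
    if (!nm %in% names(b)) {
      stop("no coefficient estimated for '", nm, "'", call. = FALSE)
    }
  }
  if (b[[i]] == 0) {
    stop("coefficient of '", i, "' is zero: slope over it is undefined",
         call. = FALSE)
  }
  iso <- c(-b[[j]], b[[i]])
  iso <- iso / sqrt(sum(iso^2))
  names(iso) <- c(i, j)
  structure(b[[j]] / b[[i]], iso_direction = iso)
}
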