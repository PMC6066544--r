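#' Detect complete or quasi-separation in a logistic fit
#'
#' Separation — a linear combination of predictors that splits the two
#' outcome classes — means the maximum-likelihood estimate does not exist:
#' coefficients diverge, fitted probabilities pile up at 0 and 1, and the
#' "100% accurate" classification this produces is a symptom of a *failed*
#' fit, not of predictive power. Three criteria are combined:
#'
#' * the fraction of fitted probabilities within `epsilon` of 0 or 1;
#' * monotone growth of the coefficient norm over the final IRLS iterations
#'   (divergence);
#' * on small problems (`n <= n_max`, non-intercept coefficients `<= p_max`),
#'   an exact linear-programming feasibility check for a strictly separating
#'   hyperplane, which when run is authoritative for the `"complete"` call.
#'
#' Classification: `"complete"` when a strict separator exists (exact check)
#' or all rows are extreme with divergent coefficients (heuristic);
#' `"quasi"` when only some rows are extreme and the fit did not converge
#' cleanly; `"nonconvergence"` when IRLS failed without extreme
#' probabilities; `"none"` otherwise. A converged fit that the exact check
#' certifies non-separable is never flagged.
#'
#' @param fit An `lr_fit`.
#' @param table Unused (the design and response are carried by the fit);
#'   accepted for call-site symmetry with [fit_logistic()].
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact feasibility
#'   check; default `NULL` runs it within the size limits.
#' @param epsilon Distance from 0/1 within which a fitted probability counts
#'   as extreme.
#' @param n_max,p_max Size limits for the exact check.
#'
#' @return A `separation_report`: `flagged`, `kind`
#'   (`none|complete|quasi|nonconvergence`), `extreme_fraction`,
#'   `diverging_terms`, `exact_checked`, `separable` (logical or `NA`).
#' @export
#' @examples
#' d <- data.frame(environment = c("A", "A", "B", "B"), x = c(-2, -1, 1, 2))
#' pt <- phenotype_table(d, data.frame(trait = "x", domain = "behavioral",
#'                                     timescale = "fast"))
#' fit <- fit_logistic(pt, lr_model_spec("x", event_level = "B"))
#' detect_separation(fit)$kind
detect_separation <- function(fit, table = NULL, exact = NULL,
                              epsilon = 1e-8, n_max = 500L, p_max = 15L) {
  stopifnot(inherits(fit, "lr_fit"))
  rep0 <- separation_heuristics(fit, epsilon = epsilon)
  k <- ncol(fit$X) - 1L
  run_exact <- if (is.null(exact)) {
    nrow(fit$X) <= n_max && k <= p_max && k >= 1L
  } else {
    isTRUE(exact)
  }
  if (!run_exact) return(rep0)

  separable <- separating_hyperplane_feasible(fit$X, fit$y)
  kind <- if (separable) {
    "complete"
  } else if (fit$converged) {
    "none"
  } else if (rep0$extreme_fraction > 0) {
    "quasi"
  } else {
    "nonconvergence"
  }
  new_separation_report(kind, rep0$extreme_fraction, rep0$diverging_terms,
                        exact_checked = TRUE, separable = separable)
}

new_separation_report <- function(kind, extreme_fraction, diverging_terms,
                                  exact_checked = FALSE, separable = NA) {
  structure(list(flagged = kind != "none", kind = kind,
                 extreme_fraction = extreme_fraction,
                 diverging_terms = diverging_terms,
                 exact_checked = exact_checked, separable = separable),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("Separation report: ", if (x$flagged) "FLAGGED" else "not flagged",
      " (kind = ", x$kind, ")\n", sep = "")
  cat("  extreme fitted-probability fraction: ",
      format(round(x$extreme_fraction, 4)), "\n", sep = "")
  if (length(x$diverging_terms)) {
    cat("  diverging terms: ", paste(x$diverging_terms, collapse = ", "),
        "\n", sep = "")
  }
  if (x$exact_checked) {
    cat("  exact feasibility check: ",
        if (isTRUE(x$separable)) "a strictly separating hyperplane exists"
        else "no strictly separating hyperplane", "\n", sep = "")
  }
  invisible(x)
}

# Heuristic classification from the fit's stored trajectory; mirrors the two
# glm warnings ("algorithm did not converge" / "fitted probabilities
# numerically 0 or 1 occurred") that jointly signal complete separation.
separation_heuristics <- function(fit, epsilon = 1e-8) {
  mu <- fit$fitted_probabilities
  extreme_fraction <- mean(mu < epsilon | mu > 1 - epsilon)

  trace <- fit$coef_trace
  growing <- FALSE
  diverging_terms <- character(0)
  if (!is.null(trace) && nrow(trace) >= 3L) {
    m <- min(10L, nrow(trace) - 1L)
    tail_tr <- trace[seq.int(nrow(trace) - m, nrow(trace)), , drop = FALSE]
    norms <- apply(abs(tail_tr), 1L, max)
    growing <- all(diff(norms) > 0)
    per_term_grow <- apply(abs(tail_tr), 2L, function(v) all(diff(v) > 0))
    final <- abs(trace[nrow(trace), ])
    diverging_terms <- colnames(trace)[per_term_grow & final > 5]
  }

  kind <- if (extreme_fraction == 1 && growing) {
    "complete"
  } else if (extreme_fraction > 0 && (!fit$converged || growing)) {
    "quasi"
  } else if (!fit$converged) {
    "nonconvergence"
  } else {
    "none"
  }
  new_separation_report(kind, extreme_fraction, diverging_terms)
}

# Exact feasibility of a strictly separating hyperplane, as the linear
# program: minimize sum(e) subject to s_i * x_i' w + e_i >= 1, e >= 0
# (s_i = +1 events, -1 non-events). Any strict separator can be rescaled to
# margin 1, so the data are strictly separable iff the optimum is 0. The
# free coefficients w are split into positive/negative parts; non-intercept
# columns are rescaled to unit max-abs first (separability is scale
# invariant). Starting from w = 0, e = 1 the slack columns form a feasible
# identity basis, so no phase-1 is needed.
separating_hyperplane_feasible <- function(X, y, tol = 1e-7) {
  s <- ifelse(y == 1, 1, -1)
  Xs <- X
  for (jc in seq_len(ncol(Xs))) {
    mx <- max(abs(Xs[, jc]))
    if (mx > 0) Xs[, jc] <- Xs[, jc] / mx
  }
  A <- Xs * s
  n <- nrow(A)
  p <- ncol(A)
  # standard form: [A, -A, I, -I] x = 1 over x = (u, v, e, r) >= 0
  Astd <- cbind(A, -A, diag(n), -diag(n))
  cvec <- c(rep(0, 2L * p), rep(1, n), rep(0, n))
  basis0 <- 2L * p + seq_len(n)
  opt <- simplex_bland(Astd, rep(1, n), cvec, basis0)
  if (opt$status != "optimal") {
    stop("separating-hyperplane LP did not solve (status: ", opt$status,
         ")", call. = FALSE)
  }
  opt$value < tol * n
}

# Dense tableau simplex with Bland's anti-cycling rule for
#   minimize c'x  s.t.  A x = b (b >= 0), x >= 0,
# given an initial basis whose columns of A form the identity.
# Deterministic and exact to tolerance on the small instances the
# separation check is limited to.
simplex_bland <- function(A, b, cvec, basis, tol = 1e-9,
                          max_iter = 20000L) {
  m <- nrow(A)
  Tb <- cbind(A, b)
  cost <- c(cvec, 0)
  for (ir in seq_len(m)) {
    cb <- cost[basis[ir]]
    if (cb != 0) cost <- cost - cb * Tb[ir, ]
  }
  for (it in seq_len(max_iter)) {
    enter <- which(cost[-length(cost)] < -tol)
    if (!length(enter)) {
      x <- numeric(ncol(A))
      x[basis] <- Tb[, ncol(Tb)]
      return(list(status = "optimal", value = sum(cvec * x), x = x))
    }
    j <- enter[1L]                         # Bland: smallest entering index
    col <- Tb[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", value = -Inf))
    ratios <- Tb[pos, ncol(Tb)] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    ir <- cand[which.min(basis[cand])]     # Bland: smallest leaving label
    piv <- Tb[ir, j]
    Tb[ir, ] <- Tb[ir, ] / piv
    upd <- Tb[, j]
    upd[ir] <- 0
    Tb <- Tb - outer(upd, Tb[ir, ])
    cost <- cost - cost[j] * Tb[ir, ]
    basis[ir] <- j
  }
  list(status = "iteration_limit", value = NA_real_)
}
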