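#' Somers' Dxy rank discrimination
#'
#' Over all event/non-event pairs, `Dxy = (C - D) / (C + D + T)` with C
#' concordant, D discordant and T tied-prediction pairs; equivalently
#' `2 * (c-index - 0.5)`. 0 means no predictive power, 1 perfect rank
#' discrimination, -1 perfect reversal. Computed from midranks, so ties are
#' handled exactly and the cost is O(n log n) rather than all-pairs.
#'
#' @param predictions Numeric scores (probabilities or any monotone
#'   transform of them; Dxy is invariant under strictly increasing
#'   transforms).
#' @param outcomes Binary outcomes: 0/1 numeric or logical, with both
#'   classes present.
#' @return Dxy in `[-1, 1]`.
#' @export
#' @examples
#' somers_dxy(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))  # (3 - 1) / 4 = 0.5
somers_dxy <- function(predictions, outcomes) {
  y <- as_binary_outcome(outcomes)
  stopifnot(length(predictions) == length(y), is.numeric(predictions))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(predictions)
  # 2*S is integer-valued even with midranks, so the numerator below equals
  # the exact pair count C - D and the single division matches brute-force
  # enumeration bit for bit
  num <- 2 * sum(r[y == 1L]) - n1 * (n1 + 1) - n1 * n0
  num / (n1 * n0)
}

as_binary_outcome <- function(outcomes) {
  if (is.logical(outcomes)) return(as.integer(outcomes))
  if (is.numeric(outcomes) && all(outcomes %in% c(0, 1))) {
    return(as.integer(outcomes))
  }
  stop("outcomes must be binary (0/1 or logical)", call. = FALSE)
}

#' Logistic calibration line of a linear predictor
#'
#' Refits the outcome on the supplied linear predictor,
#' `logit(P(y = 1)) = a + b * lp`, and returns the recalibration intercept
#' `a` and slope `b`. For a model evaluated on its own training data these
#' are 0 and 1 by construction; on new (or bootstrap-original) data a slope
#' below 1 is the signature of overfitting — the model's predictions are too
#' extreme and must be shrunk toward the mean to be honest.
#'
#' @param linear_predictor Finite numeric vector (log-odds scale).
#' @param outcomes Binary outcomes, both classes present.
#' @return Named numeric vector `c(intercept, slope)`.
#' @export
calibration_line <- function(linear_predictor, outcomes) {
  y <- as_binary_outcome(outcomes)
  stopifnot(length(linear_predictor) == length(y))
  if (!all(is.finite(linear_predictor))) {
    stop("linear predictor must be finite", call. = FALSE)
  }
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (stats::sd(linear_predictor) == 0) {
    stop("constant linear predictor: calibration slope undefined",
         call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1, lp = linear_predictor)
  res <- irls_logistic(X, y)
  if (!res$converged) {
    stop("calibration refit did not converge", call. = FALSE)
  }
  c(intercept = unname(res$beta[1L]), slope = unname(res$beta[2L]))
}

#' Bootstrap optimism-corrected validation of a logistic model
#'
#' Internal validation by the optimism bootstrap: the whole modeling
#' procedure (complete-case filtering, standardization, IRLS fit) is
#' repeated on `B` unstratified resamples of the rows; each replicate model
#' is evaluated both on its own resample ("training") and on the original
#' table ("test"). The optimism of Somers' Dxy is the average training-minus-
#' test difference over successful replicates, and the corrected Dxy is the
#' apparent value minus that optimism. The apparent calibration line is
#' (0, 1) by construction, so the corrected calibration intercept and slope
#' are the means of the original-table recalibration coefficients across
#' replicates (identical to apparent-minus-optimism).
#'
#' Replicates whose refit is singular, fails to converge, or is flagged for
#' separation are excluded and tallied rather than hidden: with few events
#' per variable, the failure rate is itself diagnostic of an overstretched
#' model.
#'
#' @param table A [phenotype_table()] (or data.frame).
#' @param spec An [lr_model_spec()].
#' @param B Number of bootstrap replicates (values below 50 warn).
#' @param seed Integer seed governing the whole resampling stream;
#'   replicate b uses the b-th consecutive draw from `set.seed(seed)`.
#' @return A `validation_result` with apparent and corrected Dxy and
#'   calibration intercept/slope, replicate accounting (`B_requested`,
#'   `B_failed`, `failure_reasons`) and the seed.
#' @export
bootstrap_validate <- function(table, spec, B = 1000L, seed = 1L) {
  stopifnot(is.data.frame(table), inherits(spec, "lr_model_spec"))
  B <- as.integer(B)
  if (B < 1L) stop("B must be positive", call. = FALSE)
  if (B < 50L) warning("B < 50 gives unstable optimism estimates",
                       call. = FALSE)

  fit0 <- suppressWarnings(fit_logistic(table, spec, quiet = TRUE))
  spec$event_level <- fit0$event_level
  mf0 <- model_frame(table, spec, quiet = TRUE)
  frame0 <- mf0$frame
  y0 <- fit0$y
  dxy_app <- somers_dxy(fit0$fitted_probabilities, y0)

  n <- nrow(frame0)
  optimism <- numeric(0)
  cal_int <- numeric(0)
  cal_slope <- numeric(0)
  reasons <- c(nonconvergence = 0L, separation = 0L, singular = 0L,
               degenerate = 0L, other = 0L)

  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      suppressWarnings(
        fit_logistic(frame0[idx, , drop = FALSE], spec, quiet = TRUE)),
      phaseaudit_singular = function(e) "singular",
      error = function(e) "other")
    if (is.character(fb)) {
      reasons[[fb]] <- reasons[[fb]] + 1L
      next
    }
    if (!fb$converged) {
      reasons[["nonconvergence"]] <- reasons[["nonconvergence"]] + 1L
      next
    }
    if (fb$separation$flagged) {
      reasons[["separation"]] <- reasons[["separation"]] + 1L
      next
    }
    dxy_train <- somers_dxy(fb$fitted_probabilities, fb$y)
    lp_test <- suppressWarnings(predict_prob(fb, frame0, type = "link"))
    cal <- tryCatch(calibration_line(lp_test, y0),
                    error = function(e) NULL)
    if (is.null(cal)) {
      reasons[["degenerate"]] <- reasons[["degenerate"]] + 1L
      next
    }
    dxy_test <- somers_dxy(lp_test, y0)
    optimism <- c(optimism, dxy_train - dxy_test)
    cal_int <- c(cal_int, cal[["intercept"]])
    cal_slope <- c(cal_slope, cal[["slope"]])
  }

  B_failed <- B - length(optimism)
  if (length(optimism) == 0L) {
    stop("all ", B, " bootstrap replicates failed (",
         paste(sprintf("%s: %d", names(reasons), reasons), collapse = ", "),
         ")", call. = FALSE)
  }

  structure(list(
    dxy_apparent = dxy_app,
    dxy_corrected = max(-1, min(1, dxy_app - mean(optimism))),
    cal_intercept_apparent = 0,
    cal_intercept_corrected = mean(cal_int),
    cal_slope_apparent = 1,
    cal_slope_corrected = mean(cal_slope),
    mean_optimism = mean(optimism),
    B_requested = B,
    B_failed = B_failed,
    failure_reasons = as.list(reasons),
    seed = seed
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Bootstrap internal validation (B = ", x$B_requested, ", seed = ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  Somers' Dxy:          apparent %6.3f  corrected %6.3f\n",
              x$dxy_apparent, x$dxy_corrected))
  cat(sprintf("  calibration intercept: apparent %5.2f   corrected %6.3f\n",
              x$cal_intercept_apparent, x$cal_intercept_corrected))
  cat(sprintf("  calibration slope:     apparent %5.2f   corrected %6.3f\n",
              x$cal_slope_apparent, x$cal_slope_corrected))
  cat(sprintf("  failed replicates: %d of %d (%.1f%%)\n", x$B_failed,
              x$B_requested, 100 * x$B_failed / x$B_requested))
  fr <- unlist(x$failure_reasons)
  fr <- fr[fr > 0]
  if (length(fr)) {
    cat("    ", paste(sprintf("%s: %d", names(fr), fr), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
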