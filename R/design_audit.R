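#' Events-per-variable design audit
#'
#' How many predictors a binary LR model can support is limited by the
#' smaller outcome group (the "limiting sample size"). Its ratio to the
#' number of non-intercept coefficients is the events-per-variable (EPV)
#' ratio; 10-20 EPV is the commonly cited minimum, and below 2 EPV a model
#' is unreliable almost by construction — apparent performance will not
#' replicate, and complete separation becomes likely.
#'
#' @param n_event,n_nonevent Outcome group sizes (both positive).
#' @param k Number of non-intercept coefficients (positive).
#' @param epv_floor Minimum EPV below which the verdict is `"warn"`
#'   (default 10); below 2 the verdict is always `"fail"`.
#' @return A `design_audit` with `n_event`, `n_nonevent`, `limiting_n`, `k`,
#'   `epv`, `epv_floor` and `verdict` (`"pass"`, `"warn"` or `"fail"`).
#' @export
#' @examples
#' events_per_variable(15, 51, 13)$verdict  # "fail": EPV just over 1
#' events_per_variable(15, 51, 5)$verdict   # "warn": 3 EPV
events_per_variable <- function(n_event, n_nonevent, k, epv_floor = 10) {
  if (k <= 0L) stop("k must be a positive coefficient count", call. = FALSE)
  if (n_event <= 0L || n_nonevent <= 0L) {
    stop("both outcome groups must be non-empty", call. = FALSE)
  }
  limiting_n <- min(n_event, n_nonevent)
  epv <- limiting_n / k
  verdict <- if (epv < 2) "fail" else if (epv < epv_floor) "warn" else "pass"
  structure(list(n_event = n_event, n_nonevent = n_nonevent,
                 limiting_n = limiting_n, k = k, epv = epv,
                 epv_floor = epv_floor, verdict = verdict),
            class = "design_audit")
}

#' @export
print.design_audit <- function(x, ...) {
  cat(sprintf(
    "Design audit: limiting n = %d, k = %d -> EPV = %.2f [%s]\n",
    x$limiting_n, x$k, x$epv, toupper(x$verdict)))
  invisible(x)
}

#' Rule-of-thumb minimum sample size per phase
#'
#' For a k-predictor model a single-strain fit estimates k + 1 coefficients
#' (incl. intercept), needing about `epv_floor * (k + 1)` individuals of
#' each phase; a model crossed with a two-level strain factor estimates
#' 2k + 2 coefficients, needing about `epv_floor * (2k + 2)` of each phase,
#' balanced across strains — exactly twice the single-strain requirement.
#' The default floor of 15 sits in the middle of the conventional 10-20 EPV
#' band.
#'
#' @param k Number of predictors (`>= 1`).
#' @param with_strain_interactions Include a two-level strain factor crossed
#'   with every predictor?
#' @param epv_floor Events-per-coefficient floor used by the rule of thumb.
#' @return Required count of individuals of *each* phase.
#' @export
#' @examples
#' min_sample_size(13)                                  # 210 per phase
#' min_sample_size(13, with_strain_interactions = TRUE) # 420 per phase
min_sample_size <- function(k, with_strain_interactions = FALSE,
                            epv_floor = 15) {
  stopifnot(k >= 1)
  n_coef <- if (with_strain_interactions) 2 * k + 2 else k + 1
  epv_floor * n_coef
}

#' Compare a strain-crossed model against a pooled model
#'
#' Whether one fitted model can be reused across laboratory strains is an
#' empirical question needing data from both strains. Model 1 crosses every
#' predictor with the strain factor (main effect plus all interactions);
#' Model 2 omits strain entirely. The models are compared by AIC and by the
#' likelihood-ratio test on `(L - 1) * (k + 1)` degrees of freedom (k + 1
#' for two strains). Pooling is recommended only when AIC favors Model 2 or
#' the LRT is decisively non-significant (default `p > 0.15`), and only from
#' an adequately powered design: when the EPV audit of Model 1 fails, the
#' verdict is `"underpowered"` — an underpowered non-significant test is not
#' evidence that strains can be pooled.
#'
#' @param table A [phenotype_table()] with the strain factor column.
#' @param spec An [lr_model_spec()]; its predictors define both models.
#' @param factor Name of the strain (or other grouping) column; every level
#'   must contain both phases.
#' @param pooling_p LRT p-value above which pooling is considered supported.
#' @return A `model_comparison` with `loglik_1`, `loglik_2`, `aic_1`,
#'   `aic_2`, `lrt_statistic`, `lrt_df`, `lrt_p`, `recommendation`
#'   (`pooled-model`, `strain-specific` or `underpowered`) and both fits.
#' @export
strain_generalization_compare <- function(table, spec, factor = "strain",
                                          pooling_p = 0.15) {
  stopifnot(is.data.frame(table), inherits(spec, "lr_model_spec"))
  if (!factor %in% names(table)) {
    stop("factor column '", factor, "' not found", call. = FALSE)
  }
  lev <- unique(as.character(table[[factor]]))
  if (length(lev) < 2L) {
    stop("factor '", factor, "' needs at least 2 levels", call. = FALSE)
  }
  tab <- table(table[[factor]], table[[spec$outcome]])
  if (any(tab == 0L)) {
    stop("empty phase-by-", factor, " cell: both phases must be observed ",
         "in every level", call. = FALSE)
  }

  spec2 <- spec
  spec2$interactions <- NULL
  spec1 <- spec
  spec1$interactions <- lapply(spec$predictors, function(p) c(factor, p))

  fit2 <- fit_logistic(table, spec2, quiet = TRUE)
  spec1$event_level <- fit2$event_level
  fit1 <- fit_logistic(table, spec1, quiet = TRUE)
  for (f in list(fit1, fit2)) {
    if (f$separation$flagged) {
      cond <- structure(
        class = c("phaseaudit_separation", "error", "condition"),
        list(message = paste0("model comparison aborted: separation (",
                              f$separation$kind, ") in ",
                              if (length(f$spec$interactions)) "Model 1"
                              else "Model 2"),
             call = NULL, separation = f$separation))
      stop(cond)
    }
  }

  p1 <- length(fit1$coefficients)
  p2 <- length(fit2$coefficients)
  lrt <- 2 * (fit1$loglik - fit2$loglik)
  lrt_df <- p1 - p2
  lrt_p <- stats::pchisq(lrt, lrt_df, lower.tail = FALSE)

  audit1 <- events_per_variable(fit1$n_event, fit1$n_nonevent, p1 - 1L)
  recommendation <- if (audit1$verdict == "fail") {
    "underpowered"
  } else if (fit2$aic < fit1$aic || lrt_p > pooling_p) {
    "pooled-model"
  } else {
    "strain-specific"
  }

  structure(list(loglik_1 = fit1$loglik, loglik_2 = fit2$loglik,
                 aic_1 = fit1$aic, aic_2 = fit2$aic,
                 lrt_statistic = lrt, lrt_df = lrt_df, lrt_p = lrt_p,
                 recommendation = recommendation,
                 design_audit_model1 = audit1,
                 pooling_p = pooling_p,
                 fit_crossed = fit1, fit_pooled = fit2),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Strain-generalization model comparison\n")
  cat(sprintf("  Model 1 (crossed): logLik = %.3f, AIC = %.2f\n",
              x$loglik_1, x$aic_1))
  cat(sprintf("  Model 2 (pooled):  logLik = %.3f, AIC = %.2f\n",
              x$loglik_2, x$aic_2))
  cat(sprintf("  LRT: chi-square = %.3f on %d df, p = %.4g\n",
              x$lrt_statistic, x$lrt_df, x$lrt_p))
  cat("  recommendation: ", x$recommendation, "\n", sep = "")
  invisible(x)
}
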