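#' Stable warning codes used in audit reports
#'
#' Downstream code and tests should match on these codes, not on prose.
#'
#' @return A data.frame with columns `code` and `message`.
#' @export
warning_catalogue <- function() {
  data.frame(
    code = c("W_SEPARATION", "W_QUASI_SEPARATION", "W_NONCONVERGENCE",
             "W_EPV_FAIL", "W_EPV_WARN", "W_HYBRID_DOMAIN",
             "W_NOT_NONMORPHOMETRIC", "W_COLLINEAR", "W_SIGN_REDUNDANT",
             "W_SIGN_INCONSISTENT", "W_VALIDATION_SKIPPED",
             "W_EVENT_LEVEL_DEFAULTED", "W_ROWS_DROPPED"),
    message = c(
      "Complete separation: the maximum-likelihood fit does not exist; apparent 100% accuracy is a symptom of estimation failure, not predictive power.",
      "Quasi-separation: some fitted probabilities are numerically 0 or 1; estimates are unreliable.",
      "IRLS did not converge; the last iterate is reported.",
      "Events per variable below 2: the model is unreliable by construction at this sample size.",
      "Events per variable below the configured floor: expect substantial overfitting.",
      "Model mixes fast-responding behavioral traits with slow morphometric or hybrid traits; its prediction is uninterpretable for individuals in transition between phases.",
      "Model was requested as non-morphometric but contains morphometric or size-normalized (hybrid) predictors; the label is refused.",
      "Predictor pair(s) at or above the collinearity threshold; standard errors and individual coefficients are unstable.",
      "A predictor is a deterministic function of the sign of another and is redundant.",
      "A flagged collinear pair has opposite-signed coefficients; the estimates likely cancel and are not individually interpretable.",
      "Bootstrap validation skipped because the base fit is separated.",
      "Event level defaulted to the alphabetically last outcome level.",
      "Rows with missing or non-finite modeled values were dropped (complete-case policy)."),
    stringsAsFactors = FALSE)
}

catalogue_message <- function(code) {
  cat_df <- warning_catalogue()
  cat_df$message[match(code, cat_df$code)]
}

#' Configuration for [audit_model()]
#'
#' @param collinearity_threshold Correlation magnitude that flags a pair.
#' @param epv_floor EPV below which the design verdict is `"warn"`.
#' @param bootstrap_B Bootstrap replicates for internal validation.
#' @param seed Integer seed for the bootstrap.
#' @param claim Optional label claimed for the model (e.g.
#'   `"non-morphometric"`); the audit refuses claims the trait domains
#'   contradict.
#' @param run_validation Run bootstrap validation (skipped automatically
#'   when the base fit is separated).
#' @return A list of class `audit_config`.
#' @export
audit_config <- function(collinearity_threshold = 0.99, epv_floor = 10,
                         bootstrap_B = 200L, seed = 1L, claim = NULL,
                         run_validation = TRUE) {
  stopifnot(collinearity_threshold > 0, collinearity_threshold <= 1,
            epv_floor > 0, bootstrap_B >= 1)
  structure(list(collinearity_threshold = collinearity_threshold,
                 epv_floor = epv_floor, bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), claim = claim,
                 run_validation = isTRUE(run_validation)),
            class = "audit_config")
}

#' Audit one logistic model on one dataset
#'
#' Runs, in order: trait-domain census, standardization, collinearity and
#' sign-redundancy screening, the events-per-variable design audit, the IRLS
#' fit, separation detection, a coefficient-sign consistency report, and
#' bootstrap internal validation. Every finding is attached as a stable
#' warning code (see [warning_catalogue()]). A separated fit is *never*
#' reported as accurate: validation is skipped and the report carries the
#' separation warning instead. Deterministic given `(table, spec, config)`.
#'
#' If a stage fails fatally, the partial report carries the
#' `completed_stages` manifest and the error message.
#'
#' @param table A [phenotype_table()].
#' @param spec An [lr_model_spec()].
#' @param config An [audit_config()].
#' @return An `audit_report`.
#' @export
audit_model <- function(table, spec, config = audit_config()) {
  stopifnot(inherits(table, "phenotype_table"),
            inherits(spec, "lr_model_spec"),
            inherits(config, "audit_config"))
  validate_phenotype_table(table)

  warnings <- data.frame(code = character(0), detail = character(0),
                         stringsAsFactors = FALSE)
  add_warning <- function(code, detail = "") {
    warnings <<- rbind(warnings,
                       data.frame(code = code, detail = detail,
                                  stringsAsFactors = FALSE))
  }
  completed <- character(0)
  report <- list()

  # -- trait-domain census ---------------------------------------------------
  meta <- trait_meta(table)
  doms <- meta$domain[match(spec$predictors, meta$trait)]
  names(doms) <- spec$predictors
  census <- list(behavioral = sum(doms == "behavioral", na.rm = TRUE),
                 morphometric = sum(doms == "morphometric", na.rm = TRUE),
                 hybrid = sum(doms == "hybrid", na.rm = TRUE))
  if (census$behavioral > 0 && (census$morphometric + census$hybrid) > 0) {
    add_warning("W_HYBRID_DOMAIN",
                paste("slow/size-linked predictors:",
                      paste(names(doms)[doms != "behavioral"],
                            collapse = ", ")))
  }
  if (!is.null(config$claim) && config$claim == "non-morphometric" &&
      (census$morphometric + census$hybrid) > 0) {
    add_warning("W_NOT_NONMORPHOMETRIC",
                paste("offending predictors:",
                      paste(names(doms)[doms != "behavioral"],
                            collapse = ", ")))
  }
  report$domain_census <- census
  completed <- c(completed, "domain_census")

  # -- standardization -------------------------------------------------------
  report$standardized <- spec$standardize
  completed <- c(completed, "standardization")

  # -- collinearity / redundancy screen -------------------------------------
  screen <- NULL
  if (length(spec$predictors) >= 2L) {
    screen <- collinearity_screen(table, spec,
                                  threshold = config$collinearity_threshold)
    if (nrow(screen$flagged_pairs)) {
      add_warning("W_COLLINEAR",
                  paste(sprintf("%s ~ %s (r = %.4f)",
                                screen$flagged_pairs$a,
                                screen$flagged_pairs$b,
                                screen$flagged_pairs$r), collapse = "; "))
    }
    if (nrow(screen$sign_redundant)) {
      add_warning("W_SIGN_REDUNDANT",
                  paste(sprintf("%s encodes sign(%s)",
                                screen$sign_redundant$derived,
                                screen$sign_redundant$base), collapse = "; "))
    }
  }
  report$collinearity <- screen
  completed <- c(completed, "collinearity_screen")

  # -- fit (the design audit needs the realized coefficient count) ----------
  if (is.null(spec$event_level)) add_warning("W_EVENT_LEVEL_DEFAULTED")
  fit <- tryCatch(suppressWarnings(fit_logistic(table, spec, quiet = TRUE)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    report$fit_error <- conditionMessage(fit)
    return(finish_audit(report, warnings, completed, config, partial = TRUE))
  }
  if (fit$n_dropped > 0L) {
    add_warning("W_ROWS_DROPPED", paste(fit$n_dropped, "row(s)"))
  }

  # -- design audit ----------------------------------------------------------
  k <- length(fit$coefficients) - 1L
  design <- if (k > 0L) {
    events_per_variable(fit$n_event, fit$n_nonevent, k,
                        epv_floor = config$epv_floor)
  }
  if (!is.null(design)) {
    if (design$verdict == "fail") {
      add_warning("W_EPV_FAIL", sprintf("EPV = %.2f", design$epv))
    } else if (design$verdict == "warn") {
      add_warning("W_EPV_WARN", sprintf("EPV = %.2f", design$epv))
    }
  }
  report$design <- design
  completed <- c(completed, "design_audit")

  report$fit <- list(coefficients = fit$coefficients,
                     standard_errors = fit$standard_errors,
                     loglik = fit$loglik, deviance = fit$deviance,
                     aic = fit$aic, converged = fit$converged,
                     n_iterations = fit$n_iterations,
                     n_event = fit$n_event, n_nonevent = fit$n_nonevent,
                     epv = fit$epv, event_level = fit$event_level)
  completed <- c(completed, "fit")

  # -- separation ------------------------------------------------------------
  sep <- detect_separation(fit)
  if (sep$kind == "complete") {
    add_warning("W_SEPARATION",
                sprintf("extreme fraction %.3f", sep$extreme_fraction))
  } else if (sep$kind == "quasi") {
    add_warning("W_QUASI_SEPARATION",
                sprintf("extreme fraction %.3f", sep$extreme_fraction))
  } else if (sep$kind == "nonconvergence") {
    add_warning("W_NONCONVERGENCE")
  }
  report$separation <- sep
  completed <- c(completed, "separation")

  # -- coefficient signs -----------------------------------------------------
  signs <- data.frame(term = names(fit$coefficients),
                      estimate = unname(fit$coefficients),
                      sign = sign(unname(fit$coefficients)),
                      stringsAsFactors = FALSE)
  if (!is.null(screen) && nrow(screen$flagged_pairs)) {
    for (ii in seq_len(nrow(screen$flagged_pairs))) {
      a <- screen$flagged_pairs$a[ii]
      b <- screen$flagged_pairs$b[ii]
      if (all(c(a, b) %in% names(fit$coefficients)) &&
          screen$flagged_pairs$r[ii] > 0 &&
          sign(fit$coefficients[[a]]) * sign(fit$coefficients[[b]]) < 0) {
        add_warning("W_SIGN_INCONSISTENT", paste(a, "vs", b))
      }
    }
  }
  report$signs <- signs
  completed <- c(completed, "sign_report")

  # -- bootstrap validation --------------------------------------------------
  report$validation <- NULL
  if (config$run_validation) {
    if (sep$flagged) {
      add_warning("W_VALIDATION_SKIPPED",
                  paste("separation kind:", sep$kind))
    } else {
      spec_resolved <- spec
      spec_resolved$event_level <- fit$event_level
      report$validation <- suppressWarnings(
        bootstrap_validate(table, spec_resolved,
                           B = config$bootstrap_B, seed = config$seed))
    }
  }
  completed <- c(completed, "validation")

  finish_audit(report, warnings, completed, config, partial = FALSE)
}

finish_audit <- function(report, warnings, completed, config, partial) {
  report$warnings <- warnings
  report$completed_stages <- completed
  report$partial <- partial
  report$config <- unclass(config)
  structure(report, class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Model audit report", if (x$partial) " (PARTIAL)", "\n", sep = "")
  cat("  completed stages: ", paste(x$completed_stages, collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$fit)) {
    cat(sprintf("  fit: %d coefficients, EPV = %s, converged = %s\n",
                length(x$fit$coefficients),
                if (is.na(x$fit$epv)) "NA" else sprintf("%.2f", x$fit$epv),
                x$fit$converged))
  }
  if (!is.null(x$fit_error)) cat("  fit error: ", x$fit_error, "\n", sep = "")
  if (nrow(x$warnings)) {
    cat("  warnings:\n")
    for (ii in seq_len(nrow(x$warnings))) {
      cat("    [", x$warnings$code[ii], "] ",
          catalogue_message(x$warnings$code[ii]),
          if (nzchar(x$warnings$detail[ii]))
            paste0(" (", x$warnings$detail[ii], ")"),
          "\n", sep = "")
    }
  } else {
    cat("  no warnings\n")
  }
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}
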