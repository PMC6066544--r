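#' Mean-centre and scale model predictors
#'
#' Centres each predictor named in the model spec to sample mean 0 and scales
#' it to sample standard deviation 1 (n - 1 denominator). The centring and
#' scaling constants are retained as an attribute so coefficients fitted on
#' the standardized scale can be mapped back to the raw scale, and so new
#' data can be standardized with the *training* constants at prediction time.
#'
#' Standardization is what makes standard errors comparable across predictors
#' whose raw scales differ by orders of magnitude; conspicuously large SEs on
#' the unit scale are a collinearity red flag that raw-scale fits can hide.
#'
#' @param table A [phenotype_table()].
#' @param spec An [lr_model_spec()]; its `predictors` are standardized.
#' @param constants Optional list with `center` and `scale` named vectors, to
#'   apply previously computed constants instead of recomputing them.
#'
#' @return The table with standardized predictor columns; the constants are
#'   attached as attribute `"standardization"`.
#' @export
#' @examples
#' d <- data.frame(environment = c("A", "A", "B"), t1 = c(1, 2, 3))
#' pt <- phenotype_table(d, data.frame(trait = "t1", domain = "behavioral",
#'                                     timescale = "fast"))
#' standardize_predictors(pt, lr_model_spec("t1"))$t1
standardize_predictors <- function(table, spec, constants = NULL) {
  stopifnot(is.data.frame(table))
  preds <- spec$predictors
  missing_cols <- setdiff(preds, names(table))
  if (length(missing_cols)) {
    stop("predictor columns missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(constants)) {
    center <- vapply(preds, function(p) mean(table[[p]], na.rm = TRUE),
                     numeric(1))
    scale <- vapply(preds, function(p) stats::sd(table[[p]], na.rm = TRUE),
                    numeric(1))
    zero <- preds[!is.na(scale) & scale == 0]
    if (length(zero)) {
      stop("zero-variance predictor(s): ", paste(zero, collapse = ", "),
           call. = FALSE)
    }
  } else {
    center <- constants$center[preds]
    scale <- constants$scale[preds]
    if (anyNA(center) || anyNA(scale)) {
      stop("standardization constants missing for some predictors",
           call. = FALSE)
    }
  }
  for (p in preds) table[[p]] <- (table[[p]] - center[[p]]) / scale[[p]]
  attr(table, "standardization") <- list(center = center, scale = scale)
  table
}
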