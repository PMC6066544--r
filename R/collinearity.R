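#' Screen model predictors for collinearity and sign redundancy
#'
#' Computes all pairwise Pearson correlations among the spec's predictors and
#' flags pairs at or above the threshold magnitude. Near-perfect collinearity
#' (e.g. r = 0.9998 between two speed measures) inflates standard errors and
#' can produce coefficient pairs of opposite sign that cancel — individually
#' "wrong-signed" estimates that are artifacts of estimation, not biology.
#' The screen additionally flags predictors that are a deterministic function
#' of the *sign* of another predictor (a binary side-of-arena indicator that
#' merely encodes the sign of a coordinate is redundant with it).
#'
#' @param table A [phenotype_table()] or data.frame.
#' @param spec An [lr_model_spec()] with at least 2 predictors.
#' @param threshold Correlation magnitude at or above which a pair is flagged.
#'
#' @return A `collinearity_screen` with the full `correlations` matrix,
#'   `flagged_pairs` (data.frame `a`, `b`, `r`), `sign_redundant`
#'   (data.frame `base`, `derived`) and an `advice` string reminding the
#'   analyst to check coefficient-sign consistency.
#' @export
collinearity_screen <- function(table, spec, threshold = 0.99) {
  stopifnot(is.data.frame(table), inherits(spec, "lr_model_spec"))
  preds <- spec$predictors
  if (length(preds) < 2L) {
    stop("collinearity screen needs at least 2 predictors", call. = FALSE)
  }
  mf <- model_frame(table, spec, quiet = TRUE)
  M <- as.matrix(mf$frame[, preds, drop = FALSE])
  R <- suppressWarnings(stats::cor(M))

  idx <- which(upper.tri(R) & abs(R) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(a = rownames(R)[idx[, 1L]],
                        b = colnames(R)[idx[, 2L]],
                        r = R[idx], stringsAsFactors = FALSE)

  sign_redundant <- sign_redundancy(M)

  structure(list(correlations = R, threshold = threshold,
                 flagged_pairs = flagged, sign_redundant = sign_redundant,
                 advice = paste("Examine whether the directions (signs) of",
                                "the estimated coefficients are consistent",
                                "internally and with prior subject",
                                "knowledge; inconsistent signs suggest an",
                                "ill-specified model.")),
            class = "collinearity_screen")
}

# A column is sign-redundant with a base column when it takes at most two
# distinct values and is constant within each sign class of the base (with
# both sign classes present and mapped to different values).
sign_redundancy <- function(M) {
  out <- data.frame(base = character(0), derived = character(0),
                    stringsAsFactors = FALSE)
  cols <- colnames(M)
  for (d in cols) {
    vd <- M[, d]
    if (length(unique(vd)) > 2L) next
    for (b in setdiff(cols, d)) {
      sgn <- sign(M[, b])
      if (length(unique(sgn)) < 2L) next
      per_class <- tapply(vd, sgn, function(v) length(unique(v)))
      vals <- tapply(vd, sgn, function(v) v[1L])
      if (all(per_class == 1L) && length(unique(vals)) == length(vals)) {
        out <- rbind(out, data.frame(base = b, derived = d,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("Collinearity screen (|r| >= ", x$threshold, ")\n", sep = "")
  if (nrow(x$flagged_pairs)) {
    for (ii in seq_len(nrow(x$flagged_pairs))) {
      cat("  ! ", x$flagged_pairs$a[ii], " ~ ", x$flagged_pairs$b[ii],
          ": r = ", format(round(x$flagged_pairs$r[ii], 4)), "\n", sep = "")
    }
  } else {
    cat("  no pair at or above threshold\n")
  }
  if (nrow(x$sign_redundant)) {
    for (ii in seq_len(nrow(x$sign_redundant))) {
      cat("  ! '", x$sign_redundant$derived[ii], "' encodes the sign of '",
          x$sign_redundant$base[ii], "' (redundant)\n", sep = "")
    }
  }
  cat("  ", x$advice, "\n", sep = "")
  invisible(x)
}
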