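#' Specify a binary logistic regression model
#'
#' Names the outcome column, which of its two levels counts as the "event"
#' (conventionally the gregarious phase), an ordered set of predictor traits,
#' optional factor-by-trait interactions, and whether predictors are
#' mean-centred and scaled to unit standard deviation before fitting.
#'
#' Predictor order is meaningful: when the design matrix is rank deficient,
#' later-listed terms are the ones reported as aliased.
#'
#' @param predictors Character vector of trait column names (may be empty for
#'   an intercept-only model).
#' @param outcome Name of the binary environment column.
#' @param event_level Which outcome level is the modeled "event". If `NULL`,
#'   the alphabetically last level is used at fit time, with a warning.
#' @param interactions Optional list of `c(factor, trait)` character pairs;
#'   each named factor also enters as a main effect.
#' @param standardize Logical; standardize predictors before fitting
#'   (scaling constants are retained so coefficients can be mapped back).
#'
#' @return An object of class `lr_model_spec`.
#' @export
#' @examples
#' lr_model_spec(c("average_speed", "erratic_movement"),
#'               event_level = "gregarious")
lr_model_spec <- function(predictors, outcome = "environment",
                          event_level = NULL, interactions = NULL,
                          standardize = FALSE) {
  predictors <- as.character(predictors)
  if (anyDuplicated(predictors)) {
    stop("duplicated predictors in model spec", call. = FALSE)
  }
  if (!is.null(interactions)) {
    stopifnot(is.list(interactions))
    ok <- vapply(interactions, function(p) is.character(p) && length(p) == 2L,
                 logical(1))
    if (!all(ok)) {
      stop("interactions must be a list of c(factor, trait) pairs",
           call. = FALSE)
    }
  }
  structure(list(outcome = outcome, event_level = event_level,
                 predictors = predictors, interactions = interactions,
                 standardize = isTRUE(standardize)),
            class = "lr_model_spec")
}

#' @export
print.lr_model_spec <- function(x, ...) {
  rhs <- if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1"
  if (length(x$interactions)) {
    rhs <- paste(rhs, "+",
                 paste(vapply(x$interactions,
                              function(p) paste(p, collapse = ":"),
                              character(1)), collapse = " + "))
  }
  cat("LR model spec: ", x$outcome, " ~ ", rhs, "\n", sep = "")
  cat("  event level: ",
      if (is.null(x$event_level)) "<default: alphabetically last>" else x$event_level,
      "; standardize: ", x$standardize, "\n", sep = "")
  invisible(x)
}

# Resolve the event level, warning when the user left it unspecified.
resolve_event_level <- function(env, spec) {
  lev <- sort(unique(as.character(env[!is.na(env)])))
  if (length(lev) != 2L) {
    stop("outcome '", spec$outcome, "' must have exactly 2 observed levels ",
         "(found ", length(lev), ")", call. = FALSE)
  }
  if (is.null(spec$event_level)) {
    warning("event level not specified; using alphabetically last level '",
            lev[2L], "' as the event", call. = FALSE)
    lev[2L]
  } else {
    if (!spec$event_level %in% lev) {
      stop("event level '", spec$event_level, "' not among outcome levels: ",
           paste(lev, collapse = ", "), call. = FALSE)
    }
    spec$event_level
  }
}

# Columns a spec touches (outcome, predictors, interaction factors).
spec_columns <- function(spec) {
  facs <- unique(vapply(spec$interactions, `[`, character(1), 1L))
  unique(c(spec$outcome, spec$predictors, facs))
}

# Build the model frame (complete cases over modeled columns) and return the
# frame plus counts of dropped rows. Predictors must be finite.
model_frame <- function(table, spec, quiet = FALSE) {
  cols <- spec_columns(spec)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("columns missing from table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(table)[, cols, drop = FALSE]
  ok <- rep(TRUE, nrow(df))
  for (cl in cols) {
    v <- df[[cl]]
    ok <- ok & !is.na(v) & (!is.numeric(v) | is.finite(v))
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0L && !quiet) {
    message(n_dropped, " row(s) dropped under complete-case policy")
  }
  list(frame = df[ok, , drop = FALSE], n_dropped = n_dropped)
}

# Design matrix in spec order: intercept, predictors, factor main effects,
# factor:trait interactions.
build_design <- function(frame, spec, xlev = NULL) {
  terms <- spec$predictors
  if (length(spec$interactions)) {
    facs <- unique(vapply(spec$interactions, `[`, character(1), 1L))
    for (fc in facs) {
      frame[[fc]] <- if (is.null(xlev)) {
        factor(frame[[fc]])
      } else {
        factor(frame[[fc]], levels = xlev[[fc]])
      }
    }
    terms <- c(terms, facs,
               vapply(spec$interactions,
                      function(p) paste(p[1L], p[2L], sep = ":"), character(1)))
  }
  f <- if (length(terms)) {
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  } else {
    ~1
  }
  stats::model.matrix(f, frame)
}
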