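#' Coefficient of variation
#'
#' The sample CV, `sd(x) / mean(x)` (n - 1 denominator), is dimensionless
#' and scale-free: `cv(a * x) == cv(x)` for any `a > 0`. That is what makes
#' it the appropriate measure for comparing relative dispersion between a
#' raw variable and a rescaled ("normalized") version of it, where a
#' variance comparison is meaningless because variance carries the square of
#' the measurement scale.
#'
#' @param x Numeric sample with positive mean, `n >= 2`.
#' @return The scalar CV estimate.
#' @export
coefficient_of_variation <- function(x) {
  stopifnot(is.numeric(x))
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  m <- mean(x)
  if (m <= 0) {
    stop("CV undefined for non-positive sample mean", call. = FALSE)
  }
  stats::sd(x) / m
}

#' Feltz-Miller asymptotic test of equal coefficients of variation
#'
#' Tests equality of CVs across k samples with the asymptotic chi-square
#' statistic of Feltz and Miller (1996): with m_i = n_i - 1, sample CVs c_i
#' and their m-weighted pooled value c, the statistic
#' `sum(m_i (c_i - c)^2) / (c^2 (0.5 + c^2))` is chi-square with k - 1
#' degrees of freedom under equality. Because the CV is scale-free, the test
#' is invariant under separate positive rescaling of each sample — unlike
#' Bartlett's variance test (see [bartlett_k2()]).
#'
#' @param samples A list of at least 2 numeric samples, each with positive
#'   mean and `n >= 2`.
#' @return A `cv_test_result` with `cv_estimates`, `ns`, `statistic`, `df`
#'   and `p_value`.
#' @export
#' @examples
#' feltz_miller_test(list(rlnorm(40), 2 * rlnorm(40)))
feltz_miller_test <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  samples <- lapply(samples, function(x) x[!is.na(x)])
  cvs <- vapply(samples, coefficient_of_variation, numeric(1))
  ns <- vapply(samples, length, integer(1))
  m <- ns - 1
  c_pooled <- sum(m * cvs) / sum(m)
  statistic <- sum(m * (cvs - c_pooled)^2) / (c_pooled^2 * (0.5 + c_pooled^2))
  df <- length(samples) - 1L
  structure(list(cv_estimates = cvs, ns = ns, statistic = statistic,
                 df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE)),
            class = "cv_test_result")
}

#' @export
print.cv_test_result <- function(x, ...) {
  cat("Feltz-Miller asymptotic test of equal CVs\n")
  cat("  CV estimates: ",
      paste(sprintf("%.4f (n=%d)", x$cv_estimates, x$ns), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  statistic = %.4g, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Bartlett's homogeneity-of-variance statistic
#'
#' A thin wrapper around [stats::bartlett.test()], provided to make its
#' scale dependence demonstrable: variance carries the square of the
#' measurement scale, so applying Bartlett's test to a variable and a
#' rescaled copy of the *same* data (e.g. raw speed vs speed divided by a
#' body-size measure) trivially yields significance — it compares scales,
#' not dispersion. Use [feltz_miller_test()] for that question.
#'
#' @param groups A list of at least 2 numeric samples on a *common* scale,
#'   each with `n >= 2` and non-zero variance.
#' @return A list with `statistic` (K squared), `df` and `p_value`.
#' @export
bartlett_k2 <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("zero-variance group: Bartlett statistic undefined", call. = FALSE)
  }
  bt <- stats::bartlett.test(groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p_value = bt$p.value)
}

#' Divide a behavioral trait by a morphometric size trait
#'
#' Adds the ratio column `<trait>_per_<size_trait>` to the table. The new
#' column is deliberately annotated with domain `"hybrid"`, never
#' `"behavioral"`: dividing a behavioral variable by a body-size measure
#' that itself differs between phases re-introduces morphometric phase
#' signal into what is meant to be a purely behavioral predictor, and the
#' audit pipeline refuses to treat such ratios as non-morphometric.
#'
#' @param table A [phenotype_table()].
#' @param trait Name of the trait to normalize.
#' @param size_trait Name of the strictly positive size trait.
#' @param new_name Optional name for the ratio column.
#' @return The table with the added hybrid-domain ratio column.
#' @export
normalize_by_morphometric <- function(table, trait, size_trait,
                                      new_name = NULL) {
  stopifnot(inherits(table, "phenotype_table"))
  for (nm in c(trait, size_trait)) {
    if (!nm %in% names(table)) {
      stop("column '", nm, "' not found", call. = FALSE)
    }
  }
  size <- table[[size_trait]]
  if (any(size <= 0, na.rm = TRUE)) {
    stop("size trait '", size_trait, "' must be strictly positive",
         call. = FALSE)
  }
  if (is.null(new_name)) new_name <- paste0(trait, "_per_", size_trait)
  meta <- trait_meta(table)
  ts <- meta$timescale[match(trait, meta$trait)]
  df <- as.data.frame(table)
  df[[new_name]] <- df[[trait]] / size
  meta <- rbind(meta, data.frame(trait = new_name, domain = "hybrid",
                                 timescale = ts, stringsAsFactors = FALSE))
  phenotype_table(df, meta,
                  environment_col = environment_col(table),
                  strain_col = attr(table, "strain_col"),
                  stadium_col = attr(table, "stadium_col"))
}

#' Correlate two traits, within or across phases
#'
#' Pearson (with the t statistic on n - 2 degrees of freedom) or Spearman
#' (with the S statistic) correlation, via [stats::cor.test()]. The `scope`
#' argument is mandatory labeling, not computation: a correlation taken
#' *across* the two phases confounds phase differences in both traits and
#' answers a different question than a correlation *within* one phase, and
#' reports must say which was computed.
#'
#' @param x,y Paired numeric samples, `n >= 3` complete pairs.
#' @param method `"pearson"` or `"spearman"`.
#' @param scope `"within-group"` or `"across-groups"`.
#' @return A list with `coefficient`, `n`, `statistic`, `df` (Pearson only),
#'   `p_value`, `method` and `scope`.
#' @export
correlate_traits <- function(x, y, method = c("pearson", "spearman"),
                             scope = c("within-group", "across-groups")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), n = n,
       statistic = unname(ct$statistic),
       df = if (method == "pearson") n - 2L else NULL,
       p_value = ct$p.value, method = method, scope = scope)
}
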