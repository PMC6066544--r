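#' Construct a two-phase phenotype table
#'
#' The central data container: one row per individual, a binary environment
#' (phase) label, optional `strain` and `stadium` factors, and named
#' continuous trait columns. Every trait column carries metadata assigning it
#' a `domain` (`"behavioral"`, `"morphometric"` or `"hybrid"` for
#' size-normalized ratios) and a response `timescale` (`"fast"` for traits
#' that shift within hours of crowding, `"slow"` for traits fixed within a
#' stadium). The domain/timescale annotation is what lets the audit pipeline
#' warn when a model mixes traits that respond to the environment on
#' decoupled timescales.
#'
#' @param data A data.frame with the environment column and all trait columns.
#' @param trait_meta A data.frame with columns `trait`, `domain`, `timescale`,
#'   one row per trait column, or a named list `list(trait = list(domain =,
#'   timescale =))`.
#' @param environment_col Name of the binary environment/phase column.
#' @param strain_col,stadium_col Optional names of categorical columns.
#'
#' @return An object of class `phenotype_table` (a data.frame carrying the
#'   trait metadata and column-role attributes).
#' @export
#' @examples
#' d <- data.frame(environment = c("A", "A", "B", "B"), t1 = c(1, 2, 3, 4))
#' pt <- phenotype_table(d, data.frame(trait = "t1", domain = "behavioral",
#'                                     timescale = "fast"))
#' traits(pt)
phenotype_table <- function(data, trait_meta, environment_col = "environment",
                            strain_col = NULL, stadium_col = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  trait_meta <- as_trait_meta(trait_meta)

  if (!environment_col %in% names(data)) {
    stop("environment column '", environment_col, "' not found in data",
         call. = FALSE)
  }
  missing_cols <- setdiff(trait_meta$trait, names(data))
  if (length(missing_cols)) {
    stop("trait columns missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (tr in trait_meta$trait) {
    if (!is.numeric(data[[tr]])) {
      stop("trait column '", tr, "' is not numeric", call. = FALSE)
    }
  }
  for (col in c(strain_col, stadium_col)) {
    if (!is.null(col) && !col %in% names(data)) {
      stop("column '", col, "' not found in data", call. = FALSE)
    }
  }

  structure(data,
            class = c("phenotype_table", "data.frame"),
            trait_meta = trait_meta,
            environment_col = environment_col,
            strain_col = strain_col,
            stadium_col = stadium_col)
}

as_trait_meta <- function(trait_meta) {
  if (is.list(trait_meta) && !is.data.frame(trait_meta)) {
    trait_meta <- data.frame(
      trait = names(trait_meta),
      domain = vapply(trait_meta, function(m) m$domain, character(1)),
      timescale = vapply(trait_meta, function(m) m$timescale, character(1)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(trait_meta),
            all(c("trait", "domain", "timescale") %in% names(trait_meta)))
  trait_meta <- as.data.frame(trait_meta)[, c("trait", "domain", "timescale")]
  trait_meta$trait <- as.character(trait_meta$trait)
  trait_meta$domain <- as.character(trait_meta$domain)
  trait_meta$timescale <- as.character(trait_meta$timescale)
  if (anyDuplicated(trait_meta$trait)) {
    stop("duplicated trait names in trait_meta", call. = FALSE)
  }
  bad_dom <- setdiff(trait_meta$domain, c("behavioral", "morphometric", "hybrid"))
  if (length(bad_dom)) {
    stop("invalid trait domain(s): ", paste(bad_dom, collapse = ", "),
         call. = FALSE)
  }
  bad_ts <- setdiff(trait_meta$timescale, c("fast", "slow"))
  if (length(bad_ts)) {
    stop("invalid trait timescale(s): ", paste(bad_ts, collapse = ", "),
         call. = FALSE)
  }
  rownames(trait_meta) <- NULL
  trait_meta
}

#' Trait names and metadata of a phenotype table
#'
#' @param x A `phenotype_table`.
#' @return `traits()` returns the character vector of trait column names;
#'   `trait_meta()` the metadata data.frame (columns `trait`, `domain`,
#'   `timescale`); `environment_col()` the name of the phase column.
#' @export
traits <- function(x) trait_meta(x)$trait

#' @rdname traits
#' @export
trait_meta <- function(x) {
  stopifnot(inherits(x, "phenotype_table"))
  attr(x, "trait_meta")
}

#' @rdname traits
#' @export
environment_col <- function(x) attr(x, "environment_col")

#' Check that a phenotype table is ready for a two-group analysis
#'
#' Asserts the invariants assumed downstream: the environment column takes
#' exactly two distinct non-missing values, and every trait column referenced
#' in the metadata exists and is numeric.
#'
#' @param x A `phenotype_table`.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_phenotype_table <- function(x) {
  stopifnot(inherits(x, "phenotype_table"))
  env <- x[[environment_col(x)]]
  lev <- unique(env[!is.na(env)])
  if (length(lev) != 2L) {
    stop("environment column '", environment_col(x), "' must take exactly 2 ",
         "distinct values in an analysis-ready table (found ", length(lev),
         ")", call. = FALSE)
  }
  uncovered <- setdiff(traits(x), names(x))
  if (length(uncovered)) {
    stop("trait_meta references missing columns: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
`[.phenotype_table` <- function(x, i, j, drop = FALSE) {
  at <- attributes(x)
  out <- NextMethod()
  if (is.data.frame(out)) {
    meta <- at$trait_meta[at$trait_meta$trait %in% names(out), , drop = FALSE]
    rownames(meta) <- NULL
    attr(out, "trait_meta") <- meta
    attr(out, "environment_col") <- at$environment_col
    attr(out, "strain_col") <-
      if (!is.null(at$strain_col) && at$strain_col %in% names(out)) at$strain_col
    attr(out, "stadium_col") <-
      if (!is.null(at$stadium_col) && at$stadium_col %in% names(out)) at$stadium_col
    class(out) <- c("phenotype_table", "data.frame")
  }
  out
}

#' @export
print.phenotype_table <- function(x, ...) {
  env <- x[[environment_col(x)]]
  tab <- table(env)
  cat("Phenotype table: ", nrow(x), " individuals (",
      paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  tm <- trait_meta(x)
  cat(nrow(tm), " traits: ",
      sum(tm$domain == "behavioral"), " behavioral, ",
      sum(tm$domain == "morphometric"), " morphometric, ",
      sum(tm$domain == "hybrid"), " hybrid\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}
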