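#' Read a phenotype table from CSV/TSV with a trait-metadata sidecar
#'
#' The delimiter is inferred from the file extension (`.tsv`/`.tab` read as
#' tab-separated, anything else as comma-separated) unless `sep` is given.
#' Trait metadata come from a YAML or JSON sidecar mapping each trait name
#' to `{domain, timescale}`. Trait columns are coerced to numeric; rows with
#' a missing or unparseable value in the outcome or any trait column are
#' dropped under the complete-case policy, with the count reported.
#'
#' @param path Path to the data file (UTF-8, header row required).
#' @param meta_path Path to the YAML (`.yaml`/`.yml`) or JSON trait-metadata
#'   sidecar.
#' @param environment_col Name of the binary phase column.
#' @param strain_col,stadium_col Optional categorical column names.
#' @param sep Field delimiter override.
#' @param quiet Suppress the dropped-row message.
#' @return A [phenotype_table()].
#' @export
read_phenotype_table <- function(path, meta_path,
                                 environment_col = "environment",
                                 strain_col = NULL, stadium_col = NULL,
                                 sep = NULL, quiet = FALSE) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  meta <- read_trait_meta(meta_path)

  if (!environment_col %in% names(df)) {
    stop("outcome column '", environment_col, "' missing from ", path,
         call. = FALSE)
  }
  unmapped <- setdiff(meta$trait, names(df))
  if (length(unmapped)) {
    stop("trait(s) in metadata but not in data: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  ok <- !is.na(df[[environment_col]])
  for (tr in meta$trait) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    df[[tr]] <- v
    ok <- ok & !is.na(v) & is.finite(v)
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0L && !quiet) {
    message(n_dropped, " row(s) dropped under complete-case policy while ",
            "reading ", basename(path))
  }
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL

  lev <- unique(df[[environment_col]])
  if (length(lev) < 2L) {
    stop("outcome column '", environment_col, "' has fewer than 2 levels ",
         "after filtering", call. = FALSE)
  }
  phenotype_table(df, meta, environment_col = environment_col,
                  strain_col = strain_col, stadium_col = stadium_col)
}

read_trait_meta <- function(meta_path) {
  raw <- if (grepl("\\.json$", meta_path, ignore.case = TRUE)) {
    jsonlite::read_json(meta_path)
  } else {
    yaml::read_yaml(meta_path)
  }
  as_trait_meta(raw)
}

#' Write a phenotype table and its trait-metadata sidecar
#'
#' @param table A [phenotype_table()].
#' @param path Output CSV path.
#' @param meta_path Output YAML sidecar path (default: `<path>_traits.yaml`
#'   next to the data file).
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(table, path, meta_path = NULL) {
  stopifnot(inherits(table, "phenotype_table"))
  if (is.null(meta_path)) {
    meta_path <- sub("\\.csv$", "_traits.yaml", path, ignore.case = TRUE)
  }
  df <- as.data.frame(table)
  # 17 significant digits guarantee exact numeric round trips
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      v <- sprintf("%.17g", df[[cl]])
      v[is.na(df[[cl]])] <- NA_character_
      df[[cl]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- trait_meta(table)
  meta_list <- lapply(seq_len(nrow(meta)), function(ii) {
    list(domain = meta$domain[ii], timescale = meta$timescale[ii])
  })
  names(meta_list) <- meta$trait
  yaml::write_yaml(meta_list, meta_path)
  invisible(path)
}

#' Serialize an audit report to JSON or markdown
#'
#' JSON output is canonical: keys follow the report's fixed stage order and
#' numbers use shortest round-trip decimal representation, so the same
#' report always serializes to identical bytes. Markdown output renders the
#' warning catalogue messages verbatim.
#'
#' @param report An `audit_report` (complete or partial).
#' @param path Output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "audit_report"))
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null",
                         pretty = TRUE)
  } else {
    writeLines(report_markdown(report), path, useBytes = TRUE)
  }
  invisible(path)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- list(
    completed_stages = report$completed_stages,
    partial = report$partial,
    domain_census = report$domain_census,
    standardized = report$standardized,
    design = if (!is.null(report$design)) unclass(report$design),
    fit = report$fit,
    fit_error = report$fit_error,
    separation = if (!is.null(report$separation))
      unclass(report$separation),
    collinearity = if (!is.null(report$collinearity)) {
      sc <- report$collinearity
      list(threshold = sc$threshold, flagged_pairs = sc$flagged_pairs,
           sign_redundant = sc$sign_redundant)
    },
    signs = report$signs,
    validation = if (!is.null(report$validation))
      unclass(report$validation),
    warnings = report$warnings,
    config = report$config[setdiff(names(report$config), "claim")],
    claim = report$config$claim
  )
  strip(out[!vapply(out, is.null, logical(1))])
}

report_markdown <- function(report) {
  lines <- c("# Model audit report", "")
  lines <- c(lines, paste0("Completed stages: ",
                           paste(report$completed_stages, collapse = ", ")),
             "")
  if (!is.null(report$design)) {
    d <- report$design
    lines <- c(lines, sprintf(
      "Design: %d events / %d non-events, k = %d, EPV = %.2f (**%s**)",
      d$n_event, d$n_nonevent, d$k, d$epv, d$verdict), "")
  }
  if (!is.null(report$fit)) {
    f <- report$fit
    lines <- c(lines, "## Fit", "",
               sprintf("- event level: %s", f$event_level),
               sprintf("- converged: %s in %d iteration(s)", f$converged,
                       f$n_iterations),
               sprintf("- deviance: %.4f; AIC: %.4f", f$deviance, f$aic), "",
               "| term | estimate | SE |", "|---|---|---|",
               sprintf("| %s | %.6g | %.6g |", names(f$coefficients),
                       f$coefficients, f$standard_errors), "")
  }
  if (!is.null(report$fit_error)) {
    lines <- c(lines, paste0("Fit error: ", report$fit_error), "")
  }
  lines <- c(lines, "## Warnings", "")
  if (nrow(report$warnings)) {
    for (ii in seq_len(nrow(report$warnings))) {
      code <- report$warnings$code[ii]
      detail <- report$warnings$detail[ii]
      lines <- c(lines, paste0("- **", code, "**: ",
                               catalogue_message(code),
                               if (nzchar(detail)) paste0(" [", detail, "]")))
    }
  } else {
    lines <- c(lines, "- none")
  }
  if (!is.null(report$validation)) {
    v <- report$validation
    lines <- c(lines, "", "## Bootstrap validation", "",
               sprintf("- Somers' Dxy: apparent %.4f, corrected %.4f",
                       v$dxy_apparent, v$dxy_corrected),
               sprintf("- calibration intercept: corrected %.4f",
                       v$cal_intercept_corrected),
               sprintf("- calibration slope: corrected %.4f",
                       v$cal_slope_corrected),
               sprintf("- failed replicates: %d of %d", v$B_failed,
                       v$B_requested))
  }
  lines
}
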