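#' Read a long-format score table
#'
#' Reads a delimited UTF-8 table with a header row: one column per facet and
#' a final `score` column.  Comma or tab delimiter is auto-detected from the
#' header.  When a design is supplied the table is validated against it
#' (columns, balance, no missing cells) and returned in normalized form.
#'
#' @param path File path.
#' @param design Optional `gcea_design` to validate against.
#' @return data.frame (normalized when `design` is given).
#' @seealso [write_scores()]
#' @export
read_scores <- function(path, design = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("score file not found: %s", path), call. = FALSE)
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  if (!length(header) || !nzchar(trimws(header))) {
    stop(sprintf("no data in score file: %s", path), call. = FALSE)
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) {
      stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (nrow(tab) == 0L) {
    stop(sprintf("no data in score file: %s", path), call. = FALSE)
  }
  if (!"score" %in% names(tab)) {
    stop(sprintf("%s: last column must be named 'score'", path),
         call. = FALSE)
  }
  if (!is.numeric(tab$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$score))))[1L]
    stop(sprintf("%s: non-numeric score at data line %d", path, bad),
         call. = FALSE)
  }
  if (!is.null(design)) tab <- check_scores(tab, design)
  tab
}

#' Write a score table
#'
#' @param scores data.frame with facet columns and `score`.
#' @param path Destination; extension `.tsv` selects a tab delimiter,
#'   anything else comma.
#' @export
write_scores <- function(scores, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(scores, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a report object
#'
#' Writes a machine-readable JSON document when `path` ends in `.json`, else
#' a human-readable delimited table (tab for `.tsv`, comma otherwise).
#' Report objects (`gcea_vc`, D-study grids, `cea_result`) are flattened via
#' [as.data.frame()] / list conversion.
#'
#' @param report The object to write.
#' @param path Destination path.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    tab <- report_to_table(report)
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    utils::write.table(tab, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

report_to_list <- function(x) {
  if (inherits(x, "gcea_vc")) {
    return(list(design = render_design(attr(x, "design")),
                sizes = as.list(attr(x, "sizes")),
                components = as.data.frame(x)))
  }
  if (inherits(x, "cea_result")) {
    return(list(
      base = list(label = x$comparator$label,
                  total_cost = x$comparator$total_cost,
                  effectiveness = x$comparator$effectiveness),
      intervention = list(label = x$intervention$label,
                          total_cost = x$intervention$total_cost,
                          effectiveness = x$intervention$effectiveness),
      delta_cost = x$delta_cost,
      delta_effectiveness = x$delta_effectiveness,
      icer = x$icer,
      icer_rescaled = x$icer_rescaled,
      icer_display = x$icer_display,
      rescale_unit = x$rescale_unit,
      n_draws = x$n_draws,
      seed = x$seed,
      ceac = data.frame(wtp = x$wtp, probability = x$ceac)))
  }
  if (is.data.frame(x)) return(x)
  x
}

report_to_table <- function(x) {
  if (inherits(x, "gcea_vc")) return(as.data.frame(x))
  if (inherits(x, "cea_result")) {
    return(data.frame(wtp = x$wtp, probability = x$ceac))
  }
  if (is.data.frame(x)) return(x)
  as.data.frame(x)
}
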