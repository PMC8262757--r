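#' Render an annotation report as CSV
#'
#' Fixed column order: `identifier, start, end, strand, name, type_key,
#' database, identity_percent, coverage_percent, priority_score,
#' display_score, fragment, description`. Coordinates are 1-based
#' inclusive (for an origin-spanning feature `end < start`: the feature
#' wraps). Rows appear in descending priority-score order with the
#' deterministic tie-break used by the filter. The four score columns are
#' printed with one decimal place.
#'
#' @param report An `annotation_report`.
#' @return The CSV text (header plus one row per kept hit).
#' @export
report_csv <- function(report) {
  stopifnot(inherits(report, "annotation_report"))
  hits <- report$kept_hits
  df <- tibble::tibble(
    identifier = rep(report$record$identifier, nrow(hits)),
    start = hits$start + 1L,
    end = hits$end,
    strand = hits$strand,
    name = hits$name,
    type_key = hits$type_key,
    database = hits$library_tag,
    identity_percent = sprintf("%.1f", hits$identity),
    coverage_percent = sprintf("%.1f", 100 * hits$subject_cov),
    priority_score = sprintf("%.1f", hits$priority),
    display_score = sprintf("%.1f", hits$display_score),
    fragment = hits$is_fragment,
    description = hits$description
  )
  readr::format_csv(df)
}

#' Write an annotation report to a CSV file
#'
#' @param report An `annotation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  writeLines(sub("\n$", "", report_csv(report)), path)
  invisible(path)
}

#' Write an annotation report as BED6
#'
#' One line per kept hit: chrom (the record identifier), 0-based half-open
#' start/end, feature name, score (the display score rounded to an
#' integer), and strand. Origin-spanning hits are split into two lines,
#' `[start, L)` and `[0, end)`.
#'
#' @param report An `annotation_report`.
#' @param path Optional output path; when `NULL` the BED text is returned.
#' @return The BED text, invisibly when `path` is given.
#' @export
write_report_bed <- function(report, path = NULL) {
  stopifnot(inherits(report, "annotation_report"))
  hits <- report$kept_hits
  L <- nchar(report$record$sequence)
  lines <- unlist(purrr::pmap(hits, function(...) {
    h <- list(...)
    strand <- if (h$strand > 0) "+" else "-"
    score <- round(h$display_score)
    nm <- gsub("[[:space:]]+", "_", h$name)
    if (h$spans_origin) {
      c(sprintf("%s\t%d\t%d\t%s\t%d\t%s", report$record$identifier,
                h$start, L, nm, score, strand),
        sprintf("%s\t%d\t%d\t%s\t%d\t%s", report$record$identifier,
                0L, h$end, nm, score, strand))
    } else {
      sprintf("%s\t%d\t%d\t%s\t%d\t%s", report$record$identifier,
              h$start, h$end, nm, score, strand)
    }
  }), use.names = FALSE)
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(lines, path)
  invisible(text)
}
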