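#' Parse a GenBank flat file into a sequence record
#'
#' A minimal single-record GenBank reader covering the parts of the format
#' this package reads and writes: the LOCUS line (name, length, topology),
#' the FEATURES table (simple spans, `complement(...)`, and two-segment
#' `join(...)` locations across the circular origin, with multi-line
#' qualifiers), and the ORIGIN sequence block. Feature coordinates are
#' converted to 0-based half-open; a `join(a..L,1..b)` whose first segment
#' ends at the sequence length and whose second starts at base 1 is folded
#' into the wrap convention (`spans_origin = TRUE`). Any other multi-segment
#' join is represented by its bounding span.
#'
#' @param x Path to a GenBank file, or its text content.
#' @return A [sequence_record()] with `source_features` populated.
#' @export
parse_genbank <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  lines <- if (!grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0) abort_input("unparsable GenBank input: no LOCUS line")
  if (length(locus_idx) > 1) {
    abort_input(sprintf(
      "multi-sequence input: found %d GenBank records, exactly 1 is accepted",
      length(locus_idx)))
  }
  locus <- strsplit(trimws(lines[locus_idx]), "[[:space:]]+")[[1]]
  name <- if (length(locus) >= 2) locus[2] else "sequence"
  topology <- if (any(tolower(locus) == "linear")) "linear" else "circular"

  # ORIGIN block
  ori_idx <- grep("^ORIGIN", lines)
  end_idx <- grep("^//", lines)
  if (length(ori_idx) != 1 || length(end_idx) < 1) {
    abort_input("unparsable GenBank input: missing ORIGIN/terminator")
  }
  seq_lines <- lines[(ori_idx + 1):(end_idx[1] - 1)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) abort_input("unparsable GenBank input: empty sequence")
  L <- nchar(sequence)

  feats <- parse_genbank_features(lines, ori_idx, L)
  sequence_record(name, sequence, topology = topology, source_features = feats)
}

parse_genbank_features <- function(lines, ori_idx, L) {
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) return(empty_features())
  block <- lines[(fstart[1] + 1):(ori_idx - 1)]
  # feature header lines have a key starting in column 6; qualifier /
  # continuation lines are indented to column 22
  is_header <- grepl("^ {5}\\S", block)
  if (!any(is_header)) return(empty_features())
  idx <- which(is_header)
  groups <- split(seq_along(block), cumsum(is_header))
  groups <- groups[names(groups) != "0"]

  rows <- purrr::map(groups, function(ii) {
    header <- block[ii[1]]
    key <- sub("^ +(\\S+).*$", "\\1", header)
    loc <- sub("^ +\\S+ +", "", header)
    rest <- if (length(ii) > 1) block[ii[-1]] else character()
    # location may continue onto the next lines until the first qualifier
    qual_start <- grep("^ +/", rest)
    loc_extra <- if (length(qual_start) == 0) rest else rest[seq_len(qual_start[1] - 1)]
    loc <- paste0(loc, paste(trimws(loc_extra), collapse = ""))
    qual_lines <- if (length(qual_start) == 0) character() else rest[qual_start[1]:length(rest)]
    quals <- parse_qualifiers(qual_lines)
    pos <- parse_genbank_location(loc, L)
    label <- if (!is.null(quals[["label"]])) quals[["label"]] else key
    tibble::tibble(
      label = label, type_key = key,
      start = pos$start, end = pos$end, strand = pos$strand,
      spans_origin = pos$spans_origin, qualifiers = list(quals)
    )
  })
  dplyr::bind_rows(rows)
}

parse_qualifiers <- function(lines) {
  lines <- trimws(lines)
  starts <- grepl("^/", lines)
  if (!any(starts)) return(stats::setNames(character(), character()))
  grp <- cumsum(starts)
  pieces <- vapply(split(lines, grp), paste, character(1), collapse = " ")
  keys <- sub("^/([^=]+)(=.*)?$", "\\1", pieces)
  vals <- ifelse(grepl("=", pieces), sub("^/[^=]+=", "", pieces), "")
  vals <- gsub("^\"|\"$", "", vals)
  stats::setNames(vals, keys)
}

# "a..b", "complement(a..b)", "join(a..b,c..d)", "complement(join(...))",
# single base "n" -> list(start, end, strand, spans_origin) 0-based half-open
parse_genbank_location <- function(loc, L) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  spans <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
    bounds <- purrr::map(segs, parse_span)
    first <- bounds[[1]]; last <- bounds[[length(bounds)]]
    if (length(bounds) == 2 && first$to == L && last$from == 1) {
      return(list(start = first$from - 1L, end = last$to,
                  strand = strand, spans_origin = TRUE))
    }
    from <- min(purrr::map_int(bounds, "from"))
    to <- max(purrr::map_int(bounds, "to"))
    return(list(start = from - 1L, end = to, strand = strand,
                spans_origin = FALSE))
  }
  b <- parse_span(loc)
  list(start = b$from - 1L, end = b$to, strand = strand, spans_origin = spans)
}

parse_span <- function(s) {
  if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
    p <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
    list(from = p[1], to = p[2])
  } else if (grepl("^[0-9]+$", s)) {
    n <- as.integer(s)
    list(from = n, to = n)
  } else {
    abort_input(sprintf("unparsable GenBank location %s", sQuote(s)))
  }
}

# ---- writing ---------------------------------------------------------------

format_genbank_location <- function(start, end, strand, spans_origin, L) {
  loc <- if (spans_origin) {
    sprintf("join(%d..%d,1..%d)", start + 1L, L, end)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand < 0) loc <- sprintf("complement(%s)", loc)
  loc
}

wrap_qualifier <- function(key, value) {
  text <- sprintf("/%s=\"%s\"", key, value)
  strwrap(text, width = 58, exdent = 0) |>
    vapply(function(l) paste0(strrep(" ", 21), l), character(1)) |>
    unname()
}

format_feature_block <- function(type_key, location, quals) {
  head <- sprintf("     %-16s%s", type_key, location)
  c(head, unlist(purrr::imap(quals, ~ wrap_qualifier(.y, .x)), use.names = FALSE))
}

format_origin_block <- function(sequence) {
  L <- nchar(sequence)
  starts <- seq(1, L, by = 60)
  lines <- vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(tens), collapse = " "))
  }, character(1))
  c("ORIGIN", lines, "//")
}

format_genbank <- function(record, feature_blocks, definition = ".") {
  L <- nchar(record$sequence)
  locus <- sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                   record$identifier, L, record$topology,
                   toupper(format(Sys.Date(), "%d-%b-%Y")))
  c(locus,
    paste0("DEFINITION  ", definition),
    "FEATURES             Location/Qualifiers",
    feature_blocks,
    format_origin_block(record$sequence))
}

#' Write an annotation report as a GenBank flat file
#'
#' Emits one LOCUS record whose topology word matches the input record.
#' Each kept hit becomes a feature with 1-based inclusive coordinates;
#' origin-spanning hits are written as a two-segment `join()` across the
#' origin (wrapped in `complement()` on the minus strand). Qualifiers carry
#' the feature label, source database tag, percent identity, percent
#' feature coverage, fragment flag, and description.
#'
#' @param report An `annotation_report` from [annotate()].
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The GenBank text, invisibly when `path` is given.
#' @export
write_genbank <- function(report, path = NULL) {
  stopifnot(inherits(report, "annotation_report"))
  rec <- report$record
  L <- nchar(rec$sequence)
  hits <- report$kept_hits
  blocks <- character()
  if (nrow(hits) > 0) {
    blocks <- unlist(purrr::pmap(hits, function(...) {
      h <- list(...)
      loc <- format_genbank_location(h$start, h$end, h$strand, h$spans_origin, L)
      quals <- c(
        label = h$name,
        database = h$library_tag,
        identity = sprintf("%.1f", h$identity),
        match_coverage = sprintf("%.1f", 100 * h$subject_cov),
        fragment = tolower(as.character(h$is_fragment)),
        note = h$description
      )
      format_feature_block(h$type_key, loc, as.list(quals))
    }), use.names = FALSE)
  }
  text <- paste(format_genbank(rec, blocks,
                               definition = "annotated with plasmidann"),
                collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' Merge predicted features into an input GenBank record
#'
#' Writes a GenBank file containing the union of the record's pre-existing
#' features (unmodified) and the report's predicted features. Predictions
#' carry the qualifier `generated_by="plasmidann"` so the two sets remain
#' separable; no deduplication is attempted across the sets.
#'
#' @param original A [sequence_record()] parsed from GenBank input.
#' @param report An `annotation_report` for the same sequence.
#' @param path Optional output path.
#' @return The merged GenBank text, invisibly when `path` is given.
#' @export
merge_annotations <- function(original, report, path = NULL) {
  stopifnot(inherits(original, "seq_record"),
            inherits(report, "annotation_report"))
  if (!nzchar(original$sequence)) abort_input("original record has no sequence")
  L <- nchar(original$sequence)
  orig_blocks <- character()
  if (nrow(original$source_features) > 0) {
    orig_blocks <- unlist(purrr::pmap(original$source_features, function(...) {
      f <- list(...)
      loc <- format_genbank_location(f$start, f$end, f$strand, f$spans_origin, L)
      quals <- as.list(f$qualifiers)
      if (is.null(quals[["label"]])) quals$label <- f$label
      format_feature_block(f$type_key, loc, quals)
    }), use.names = FALSE)
  }
  pred_blocks <- character()
  if (nrow(report$kept_hits) > 0) {
    pred_blocks <- unlist(purrr::pmap(report$kept_hits, function(...) {
      h <- list(...)
      loc <- format_genbank_location(h$start, h$end, h$strand, h$spans_origin, L)
      quals <- list(
        label = h$name,
        database = h$library_tag,
        identity = sprintf("%.1f", h$identity),
        match_coverage = sprintf("%.1f", 100 * h$subject_cov),
        fragment = tolower(as.character(h$is_fragment)),
        note = h$description,
        generated_by = "plasmidann"
      )
      format_feature_block(h$type_key, loc, quals)
    }), use.names = FALSE)
  }
  text <- paste(format_genbank(original, c(orig_blocks, pred_blocks),
                               definition = "merged annotations"),
                collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}
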