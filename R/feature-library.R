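#' Construct a feature library
#'
#' A searchable collection of genetic parts (nucleotide) or proteins, with
#' the per-library search cutoffs attached. Default cutoffs follow the
#' published per-database configuration: nucleotide libraries use an
#' E-value cutoff of 1 and a 98% identity cutoff; translated (protein)
#' libraries use E <= 0.001 with a 98% identity cutoff, relaxed to 10% for
#' broad curated-protein collections (a `library_tag` containing
#' "swissprot"); covariance libraries use E <= 1 with no identity cutoff.
#'
#' @param entries Tibble with columns `entry_id`, `name`, `type_key`,
#'   `description`, `sequence`, and optionally `annotation_score`.
#' @param library_tag Short text tag identifying the library in output.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param search_kind `"nucleotide"`, `"translated"`, or `"covariance"`.
#'   Defaults to `"nucleotide"` for nucleotide libraries and
#'   `"translated"` for protein libraries.
#' @param evalue_cutoff,identity_cutoff Optional overrides of the default
#'   cutoffs; `identity_cutoff` is a percent in `[0, 100]` or `NA` for
#'   none.
#' @return A list of class `feature_library`.
#' @export
feature_library <- function(entries, library_tag, alphabet = NULL,
                            search_kind = NULL,
                            evalue_cutoff = NULL, identity_cutoff = NULL) {
  entries <- tibble::as_tibble(entries)
  required <- c("entry_id", "name", "type_key", "description", "sequence")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    abort_input(paste0("library entries lack column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (!"annotation_score" %in% names(entries)) {
    entries$annotation_score <- NA_integer_
  }
  entries$entry_id <- unname(as.character(entries$entry_id))
  entries$annotation_score <- as.integer(entries$annotation_score)
  entries$name <- dplyr::coalesce(as.character(entries$name), entries$entry_id)
  entries$description <- dplyr::coalesce(as.character(entries$description), "")
  entries$sequence <- unname(toupper(entries$sequence))
  entries$feature_length <- nchar(entries$sequence)
  entries <- dplyr::select(entries, dplyr::all_of(
    c("entry_id", "name", "type_key", "description", "annotation_score",
      "sequence", "feature_length")))
  if (anyDuplicated(entries$entry_id)) {
    abort_input("entry_ids are not unique within the library")
  }
  if (is.null(alphabet)) alphabet <- infer_alphabet(entries$sequence)
  alphabet <- match.arg(alphabet, c("nucleotide", "protein"))
  check_alphabet(entries, alphabet)
  if (is.null(search_kind)) {
    search_kind <- if (alphabet == "nucleotide") "nucleotide" else "translated"
  }
  search_kind <- match.arg(search_kind, c("nucleotide", "translated", "covariance"))
  if (search_kind == "translated" && alphabet != "protein") {
    abort_input("translated search requires a protein library")
  }
  defaults <- library_default_cutoffs(search_kind, library_tag)
  if (is.null(evalue_cutoff)) evalue_cutoff <- defaults$evalue
  if (is.null(identity_cutoff)) identity_cutoff <- defaults$identity
  stopifnot(evalue_cutoff > 0)
  if (!is.na(identity_cutoff)) {
    stopifnot(identity_cutoff >= 0, identity_cutoff <= 100)
  }
  structure(
    list(
      library_tag = library_tag,
      alphabet = alphabet,
      search_kind = search_kind,
      entries = entries,
      evalue_cutoff = as.numeric(evalue_cutoff),
      identity_cutoff = as.numeric(identity_cutoff)
    ),
    class = "feature_library"
  )
}

#' @export
print.feature_library <- function(x, ...) {
  cat(sprintf("<feature_library> %s: %d %s entr%s, %s search, E<=%g, identity>=%s\n",
              x$library_tag, nrow(x$entries), x$alphabet,
              if (nrow(x$entries) == 1) "y" else "ies",
              x$search_kind, x$evalue_cutoff,
              if (is.na(x$identity_cutoff)) "none" else paste0(x$identity_cutoff, "%")))
  invisible(x)
}

library_default_cutoffs <- function(search_kind, library_tag = "") {
  switch(search_kind,
    nucleotide = list(evalue = 1, identity = 98),
    translated = if (grepl("swissprot", library_tag, ignore.case = TRUE)) {
      list(evalue = 0.001, identity = 10)
    } else {
      list(evalue = 0.001, identity = 98)
    },
    covariance = list(evalue = 1, identity = NA_real_)
  )
}

infer_alphabet <- function(seqs) {
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  if (all(chars %in% IUPAC_DNA)) "nucleotide" else "protein"
}

check_alphabet <- function(entries, alphabet) {
  legal <- if (alphabet == "nucleotide") IUPAC_DNA else PROTEIN_ALPHABET
  for (i in seq_len(nrow(entries))) {
    chars <- unique(strsplit(entries$sequence[i], "")[[1]])
    bad <- setdiff(chars, legal)
    if (length(bad) > 0) {
      abort_input(sprintf(
        "entry %s contains character(s) %s illegal for a %s library",
        sQuote(entries$entry_id[i]), paste(sQuote(bad), collapse = ", "),
        alphabet))
    }
  }
  invisible(entries)
}

#' Remove entries with identical sequences
#'
#' Collapses library entries whose sequences are exactly identical after
#' uppercasing; within each duplicate group the first-listed entry
#' survives, and the output preserves the input order of survivors.
#' Reverse complements are deliberately not treated as duplicates.
#'
#' @param entries Tibble of library entries.
#' @return The deduplicated tibble.
#' @export
#' @examples
#' e <- tibble::tibble(entry_id = c("a", "b"), name = c("a", "b"),
#'   type_key = "CDS", description = "", sequence = c("ATG", "atg"))
#' dedup_identical(e)
dedup_identical <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) return(entries)
  dplyr::filter(entries, !duplicated(toupper(.data$sequence)))
}

#' Filter entries by annotation score
#'
#' Keeps entries whose `annotation_score` is at least `min_score`
#' (boundary inclusive). Entries without a score (`NA`, or the column
#' absent entirely) are kept: the filter targets libraries that carry
#' curation metadata, such as Swiss-Prot-style collections.
#'
#' @param entries Tibble of library entries.
#' @param min_score Minimum annotation score; default 3.
#' @return The filtered tibble.
#' @export
filter_by_annotation_score <- function(entries, min_score = 3L) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0 || !"annotation_score" %in% names(entries)) {
    return(entries)
  }
  dplyr::filter(entries, is.na(.data$annotation_score) |
                  .data$annotation_score >= min_score)
}

#' Load a feature library from a directory
#'
#' The directory must contain one FASTA file of sequences (`*.fa`,
#' `*.fasta`, or `*.faa`) and one tab-separated metadata sidecar (`*.tsv`)
#' keyed by `entry_id`, with columns `entry_id`, `name`, `type_key`,
#' `description`, and optionally `annotation_score`. Comment lines at the
#' top of the sidecar of the form `# key: value` override library
#' properties: `library_tag`, `alphabet`, `search_kind`, `evalue_cutoff`,
#' `identity_cutoff`. Defaults follow [feature_library()].
#'
#' @param directory Path to the library directory.
#' @return A [feature_library()].
#' @export
load_library <- function(directory) {
  if (!dir.exists(directory)) {
    abort_input(sprintf("library directory %s does not exist", sQuote(directory)))
  }
  fasta <- list.files(directory, "\\.(fa|fasta|faa)$", full.names = TRUE)
  tsv <- list.files(directory, "\\.tsv$", full.names = TRUE)
  if (length(fasta) != 1 || length(tsv) != 1) {
    abort_input(sprintf(
      "library directory must hold exactly one FASTA and one TSV (found %d / %d)",
      length(fasta), length(tsv)))
  }
  set <- Biostrings::readBStringSet(fasta)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1)

  header <- character()
  con <- file(tsv, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con); on.exit()
  opts <- parse_sidecar_header(header)
  meta <- readr::read_tsv(tsv, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (!"entry_id" %in% names(meta)) {
    abort_input("library sidecar lacks an entry_id column")
  }
  orphans <- setdiff(ids, meta$entry_id)
  if (length(orphans) > 0) {
    abort_input(paste0("FASTA id(s) missing from sidecar: ",
                       paste(orphans, collapse = ", ")))
  }
  extra <- setdiff(meta$entry_id, ids)
  if (length(extra) > 0) {
    abort_input(paste0("sidecar id(s) missing from FASTA: ",
                       paste(extra, collapse = ", ")))
  }
  entries <- tibble::tibble(entry_id = ids,
                            sequence = as.character(set)) |>
    dplyr::left_join(meta, by = "entry_id") |>
    dplyr::select(dplyr::all_of(c("entry_id", "name", "type_key", "description")),
                  dplyr::any_of("annotation_score"), dplyr::all_of("sequence"))
  feature_library(
    entries,
    library_tag = opts$library_tag %||% basename(normalizePath(directory)),
    alphabet = opts$alphabet,
    search_kind = opts$search_kind,
    evalue_cutoff = opts$evalue_cutoff,
    identity_cutoff = opts$identity_cutoff
  )
}

parse_sidecar_header <- function(lines) {
  opts <- list(library_tag = NULL, alphabet = NULL, search_kind = NULL,
               evalue_cutoff = NULL, identity_cutoff = NULL)
  for (line in lines) {
    m <- regmatches(line, regexec("^#\\s*([a-z_]+)\\s*:\\s*(\\S+)", line))[[1]]
    if (length(m) == 3 && m[2] %in% names(opts)) {
      val <- m[3]
      if (m[2] %in% c("evalue_cutoff", "identity_cutoff")) val <- as.numeric(val)
      opts[[m[2]]] <- val
    }
  }
  opts
}

#' Write a feature library to a directory
#'
#' Inverse of [load_library()]: writes `features.fa` and `features.tsv`
#' (with a header block recording the library tag, alphabet, search kind,
#' and cutoffs) such that reloading reproduces the library.
#'
#' @param library A [feature_library()].
#' @param directory Output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
dump_library <- function(library, directory) {
  stopifnot(inherits(library, "feature_library"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(directory, "features.fa")
  writeLines(paste0(">", library$entries$entry_id, "\n", library$entries$sequence), fa)
  tsv <- file.path(directory, "features.tsv")
  hdr <- c(
    sprintf("# library_tag: %s", library$library_tag),
    sprintf("# alphabet: %s", library$alphabet),
    sprintf("# search_kind: %s", library$search_kind),
    sprintf("# evalue_cutoff: %g", library$evalue_cutoff),
    if (!is.na(library$identity_cutoff))
      sprintf("# identity_cutoff: %g", library$identity_cutoff)
  )
  writeLines(hdr, tsv)
  meta <- dplyr::select(library$entries, dplyr::all_of(
    c("entry_id", "name", "type_key", "description", "annotation_score")))
  readr::write_tsv(meta, tsv, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(directory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
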