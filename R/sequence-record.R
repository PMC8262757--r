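#' Construct a plasmid sequence record
#'
#' The central input object of the pipeline: one plasmid (or other construct)
#' with its nucleotide sequence, topology, and any pre-existing annotations
#' carried over from a GenBank source file. The sequence is uppercased on
#' construction; validation against the IUPAC alphabet and length limits is
#' performed separately by [validate_sequence()].
#'
#' Coordinates of `source_features` are 0-based half-open with strand
#' `+1`/`-1`. A feature that crosses the circular origin is stored in the
#' wrap convention: `spans_origin = TRUE` and `end <= start`, meaning the
#' feature runs from `start` to the end of the sequence and continues from
#' position 0 to `end`.
#'
#' @param identifier Short text label (no whitespace).
#' @param sequence Nucleotide string.
#' @param topology `"circular"` or `"linear"`.
#' @param source_features Tibble of pre-existing features (see
#'   [empty_features()] for the column layout).
#' @return A list of class `seq_record`.
#' @export
#' @examples
#' sequence_record("p1", "atgcatgc")
sequence_record <- function(identifier, sequence,
                            topology = c("circular", "linear"),
                            source_features = empty_features()) {
  topology <- match.arg(topology)
  stopifnot(is.character(identifier), length(identifier) == 1,
            is.character(sequence), length(sequence) == 1)
  structure(
    list(
      identifier = identifier,
      sequence = toupper(sequence),
      topology = topology,
      source_features = source_features
    ),
    class = "seq_record"
  )
}

#' Empty pre-existing feature table
#'
#' Column layout used for features carried over from GenBank input:
#' `label`, `type_key`, `start`, `end` (0-based half-open), `strand`
#' (+1/-1), `spans_origin`, and a list-column `qualifiers` of named
#' character vectors.
#'
#' @return A zero-row tibble.
#' @export
empty_features <- function() {
  tibble::tibble(
    label = character(),
    type_key = character(),
    start = integer(),
    end = integer(),
    strand = integer(),
    spans_origin = logical(),
    qualifiers = list()
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %s bases, %s, %d source feature(s)\n",
              x$identifier, format(nchar(x$sequence), big.mark = ","),
              x$topology, nrow(x$source_features)))
  invisible(x)
}

#' Read a plasmid sequence from FASTA, GenBank, or raw text
#'
#' Accepts a file path or the sequence content itself. With
#' `format = "auto"` the format is sniffed from the first non-blank
#' character: `>` means FASTA, a leading `LOCUS` line means GenBank,
#' anything else is treated as raw nucleotide text. Raw text may contain
#' whitespace and line numbers (stripped before validation). Exactly one
#' sequence record is accepted; multi-record files are rejected with the
#' record count.
#'
#' Topology resolution: an explicit `topology` argument wins; otherwise the
#' GenBank LOCUS topology word is used when present; otherwise
#' `config$topology_default` (circular) applies.
#'
#' @param source A file path, or a character scalar holding the content.
#' @param format One of `"auto"`, `"fasta"`, `"genbank"`, `"raw"`.
#' @param topology Optional override: `"circular"` or `"linear"`.
#' @param config A [pipeline_config()]; supplies the file-size limit and the
#'   default topology.
#' @return A [sequence_record()]. GenBank input populates
#'   `source_features`; FASTA and raw input leave it empty.
#' @export
#' @examples
#' read_sequence_input(">p1\natgc", format = "fasta")
read_sequence_input <- function(source,
                                format = c("auto", "fasta", "genbank", "raw"),
                                topology = NULL,
                                config = pipeline_config()) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1)
  is_path <- !grepl("[\n>]", source) && file.exists(source) &&
    !dir.exists(source)
  if (is_path) {
    size <- file.info(source)$size
    if (size > config$max_file_bytes) {
      abort_input(sprintf(
        "input file is %d bytes, over the %d-byte limit", size,
        config$max_file_bytes))
    }
    text <- paste(readLines(source, warn = FALSE), collapse = "\n")
    default_id <- tools::file_path_sans_ext(basename(source))
  } else {
    if (nchar(source, type = "bytes") > config$max_file_bytes) {
      abort_input(sprintf("input text is over the %d-byte limit",
                          config$max_file_bytes))
    }
    text <- source
    default_id <- "sequence"
  }
  if (!nzchar(trimws(text))) abort_input("input is empty")

  if (format == "auto") {
    first <- substr(trimws(text), 1, 5)
    format <- if (startsWith(first, ">")) "fasta"
      else if (startsWith(first, "LOCUS")) "genbank"
      else "raw"
  }

  rec <- switch(format,
    fasta = read_fasta_record(text),
    genbank = parse_genbank(text),
    raw = {
      seq <- gsub("[0-9[:space:]]", "", text)
      sequence_record(default_id, seq, topology = config$topology_default)
    }
  )
  if (format == "fasta") {
    rec$topology <- config$topology_default
  }
  if (!is.null(topology)) {
    rec$topology <- match.arg(topology, c("circular", "linear"))
  }
  rec$source_format <- format
  rec
}

# Single-record FASTA reader built on Biostrings; the alphabet is not
# constrained here so that validate_sequence() can report offending
# characters itself.
read_fasta_record <- function(text) {
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(text, tf)
  set <- tryCatch(Biostrings::readBStringSet(tf),
                  error = function(e) {
                    abort_input(paste0("malformed FASTA input: ",
                                       conditionMessage(e)))
                  })
  if (length(set) != 1) {
    abort_input(sprintf(
      "multi-sequence input: found %d records, exactly 1 is accepted",
      length(set)))
  }
  id <- strsplit(names(set)[1], "[ \t]")[[1]][1]
  if (!nzchar(id)) id <- "sequence"
  sequence_record(id, as.character(set[[1]]))
}

#' Validate a sequence record against the configured limits
#'
#' Checks that the sequence is non-empty, no longer than
#' `config$max_seq_len` bases, composed only of IUPAC DNA codes
#' (`A,C,G,T` plus ambiguity codes; `U` is rejected), and that the
#' identifier contains no whitespace that would corrupt FASTA/GenBank
#' headers. Returns the record unchanged on success; the check is
#' idempotent.
#'
#' @param record A [sequence_record()].
#' @param config A [pipeline_config()].
#' @return The validated record, invisibly identical to the input.
#' @export
validate_sequence <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "seq_record"))
  n <- nchar(record$sequence)
  if (n < 1) abort_input("sequence is empty")
  if (n > config$max_seq_len) {
    abort_input(sprintf(
      "sequence length %d exceeds the %d-base limit", n, config$max_seq_len))
  }
  chars <- strsplit(record$sequence, "")[[1]]
  bad <- !(chars %in% IUPAC_DNA)
  if (any(bad)) {
    pos <- which(bad)
    show <- utils::head(pos, 5)
    abort_input(sprintf(
      "invalid character(s) %s at position(s) %s%s (IUPAC DNA codes only)",
      paste(sQuote(unique(chars[show])), collapse = ", "),
      paste(show, collapse = ", "),
      if (length(pos) > 5) sprintf(" (and %d more)", length(pos) - 5) else ""))
  }
  if (grepl("[[:space:]]", record$identifier)) {
    abort_input(sprintf("identifier %s contains whitespace",
                        sQuote(record$identifier)))
  }
  record
}
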