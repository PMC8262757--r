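#' Prepare the working sequence for homology search
#'
#' Circular plasmids are doubled (the sequence concatenated with itself)
#' before searching so that features spanning the arbitrary linearization
#' point are found as contiguous matches; linear records are used as-is.
#' Hit coordinates on the doubled sequence are mapped back to the plasmid
#' by [localize_hits()].
#'
#' @param record A validated [sequence_record()].
#' @return A list with `working` (the search sequence), `plasmid_length`,
#'   and `topology`.
#' @export
#' @examples
#' prepare_working_sequence(sequence_record("p", "ATGC"))$working
prepare_working_sequence <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  working <- if (record$topology == "circular") {
    paste0(record$sequence, record$sequence)
  } else {
    record$sequence
  }
  list(working = working, plasmid_length = nchar(record$sequence),
       topology = record$topology)
}

#' Describe a search backend
#'
#' @param mode `"internal"` (pure-R iterated Smith-Waterman),
#'   `"external"` (invoke a search program and parse its tabular output),
#'   or `"precomputed"` (parse a user-supplied tabular hit file).
#' @param program_path Path to the external program (defaults to `blastn`
#'   for nucleotide and `blastx` for translated searches; covariance
#'   searches expect `cmscan`).
#' @param scoring_matrix Protein scoring matrix for external translated
#'   searches (default `"PAM30"`, tuned for near-identical matches).
#' @param hits_file Tabular hit file for `mode = "precomputed"`.
#' @param model_file Covariance-model file for external `cmscan` runs.
#' @param min_anchor Minimum reported alignment length for the internal
#'   backend (columns; defaults come from [pipeline_config()]).
#' @return A list of class `search_backend`.
#' @export
search_backend <- function(mode = c("internal", "external", "precomputed"),
                           program_path = NULL, scoring_matrix = "PAM30",
                           hits_file = NULL, model_file = NULL,
                           min_anchor = NULL) {
  mode <- match.arg(mode)
  if (mode == "precomputed" && is.null(hits_file)) {
    abort_input("precomputed backend requires a hits_file")
  }
  structure(list(mode = mode, program_path = program_path,
                 scoring_matrix = scoring_matrix, hits_file = hits_file,
                 model_file = model_file, min_anchor = min_anchor),
            class = "search_backend")
}

#' Search a feature library against the working sequence
#'
#' Produces raw hits in working-sequence coordinates (0-based half-open,
#' strand +1/-1), with percent identity, E-value, alignment length in
#' nucleotides (residue columns x 3 for translated searches), and subject
#' coverage (fraction of the library feature's length covered by the
#' aligned subject span, capped at 1).
#'
#' The internal backend reports every local alignment at or above the
#' reporting floor, so every exact occurrence of an entry (or its reverse
#' complement) is reported with identity 100 and coverage 1. Covariance
#' libraries have no internal mode; their hits come from external
#' `cmscan` runs or precomputed tables.
#'
#' @param working Working sequence string from
#'   [prepare_working_sequence()].
#' @param library A [feature_library()].
#' @param backend A [search_backend()].
#' @param config A [pipeline_config()] (supplies internal-backend anchors).
#' @return A tibble of raw hits.
#' @export
search_library <- function(working, library,
                           backend = search_backend("internal"),
                           config = pipeline_config()) {
  stopifnot(inherits(library, "feature_library"),
            inherits(backend, "search_backend"))
  if (library$search_kind == "covariance" && backend$mode == "internal") {
    abort_input("covariance libraries support only external or precomputed backends")
  }
  switch(backend$mode,
    internal = {
      if (library$search_kind == "nucleotide") {
        internal_search_nucleotide(
          working, library, backend$min_anchor %||% config$min_anchor_nt)
      } else {
        internal_search_translated(
          working, library, backend$min_anchor %||% config$min_anchor_aa)
      }
    },
    external = run_external_search(working, library, backend),
    precomputed = parse_tabular_hits(backend$hits_file, library)
  )
}

run_external_search <- function(working, library, backend) {
  program <- backend$program_path %||% switch(library$search_kind,
    nucleotide = "blastn", translated = "blastx", covariance = "cmscan")
  if (Sys.which(program) == "" && !file.exists(program)) {
    abort_input(sprintf("external search program %s not found", sQuote(program)))
  }
  td <- tempfile("search"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "query.fa")
  writeLines(c(">query", working), qf)

  if (library$search_kind == "covariance") {
    if (is.null(backend$model_file)) {
      abort_input("external covariance search requires a model_file")
    }
    tbl <- file.path(td, "hits.tbl")
    status <- system2(program, c("--tblout", tbl, "--noali",
                                 shQuote(backend$model_file), shQuote(qf)),
                      stdout = FALSE, stderr = TRUE)
    if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
      abort_input(paste0("cmscan failed: ", paste(status, collapse = " ")))
    }
    return(parse_cmscan_tblout(tbl, library))
  }

  dbf <- file.path(td, "lib.fa")
  writeLines(paste0(">", library$entries$entry_id, "\n",
                    library$entries$sequence), dbf)
  dbtype <- if (library$alphabet == "nucleotide") "nucl" else "prot"
  mk <- system2("makeblastdb", c("-in", shQuote(dbf), "-dbtype", dbtype),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(mk, "status")) && attr(mk, "status") != 0) {
    abort_input(paste0("makeblastdb failed: ", paste(mk, collapse = " ")))
  }
  outfmt <- "6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore slen"
  args <- c("-query", shQuote(qf), "-db", shQuote(dbf),
            "-outfmt", shQuote(outfmt), "-evalue", "10")
  if (library$search_kind == "nucleotide") {
    args <- c(args, "-task", "blastn", "-word_size", "11", "-dust", "no",
              "-soft_masking", "false")
  } else {
    args <- c(args, "-matrix", backend$scoring_matrix,
              "-seg", "no")
  }
  out <- system2(program, args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    abort_input(sprintf("%s failed: %s", program, paste(out, collapse = " ")))
  }
  parse_tabular_hits(paste(out, collapse = "\n"), library)
}

#' Parse tab-separated search output into raw hits
#'
#' Consumes the extended 13-column tabular layout (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore slen`,
#' BLAST `-outfmt 6` plus `slen`) produced by nucleotide or translated
#' searches, or — for covariance libraries — the per-target table written
#' by `cmscan --tblout`. Query coordinates convert from 1-based inclusive
#' to 0-based half-open; an inverted coordinate pair (query or subject)
#' signals the minus strand and the pair is swapped. Translated rows
#' report `align_length_nt` as residues x 3; covariance rows fix identity
#' at 100 and coverage at 1 (the score override gives such hits a priority
#' equal to their match length).
#'
#' @param x Tabular text, or a path to a file holding it.
#' @param library The [feature_library()] the table was searched against.
#' @return A tibble of raw hits.
#' @export
parse_tabular_hits <- function(x, library) {
  stopifnot(inherits(library, "feature_library"))
  if (library$search_kind == "covariance") {
    return(parse_cmscan_tblout(x, library))
  }
  lines <- if (!grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_raw_hits())
  translated <- library$search_kind == "translated"
  lens <- stats::setNames(library$entries$feature_length,
                          library$entries$entry_id)
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(trimws(line), "[\t ]+")[[1]]
    if (length(f) < 13) {
      abort_input(sprintf("malformed hit table row %d: expected 13 columns, got %d",
                          i, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(3:11, 13)]))
    if (anyNA(num)) {
      abort_input(sprintf("malformed hit table row %d: non-numeric field", i))
    }
    sseqid <- f[2]
    if (!sseqid %in% names(lens)) {
      abort_input(sprintf("hit table row %d names unknown entry %s", i,
                          sQuote(sseqid)))
    }
    pident <- num[1]; len <- num[2]
    qstart <- num[5]; qend <- num[6]; sstart <- num[7]; send <- num[8]
    evalue <- num[9]; slen <- num[10]
    q_inv <- qstart > qend
    s_inv <- sstart > send
    strand <- if (xor(q_inv, s_inv)) -1L else 1L
    qs <- min(qstart, qend); qe <- max(qstart, qend)
    s_span <- abs(send - sstart) + 1
    tibble::tibble(
      entry_id = sseqid, library_tag = library$library_tag,
      search_kind = library$search_kind,
      q_start = as.integer(qs - 1), q_end = as.integer(qe),
      strand = strand,
      identity = pident,
      align_length_nt = as.integer(if (translated) 3 * len else len),
      subject_cov = min(1, s_span / slen),
      evalue = evalue, spans_origin = FALSE
    )
  })
  dplyr::bind_rows(rows)
}

# cmscan --tblout per-target format: target(model) name, accession, query
# name, accession, mdl, mdl from, mdl to, seq from, seq to, strand, trunc,
# pass, gc, bias, score, E-value, inc, description...
parse_cmscan_tblout <- function(x, library) {
  lines <- if (!grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_raw_hits())
  known <- library$entries$entry_id
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(trimws(line), "[\t ]+")[[1]]
    if (length(f) < 17) {
      abort_input(sprintf("malformed cmscan row %d: expected >=17 columns, got %d",
                          i, length(f)))
    }
    target <- f[1]
    if (!target %in% known) {
      abort_input(sprintf("cmscan row %d names unknown model %s", i,
                          sQuote(target)))
    }
    sf <- as.integer(f[8]); st <- as.integer(f[9])
    strand <- if (f[10] == "-") -1L else 1L
    qs <- min(sf, st); qe <- max(sf, st)
    tibble::tibble(
      entry_id = target, library_tag = library$library_tag,
      search_kind = "covariance",
      q_start = qs - 1L, q_end = qe, strand = strand,
      identity = 100, align_length_nt = qe - qs + 1L,
      subject_cov = 1,
      evalue = as.numeric(f[16]), spans_origin = FALSE
    )
  })
  dplyr::bind_rows(rows)
}

#' Apply per-library E-value and identity cutoffs
#'
#' Keeps hits with `evalue <= library$evalue_cutoff` and `identity >=
#' library$identity_cutoff` (the identity test is skipped when the library
#' declares none, as covariance libraries do). Order is preserved and the
#' hit count never increases.
#'
#' @param hits Raw-hit tibble from [search_library()].
#' @param library The [feature_library()] the hits came from.
#' @return The filtered tibble.
#' @export
apply_cutoffs <- function(hits, library) {
  stopifnot(inherits(library, "feature_library"))
  keep <- hits$evalue <= library$evalue_cutoff
  if (!is.na(library$identity_cutoff)) {
    keep <- keep & hits$identity >= library$identity_cutoff
  }
  hits[keep, , drop = FALSE]
}

#' Map working-sequence hits back onto the plasmid
#'
#' For circular records the search ran on the doubled sequence: a hit
#' lying entirely within the second copy (`q_start >= L`) is discarded as
#' the image of a first-copy hit; a hit crossing the copy boundary
#' (`q_start < L < q_end`) is rewritten into the wrap convention
#' (`end = q_end - L`, `spans_origin = TRUE`); a hit longer than the
#' plasmid itself is truncated to one full turn. Linear records pass
#' through unchanged.
#'
#' @param hits Raw-hit tibble in working-sequence coordinates.
#' @param plasmid_length Length `L` of the (un-doubled) plasmid.
#' @param topology `"circular"` or `"linear"`.
#' @return The localized tibble; `q_start`/`q_end` are renamed to
#'   `start`/`end` in plasmid coordinates.
#' @export
localize_hits <- function(hits, plasmid_length, topology) {
  L <- plasmid_length
  out <- dplyr::rename(hits, start = "q_start", end = "q_end")
  if (topology == "linear") return(out)
  out <- dplyr::filter(out, .data$start < L)
  # full-circle cap: truncate anything spanning more than one turn
  over <- (out$end - out$start) > L
  out$end[over] <- out$start[over] + L
  spans <- out$end > L
  out$end[spans] <- out$end[spans] - L
  out$spans_origin <- out$spans_origin | spans
  drop_partial_images(out, L)
}

# An origin-spanning match on the doubled sequence leaves partial images
# of itself at the copy boundary (the same plasmid bases matched again as
# a shorter alignment). Such a hit is discarded when its circular
# interval is contained in that of a longer hit to the same entry on the
# same strand: its first-copy information is already fully represented,
# exactly as for whole hits starting in the second copy.
drop_partial_images <- function(hits, L) {
  n <- nrow(hits)
  if (n < 2) return(hits)
  ulen <- ifelse(hits$spans_origin, hits$end + L - hits$start,
                 hits$end - hits$start)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[j] || ulen[i] >= ulen[j]) next
      if (hits$entry_id[i] != hits$entry_id[j] ||
          hits$strand[i] != hits$strand[j]) next
      gs <- hits$start[j]; ge <- gs + ulen[j]
      for (k in c(-L, 0L, L)) {
        if (hits$start[i] + k >= gs && hits$start[i] + k + ulen[i] <= ge) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  hits[!drop, , drop = FALSE]
}
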