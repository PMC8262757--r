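# Internal local-alignment backend.
#
# Finds all sufficiently strong local alignments between a library entry and
# the working sequence by iterated Smith-Waterman: the optimal local
# alignment is computed (Biostrings::pairwiseAlignment), recorded, and its
# footprint on the working sequence is masked with a character that scores
# heavily negative against everything, then the alignment is repeated until
# the score drops below the reporting floor. This recovers every
# non-overlapping occurrence of an entry, including the second-copy image
# produced by circular doubling, without heuristic seeding.
#
# Scoring: nucleotide match +2 / mismatch -3, gap open 10 / extend 2
# (classic megablast-like rewards); translated mode uses PAM30 with gap
# open 10 / extend 1, matching the matrix choice of translated plasmid
# searches tuned for near-identical protein matches.

NT_GAP_OPEN <- 10
NT_GAP_EXT <- 2
AA_GAP_OPEN <- 10
AA_GAP_EXT <- 1
MASK_CHAR <- "+"
MAX_ALIGN_PASSES <- 32L

nt_substitution_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      base <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                       baseOnly = FALSE)
      letters_all <- unique(c(rownames(base), MASK_CHAR))
      m <- matrix(-1000, length(letters_all), length(letters_all),
                  dimnames = list(letters_all, letters_all))
      m[rownames(base), colnames(base)] <- base
      cache <<- m
    }
    cache
  }
})

aa_substitution_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pam30 <- get_scoring_matrix("PAM30")
      letters_all <- unique(c(Biostrings::AA_ALPHABET, rownames(pam30)))
      m <- matrix(-1000, length(letters_all), length(letters_all),
                  dimnames = list(letters_all, letters_all))
      m[rownames(pam30), colnames(pam30)] <- pam30
      cache <<- m
    }
    cache
  }
})

get_scoring_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# All local alignments of `entry` against `subject_seq` with score >= floor
# and >= min_cols alignment columns. Returns a tibble with 0-based
# half-open subject coordinates, 1-based inclusive entry (pattern) span,
# match counts, alignment columns, and raw score.
iterated_local_alignments <- function(entry, subject_seq, alphabet,
                                      min_cols, score_floor) {
  if (alphabet == "nucleotide") {
    mat <- nt_substitution_matrix()
    go <- NT_GAP_OPEN; ge <- NT_GAP_EXT
    as_x <- Biostrings::DNAString
  } else {
    mat <- aa_substitution_matrix()
    go <- AA_GAP_OPEN; ge <- AA_GAP_EXT
    as_x <- Biostrings::AAString
  }
  pat <- as_x(entry)
  subj <- subject_seq
  out <- vector("list", MAX_ALIGN_PASSES)
  for (i in seq_len(MAX_ALIGN_PASSES)) {
    al <- Biostrings::pairwiseAlignment(
      pat, as_x(subj), type = "local", substitutionMatrix = mat,
      gapOpening = go, gapExtension = ge)
    sc <- Biostrings::score(al)
    s <- BiocGenerics::start(Biostrings::subject(al))
    e <- BiocGenerics::end(Biostrings::subject(al))
    if (sc < score_floor || e < s) break
    cols <- Biostrings::nchar(al)
    if (cols >= min_cols) {
      out[[i]] <- tibble::tibble(
        s_start = s - 1L, s_end = e,
        p_start = BiocGenerics::start(Biostrings::pattern(al)),
        p_end = BiocGenerics::end(Biostrings::pattern(al)),
        nmatch = Biostrings::nmatch(al),
        ncols = cols,
        raw_score = sc
      )
    }
    # mask the footprint and look for further occurrences
    subj <- paste0(substr(subj, 1, s - 1), strrep(MASK_CHAR, e - s + 1),
                   substr(subj, e + 1, nchar(subj)))
  }
  dplyr::bind_rows(out)
}

# Rough Karlin-Altschul E-value for internal-backend hits; used only
# against per-library cutoffs, never for ranking.
approx_evalue <- function(raw_score, m, n, alphabet) {
  if (alphabet == "nucleotide") {
    lambda <- 0.625; K <- 0.41   # ungapped estimates for +2/-3 scoring
  } else {
    lambda <- 0.30; K <- 0.13    # rough PAM30 parameters
  }
  bits <- (lambda * raw_score - log(K)) / log(2)
  pmax(K * m * n * 2^(-bits), 1e-300)
}

empty_raw_hits <- function() {
  tibble::tibble(
    entry_id = character(), library_tag = character(),
    search_kind = character(),
    q_start = integer(), q_end = integer(), strand = integer(),
    identity = numeric(), align_length_nt = integer(),
    subject_cov = numeric(), evalue = numeric(), spans_origin = logical()
  )
}

# Nucleotide search of one library against the working sequence.
internal_search_nucleotide <- function(working, library, min_anchor) {
  n_total <- sum(library$entries$feature_length)
  W <- nchar(working)
  score_floor <- 2 * min_anchor
  hits <- purrr::pmap(library$entries, function(entry_id, sequence,
                                                feature_length, ...) {
    per_strand <- function(entry_seq, strand) {
      als <- iterated_local_alignments(entry_seq, working, "nucleotide",
                                       min_cols = min_anchor,
                                       score_floor = score_floor)
      if (nrow(als) == 0) return(NULL)
      tibble::tibble(
        entry_id = entry_id, library_tag = library$library_tag,
        search_kind = library$search_kind,
        q_start = als$s_start, q_end = als$s_end, strand = strand,
        identity = 100 * als$nmatch / als$ncols,
        align_length_nt = as.integer(als$ncols),
        subject_cov = pmin(1, (als$p_end - als$p_start + 1) / feature_length),
        evalue = approx_evalue(als$raw_score, W, n_total, "nucleotide"),
        spans_origin = FALSE
      )
    }
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence)))
    dplyr::bind_rows(per_strand(sequence, 1L), per_strand(rc, -1L))
  })
  dplyr::bind_rows(c(list(empty_raw_hits()), hits))
}

# Translated search: align each protein entry against all six conceptual
# reading frames of the working sequence; coordinates are reported in
# nucleotides on the working sequence, alignment lengths as residues x 3.
internal_search_translated <- function(working, library, min_anchor) {
  W <- nchar(working)
  n_total <- sum(library$entries$feature_length)
  score_floor <- 4 * min_anchor
  frames <- translated_frames(working)
  hits <- purrr::pmap(library$entries, function(entry_id, sequence,
                                                feature_length, ...) {
    per_frame <- purrr::map(frames, function(fr) {
      als <- iterated_local_alignments(sequence, fr$protein, "protein",
                                       min_cols = min_anchor,
                                       score_floor = score_floor)
      if (nrow(als) == 0) return(NULL)
      # aa position p (1-based, on the frame) covers frame nt offsets
      # 3(p-1)..3p; map to forward working coordinates per strand
      aa_s <- als$s_start + 1L  # 1-based first aligned residue of the frame
      aa_e <- als$s_end         # 1-based last aligned residue
      if (fr$strand > 0) {
        q_start <- fr$offset + 3L * (aa_s - 1L)
        q_end <- fr$offset + 3L * aa_e
      } else {
        q_start <- W - (fr$offset + 3L * aa_e)
        q_end <- W - (fr$offset + 3L * (aa_s - 1L))
      }
      tibble::tibble(
        entry_id = entry_id, library_tag = library$library_tag,
        search_kind = library$search_kind,
        q_start = as.integer(q_start), q_end = as.integer(q_end),
        strand = fr$strand,
        identity = 100 * als$nmatch / als$ncols,
        align_length_nt = as.integer(3L * als$ncols),
        subject_cov = pmin(1, (als$p_end - als$p_start + 1) / feature_length),
        evalue = approx_evalue(als$raw_score, W / 3, n_total, "protein"),
        spans_origin = FALSE
      )
    })
    dplyr::bind_rows(per_frame)
  })
  dplyr::bind_rows(c(list(empty_raw_hits()), hits))
}

translated_frames <- function(working) {
  fwd <- Biostrings::DNAString(working)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- list()
  for (strand in c(1L, -1L)) {
    src <- if (strand > 0) fwd else rev
    for (offset in 0:2) {
      n_codons <- (length(src) - offset) %/% 3
      if (n_codons < 1) next
      sub <- Biostrings::subseq(src, start = offset + 1,
                                width = 3 * n_codons)
      prot <- suppressWarnings(as.character(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
      frames[[length(frames) + 1]] <- list(protein = prot, offset = offset,
                                           strand = strand)
    }
  }
  frames
}
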