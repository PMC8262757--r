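# Deterministic synthetic fixtures: toy feature libraries and composed
# plasmids with exact ground truth. Generated sequences are screened so
# that the only alignments able to pass the nucleotide cutoffs (98%
# identity, E <= 1) are the planted ones: entries share no 11-mer with
# each other (on either strand), and spacer DNA shares no 11-mer with any
# entry, including across segment junctions and the circular origin. A
# >=98%-identity spurious hit long enough to pass the E-value cutoff must
# contain an exact run of at least 11 bases, so the screen makes ground
# truth unambiguous.

DNA_BASES <- c("A", "C", "G", "T")
SCREEN_K <- 11L

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# sample() treats a length-one vector as 1:n; draw from a range safely
sample_range <- function(range, n = 1) {
  range[1] + sample.int(range[2] - range[1] + 1, n, replace = TRUE) - 1L
}

kmers <- function(seq, k = SCREEN_K) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1), k:n)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Generate a toy feature library
#'
#' Entries are independent uniform-random sequences, rejection-sampled so
#' that no two entries (or their reverse complements, for nucleotide
#' libraries) share an exact 11-base run -- which guarantees no
#' cross-hits between entries at the default nucleotide cutoffs. Output
#' is deterministic for a given seed.
#'
#' @param n_entries Number of entries (>= 1).
#' @param length_range Two-element integer range of entry lengths.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param seed Integer seed.
#' @param library_tag Library tag for the result.
#' @param type_key Feature type assigned to every entry.
#' @return A [feature_library()].
#' @export
generate_toy_library <- function(n_entries, length_range = c(150L, 400L),
                                 alphabet = c("nucleotide", "protein"),
                                 seed = 1L, library_tag = "toy",
                                 type_key = "misc_feature") {
  alphabet <- match.arg(alphabet)
  stopifnot(n_entries >= 1, length_range[1] >= 20,
            length_range[2] >= length_range[1])
  withr::with_seed(seed, {
    seqs <- character(n_entries)
    seen <- character()
    for (i in seq_len(n_entries)) {
      repeat {
        len <- sample_range(length_range)
        cand <- if (alphabet == "nucleotide") random_dna(len) else
          paste(sample(PROTEIN_ALPHABET[1:20], len, replace = TRUE),
                collapse = "")
        if (alphabet == "protein") { seqs[i] <- cand; break }
        km_f <- kmers(cand)
        km_r <- kmers(revcomp(cand))
        km <- unique(c(km_f, km_r))
        # an entry must not share a k-mer with other entries, either
        # strand, nor with its own reverse complement (else a planted
        # copy would spawn a minus-strand self-hit)
        if (!any(km_f %in% km_r) && !any(km %in% seen)) {
          seqs[i] <- cand
          seen <- c(seen, km)
          break
        }
      }
    }
    entries <- tibble::tibble(
      entry_id = sprintf("%s_%03d", library_tag, seq_len(n_entries)),
      name = sprintf("feat%03d", seq_len(n_entries)),
      type_key = type_key,
      description = sprintf("synthetic toy feature %d", seq_len(n_entries)),
      sequence = seqs
    )
    feature_library(entries, library_tag = library_tag, alphabet = alphabet)
  })
}

#' Build a planting layout
#'
#' Convenience constructor for the `layout` argument of
#' [plant_features()]: one row per feature copy to plant, in plasmid
#' order.
#'
#' @param entry_id Library entry ids (recycled columns follow).
#' @param strand +1 or -1 per planted copy.
#' @param truncation_frac Fraction of the feature actually planted, in
#'   `(0, 1]`.
#' @param keep_end `"head"` or `"tail"`: which end of the feature the
#'   truncated copy retains.
#' @return A tibble layout.
#' @export
toy_layout <- function(entry_id, strand = 1L, truncation_frac = 1,
                       keep_end = "head") {
  tibble::tibble(entry_id = entry_id, strand = as.integer(strand),
                 truncation_frac = truncation_frac, keep_end = keep_end)
}

#' Introduce point substitutions into a sequence
#'
#' Substitutes exactly `floor(length * rate)` positions, chosen without
#' replacement, each changed to a different base; deterministic for a
#' given seed. No indels are introduced, so coordinates are preserved.
#'
#' @param seq Nucleotide string.
#' @param rate Substitution rate in `[0, 0.05)`.
#' @param seed Integer seed.
#' @return A list with `sequence` (mutated) and `positions` (1-based).
#' @export
mutate_sequence <- function(seq, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 0.05)
  n <- nchar(seq)
  n_mut <- floor(n * rate)
  if (n_mut == 0) return(list(sequence = seq, positions = integer()))
  withr::with_seed(seed, {
    pos <- sort(sample.int(n, n_mut))
    chars <- strsplit(seq, "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    }
    list(sequence = paste(chars, collapse = ""), positions = pos)
  })
}

# reverse-translate a protein with uniformly sampled synonymous codons
reverse_translate <- function(protein, seed = 1L) {
  code <- Biostrings::GENETIC_CODE
  withr::with_seed(seed, {
    aas <- strsplit(protein, "")[[1]]
    codons <- vapply(aas, function(aa) {
      opts <- names(code)[code == aa]
      if (length(opts) == 0) stop("no codon for residue ", aa)
      sample(opts, 1)
    }, character(1))
    paste(codons, collapse = "")
  })
}

#' Compose a toy plasmid with planted features and exact ground truth
#'
#' Concatenates (possibly truncated, reverse-complemented, and
#' point-mutated) copies of library features separated by random spacer
#' DNA, recording the exact planted interval, strand, planted length and
#' mutation count of every copy. Truncation keeps the head or tail of the
#' feature (`ceiling(truncation_frac * length)` bases, emulating cloning
#' relics). Spacers are screened against the library (see
#' [generate_toy_library()]) and junction bases are forced to mismatch
#' the feature's continuation, so recovered alignments end exactly at the
#' planted boundaries. For protein libraries each planted copy is a
#' reverse-translated CDS of the entry.
#'
#' With circular topology, `rotate` shifts the origin by that many bases
#' (truth coordinates are remapped, possibly into the wrap convention);
#' `wrap_last = TRUE` instead rotates so the final planted feature
#' straddles the origin.
#'
#' @param library A [feature_library()].
#' @param layout A [toy_layout()] tibble.
#' @param spacer_range Integer range of spacer lengths between features.
#' @param mutation_rate Per-copy substitution rate (see
#'   [mutate_sequence()]).
#' @param seed Integer seed; all randomness derives from it.
#' @param topology `"circular"` or `"linear"`.
#' @param rotate Rotation of the origin in bases (circular only).
#' @param wrap_last Rotate so the last feature spans the origin.
#' @param id Identifier of the toy plasmid.
#' @return A list of class `toy_plasmid`: `record` (a
#'   [sequence_record()]), `truth` (tibble of planted features), `seed`,
#'   and `params`.
#' @export
plant_features <- function(library, layout, spacer_range = c(40L, 120L),
                           mutation_rate = 0, seed = 1L,
                           topology = c("circular", "linear"),
                           rotate = 0L, wrap_last = FALSE,
                           id = "toy_plasmid") {
  stopifnot(inherits(library, "feature_library"))
  topology <- match.arg(topology)
  layout <- tibble::as_tibble(layout)
  bad <- setdiff(layout$entry_id, library$entries$entry_id)
  if (length(bad) > 0) {
    abort_input(paste0("layout names unknown entries: ",
                       paste(bad, collapse = ", ")))
  }
  is_protein <- library$alphabet == "protein"

  withr::with_seed(seed, {
    pieces <- list()   # per planted feature: sequence piece + bookkeeping
    for (i in seq_len(nrow(layout))) {
      row <- layout[i, ]
      entry <- library$entries[library$entries$entry_id == row$entry_id, ]
      feat_nt <- if (is_protein) {
        reverse_translate(entry$sequence, seed = sample.int(2^30, 1))
      } else {
        entry$sequence
      }
      flen <- nchar(feat_nt)
      planted_len <- ceiling(row$truncation_frac * flen)
      if (planted_len < 20) {
        abort_input("truncation must keep at least 20 bases")
      }
      piece <- if (row$keep_end == "tail") {
        substr(feat_nt, flen - planted_len + 1, flen)
      } else {
        substr(feat_nt, 1, planted_len)
      }
      mut <- mutate_sequence(piece, mutation_rate, seed = sample.int(2^30, 1))
      piece <- mut$sequence
      if (row$strand < 0) piece <- revcomp(piece)
      pieces[[i]] <- list(seq = piece, entry_id = row$entry_id,
                          strand = row$strand, planted_len = planted_len,
                          flen_nt = flen,
                          feature_length = if (is_protein) nchar(entry$sequence)
                                           else flen,
                          truncation_frac = row$truncation_frac,
                          keep_end = row$keep_end,
                          mutation_count = length(mut$positions),
                          junctions = if (is_protein) list() else
                            truncation_continuations(feat_nt, planted_len,
                                                     row$keep_end, row$strand))
    }

    n_spacers <- nrow(layout) + 1
    spacer_lens <- sample_range(spacer_range, n_spacers)
    spacers <- vapply(spacer_lens, random_dna, character(1))

    screen <- if (is_protein) character() else
      unique(unlist(lapply(library$entries$sequence,
                           function(s) c(kmers(s), kmers(revcomp(s))))))

    assembled <- assemble_and_screen(pieces, spacers, screen,
                                     circular = topology == "circular")
    seq <- assembled$sequence
    starts <- assembled$feature_starts
    L <- nchar(seq)

    truth <- dplyr::bind_rows(purrr::imap(pieces, function(p, i) {
      tibble::tibble(
        entry_id = p$entry_id,
        start = starts[i],
        end = starts[i] + p$planted_len,
        strand = p$strand,
        spans_origin = FALSE,
        planted_len = p$planted_len,
        feature_length = p$feature_length,
        coverage = p$planted_len / p$flen_nt,
        truncation_frac = p$truncation_frac,
        keep_end = p$keep_end,
        mutation_count = p$mutation_count
      )
    }))

    if (topology == "circular" && wrap_last) {
      last <- nrow(truth)
      rotate <- truth$start[last] + truth$planted_len[last] %/% 2
    }
    if (topology == "circular" && rotate != 0) {
      rotate <- rotate %% L
      seq <- paste0(substr(seq, rotate + 1, L), substr(seq, 1, rotate))
      truth$start <- (truth$start - rotate) %% L
      ends <- truth$start + truth$planted_len
      truth$spans_origin <- ends > L
      truth$end <- ifelse(truth$spans_origin, ends - L, ends)
    }

    structure(
      list(record = sequence_record(id, seq, topology = topology),
           truth = truth, seed = seed,
           params = list(spacer_range = spacer_range,
                         mutation_rate = mutation_rate, rotate = rotate)),
      class = "toy_plasmid"
    )
  })
}

#' @export
print.toy_plasmid <- function(x, ...) {
  cat(sprintf("<toy_plasmid> %s: %d bp %s, %d planted feature(s), seed %d\n",
              x$record$identifier, nchar(x$record$sequence),
              x$record$topology, nrow(x$truth), x$seed))
  invisible(x)
}

# Where a truncated planting could extend, the alignment would run into
# the unplanted continuation of the feature. Each junction is described
# by the side of the piece it sits on ("before"/"after", in plasmid
# orientation) and the continuation bases c_1, c_2, ... in plasmid-strand
# space, ordered moving away from the piece. Spacer bases adjacent to the
# junction are later constrained to mismatch c_{j-1}, c_j, and c_{j+1},
# so neither diagonal nor one-off-diagonal alignment columns can match
# and the recovered hit ends exactly at the planted boundary.
JUNCTION_SCREEN_LEN <- 15L

truncation_continuations <- function(feat_nt, planted_len, keep_end, strand) {
  flen <- nchar(feat_nt)
  if (planted_len >= flen) return(list())
  rest <- flen - planted_len
  d <- min(JUNCTION_SCREEN_LEN, rest)
  if (keep_end == "tail") {
    # continuation runs leftwards from the kept tail
    cont <- strsplit(substr(feat_nt, flen - planted_len - d + 1,
                            flen - planted_len), "")[[1]]
    cont <- rev(cont)
    if (strand > 0) {
      list(list(side = "before", bases = cont))
    } else {
      list(list(side = "after", bases = comp_bases(cont)))
    }
  } else {
    cont <- strsplit(substr(feat_nt, planted_len + 1, planted_len + d),
                     "")[[1]]
    if (strand > 0) {
      list(list(side = "after", bases = cont))
    } else {
      list(list(side = "before", bases = comp_bases(cont)))
    }
  }
}

comp_bases <- function(b) unname(c(A = "T", C = "G", G = "C", T = "A")[b])

# Assemble spacer0 f1 spacer1 f2 ... spacerN; then repair spacer bases
# until no k-mer window touching a spacer base matches the library screen
# (scanned across the origin for circular topology) and all junction
# mismatch constraints hold.
assemble_and_screen <- function(pieces, spacers, screen, circular,
                                max_rounds = 200L) {
  k <- SCREEN_K
  build <- function() {
    segs <- character(0)
    is_spacer <- logical(0)
    piece_of <- integer(0)
    for (i in seq_along(pieces)) {
      segs <- c(segs, spacers[i], pieces[[i]]$seq)
      is_spacer <- c(is_spacer, TRUE, FALSE)
      piece_of <- c(piece_of, NA_integer_, i)
    }
    segs <- c(segs, spacers[length(spacers)])
    is_spacer <- c(is_spacer, TRUE)
    list(segs = segs, is_spacer = is_spacer)
  }

  # Constrain spacer bases near truncation junctions so that diagonal and
  # one-off-diagonal alignment columns against the feature continuation
  # all mismatch. Forbidding {c_{j-1}, c_j, c_{j+1}} leaves at least one
  # of the four bases available, so the constraint is always satisfiable.
  apply_junction_constraints <- function(chars, feature_starts, spacer_mask) {
    n <- length(chars)
    for (i in seq_along(pieces)) {
      p <- pieces[[i]]
      s <- feature_starts[i]          # 0-based start of piece
      e <- s + nchar(p$seq)           # 0-based half-open end
      for (jn in p$junctions) {
        cb <- jn$bases
        for (j in seq_along(cb)) {
          pos0 <- if (jn$side == "after") e + (j - 1L) else s - j
          if (circular) pos0 <- pos0 %% n
          if (pos0 < 0 || pos0 >= n) next
          pos <- pos0 + 1L
          if (!spacer_mask[pos]) next
          forbidden <- unique(c(cb[j],
                                if (j > 1) cb[j - 1],
                                if (j < length(cb)) cb[j + 1]))
          if (chars[pos] %in% forbidden) {
            chars[pos] <- sample(setdiff(DNA_BASES, forbidden), 1)
          }
        }
      }
    }
    chars
  }

  parts <- build()
  seq <- paste(parts$segs, collapse = "")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  seg_lens <- nchar(parts$segs)
  seg_ends <- cumsum(seg_lens)
  feature_starts <- seg_ends[which(!parts$is_spacer)] - seg_lens[which(!parts$is_spacer)]
  spacer_mask <- rep(parts$is_spacer, seg_lens)

  chars <- apply_junction_constraints(chars, feature_starts, spacer_mask)

  if (length(screen) > 0 && n >= k) {
    for (round in seq_len(max_rounds)) {
      doubled <- if (circular) c(chars, chars[seq_len(min(k - 1, n))]) else chars
      mask2 <- if (circular) c(spacer_mask, spacer_mask[seq_len(min(k - 1, n))]) else spacer_mask
      text <- paste(doubled, collapse = "")
      wins <- substring(text, 1:(length(doubled) - k + 1),
                        k:length(doubled))
      touches_spacer <- vapply(1:(length(doubled) - k + 1), function(s) {
        any(mask2[s:(s + k - 1)])
      }, logical(1))
      bad <- which(touches_spacer & (wins %in% screen))
      if (length(bad) == 0) break
      for (s in bad) {
        span <- ((s:(s + k - 1) - 1) %% n) + 1
        for (pos in span[spacer_mask[span]]) {
          chars[pos] <- sample(DNA_BASES, 1)
        }
      }
      chars <- apply_junction_constraints(chars, feature_starts, spacer_mask)
      if (round == max_rounds) {
        stop("could not screen spacers against the library; ",
             "try a different seed")
      }
    }
  }

  list(sequence = paste(chars, collapse = ""),
       feature_starts = as.integer(feature_starts))
}
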