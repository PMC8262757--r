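# Independent oracles used by the property tests. These deliberately share
# no code with the package: the aligner oracle is a plain Gotoh DP over
# character vectors, and the interval oracle works on enumerated base sets.

# Brute-force local alignment (Smith-Waterman with affine gaps), same
# scoring as the package's nucleotide backend: match +2, mismatch -3,
# gap open 10, gap extension 2 (a gap of length g costs 10 + 2g).
# Returns the single best local alignment: score, 0-based half-open
# subject interval, 1-based pattern span, matches, and columns.
sw_oracle <- function(pattern, subject,
                      match = 2, mismatch = -3, gap_open = 10, gap_ext = 2) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)     # aligned-pair state
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in subject (consumes pattern)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in pattern (consumes subject)
  tbM <- matrix("0", n + 1, m + 1)
  tbIx <- matrix("M", n + 1, m + 1)
  tbIy <- matrix("M", n + 1, m + 1)
  open <- -(gap_open + gap_ext)
  ext <- -gap_ext
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (p[i] == s[j]) match else mismatch
      cand <- c(0, M[i, j] + sub, Ix[i, j] + sub, Iy[i, j] + sub)
      w <- which.max(cand)
      M[i + 1, j + 1] <- cand[w]
      # a predecessor M-cell worth 0 is an alignment start, not a column
      tbM[i + 1, j + 1] <- if (w == 2 && M[i, j] <= 0) "0"
        else c("0", "M", "Ix", "Iy")[w]
      cx <- c(M[i, j + 1] + open, Ix[i, j + 1] + ext)
      Ix[i + 1, j + 1] <- max(cx)
      tbIx[i + 1, j + 1] <- if (which.max(cx) == 1) "M" else "Ix"
      cy <- c(M[i + 1, j] + open, Iy[i + 1, j] + ext)
      Iy[i + 1, j + 1] <- max(cy)
      tbIy[i + 1, j + 1] <- if (which.max(cy) == 1) "M" else "Iy"
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, s_start = NA, s_end = NA, p_start = NA,
                p_end = NA, nmatch = 0, ncols = 0))
  }
  i <- bi; j <- bj; state <- "M"
  nmatch <- 0; ncols <- 0
  repeat {
    if (state == "M") {
      nmatch <- nmatch + (p[i] == s[j])
      ncols <- ncols + 1
      src <- tbM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
      if (src == "0") break
      state <- src
    } else if (state == "Ix") {
      ncols <- ncols + 1
      src <- tbIx[i + 1, j + 1]
      i <- i - 1
      state <- src
    } else {
      ncols <- ncols + 1
      src <- tbIy[i + 1, j + 1]
      j <- j - 1
      state <- src
    }
  }
  list(score = best, s_start = j, s_end = bj, p_start = i + 1, p_end = bi,
       nmatch = nmatch, ncols = ncols)
}

# Enumerate the 0-based positions of a (possibly origin-wrapped) interval
# on a circle of length L, in interval order.
interval_bases <- function(start, end, spans_origin, L) {
  len <- (if (spans_origin) end + L else end) - start
  (seq.int(start, length.out = len) %% L)
}

# Trimmed core by base enumeration: drop floor(len * trim) bases from
# each end of the ordered base list; degenerate cores keep the middle base.
core_bases <- function(start, end, spans_origin, L, trim) {
  b <- interval_bases(start, end, spans_origin, L)
  t <- floor(length(b) * trim)
  if (length(b) - 2 * t < 1) return(b[length(b) %/% 2 + 1])
  b[(t + 1):(length(b) - t)]
}

# Greedy filter oracle on base sets: same scan order contract, fully
# independent interval geometry.
filter_oracle <- function(hits, L, circular, trim) {
  ord <- order(-hits$priority, -hits$align_length_nt, hits$start,
               hits$library_tag, hits$entry_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  kept <- logical(nrow(hits))
  cores <- list()
  for (i in seq_len(nrow(hits))) {
    full <- interval_bases(hits$start[i], hits$end[i], hits$spans_origin[i],
                           if (circular) L else 10 * L)
    if (!circular) {
      full <- seq.int(hits$start[i], hits$end[i] - 1)
    }
    blocked <- any(vapply(cores, function(co) length(intersect(full, co)) > 0,
                          logical(1)))
    if (!blocked) {
      kept[i] <- TRUE
      co <- if (circular) {
        core_bases(hits$start[i], hits$end[i], hits$spans_origin[i], L, trim)
      } else {
        b <- seq.int(hits$start[i], hits$end[i] - 1)
        t <- floor(length(b) * trim)
        if (length(b) - 2 * t < 1) b[length(b) %/% 2 + 1]
        else b[(t + 1):(length(b) - t)]
      }
      cores[[length(cores) + 1]] <- co
    }
  }
  hits[kept, , drop = FALSE]
}

# Random scored-hit tables for filter property tests.
random_hits <- function(n, L, allow_wrap = TRUE) {
  start <- sample.int(L, n) - 1L
  len <- sample(5:max(6, L %/% 2), n, replace = TRUE)
  ends <- start + len
  spans <- allow_wrap & ends > L
  tibble::tibble(
    entry_id = sprintf("e%02d", seq_len(n)),
    library_tag = sample(c("libA", "libB"), n, replace = TRUE),
    search_kind = "nucleotide",
    start = start,
    end = ifelse(spans, ends - L, pmin(ends, L)),
    strand = sample(c(1L, -1L), n, replace = TRUE),
    identity = round(stats::runif(n, 90, 100), 1),
    align_length_nt = as.integer(ifelse(spans, len, pmin(ends, L) - start)),
    subject_cov = round(stats::runif(n, 0.3, 1), 2),
    evalue = 1e-10,
    spans_origin = spans,
    priority = round(stats::runif(n, 1, 100), 1)
  )
}

# Small deterministic toy setup shared across tests.
toy_setup <- function(lib_seed = 7, plasmid_seed = 3, n = 4,
                      layout_rows = 3, ...) {
  lib <- generate_toy_library(n, seed = lib_seed)
  ids <- lib$entries$entry_id[seq_len(layout_rows)]
  toy <- plant_features(lib, toy_layout(ids), seed = plasmid_seed, ...)
  list(lib = lib, toy = toy)
}
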