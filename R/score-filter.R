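# Priority scoring, trimmed-core overlap resolution, and fragment
# flagging: the ranking logic that decides which of many overlapping
# homology hits are reported.

#' Compute the hit priority score
#'
#' Each hit is scored as the product of three terms: the match length in
#' nucleotides, the fractional percent identity, and the fraction of the
#' library feature's length covered by the match:
#' `align_length_nt * (identity / 100) * subject_cov`. The score favours
#' long, near-perfect, complete matches over the E-values and bit scores
#' of the underlying search programs, which can rank short perfect hits
#' above the intended full-length feature.
#'
#' Covariance-model hits are detected by a score threshold rather than by
#' alignment to a concrete sequence, so their identity and coverage terms
#' are fixed at 1: their priority equals the match length, the same scale
#' a perfect full-length nucleotide hit attains.
#'
#' @param hits Localized hit tibble.
#' @return The tibble with a `priority` column added.
#' @export
compute_priority_score <- function(hits) {
  dplyr::mutate(
    hits,
    priority = ifelse(
      .data$search_kind == "covariance",
      as.numeric(.data$align_length_nt),
      .data$align_length_nt * (.data$identity / 100) * .data$subject_cov
    )
  )
}

#' Trimmed core of a hit interval
#'
#' Shrinks an interval by `floor(length * trim_frac)` bases on each side;
#' the result is the "core" that lower-scoring hits must avoid. Interval
#' length is computed on the circle for origin-spanning hits. If trimming
#' would empty or invert the interval, the single central base is
#' returned.
#'
#' @param start,end 0-based half-open interval (wrap convention for
#'   origin-spanning hits).
#' @param spans_origin Logical; whether the interval wraps the origin.
#' @param L Plasmid length.
#' @param trim_frac Fraction trimmed from each side (default 0.15).
#' @return A list with `start`, `end`, `spans_origin` of the core.
#' @export
#' @examples
#' trimmed_core(0, 100, FALSE, 1000)   # [15, 85)
trimmed_core <- function(start, end, spans_origin, L, trim_frac = 0.15) {
  uend <- if (spans_origin) end + L else end
  len <- uend - start
  t <- floor(len * trim_frac)
  cs <- start + t
  ce <- uend - t
  if (ce - cs < 1) {
    cs <- start + len %/% 2
    ce <- cs + 1
  }
  if (cs >= L) {  # whole core lies in the wrapped-around part
    cs <- cs - L
    ce <- ce - L
  }
  list(start = cs,
       end = if (ce > L) ce - L else ce,
       spans_origin = ce > L && cs < L)
}

# unwrapped [start, uend) representation of a wrapped interval
unwrap_interval <- function(start, end, spans_origin, L) {
  c(start, if (spans_origin) end + L else end)
}

# does [s1,e1) intersect [s2,e2) on the circle of circumference L?
# (linear topology: plain interval overlap)
circular_intersects <- function(s1, e1, s2, e2, L, circular) {
  shifts <- if (circular) c(-L, 0, L) else 0
  any(s1 < e2 + shifts & s2 + shifts < e1)
}

#' Resolve overlapping hits with the trimmed-core greedy filter
#'
#' Hits are sorted by descending priority score (ties broken by longer
#' alignment, then smaller start, then library tag, then entry id) and
#' scanned in that order. A hit is kept if and only if its full interval
#' does not intersect the trimmed core (see [trimmed_core()]) of any
#' already-kept hit; intersection is evaluated on the circle for circular
#' topology. Trimming the winners' flanks lets inherently overlapping
#' features (for example the repA and repC genes of the RSF1010 origin)
#' coexist while still suppressing redundant variants of the same
#' feature.
#'
#' @param hits Scored, localized hit tibble (must carry `priority`).
#' @param L Plasmid length.
#' @param topology `"circular"` or `"linear"`.
#' @param trim_frac Fraction trimmed from each side of a winner.
#' @return The kept hits, in scan (descending-score) order.
#' @export
resolve_overlaps <- function(hits, L, topology, trim_frac = 0.15) {
  stopifnot("priority" %in% names(hits))
  circular <- topology == "circular"
  ord <- order(-hits$priority, -hits$align_length_nt, hits$start,
               hits$library_tag, hits$entry_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  n <- nrow(hits)
  if (n == 0) return(hits)
  keep <- logical(n)
  cores <- list()
  for (i in seq_len(n)) {
    iv <- unwrap_interval(hits$start[i], hits$end[i], hits$spans_origin[i], L)
    blocked <- FALSE
    for (core in cores) {
      if (circular_intersects(iv[1], iv[2], core[1], core[2], L, circular)) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) {
      keep[i] <- TRUE
      co <- trimmed_core(hits$start[i], hits$end[i], hits$spans_origin[i],
                         L, trim_frac)
      cores[[length(cores) + 1]] <- unwrap_interval(co$start, co$end,
                                                    co$spans_origin, L)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Flag incomplete feature fragments
#'
#' Marks hits whose subject coverage is strictly below the configured
#' threshold (default 0.95) as possible feature fragments: relics of past
#' cloning that no longer span the full library feature but may retain or
#' regain function.
#'
#' @param hits Hit tibble with `subject_cov`.
#' @param fragment_threshold Coverage threshold; strictly-below is a
#'   fragment.
#' @return The tibble with an `is_fragment` column.
#' @export
flag_fragment <- function(hits, fragment_threshold = 0.95) {
  dplyr::mutate(hits, is_fragment = .data$subject_cov < fragment_threshold)
}

#' Combined display score
#'
#' The score surfaced to users alongside each feature: the fraction of
#' the feature's length matched multiplied by the percent identity of the
#' match, i.e. `subject_cov * identity`, a percentage in `[0, 100]`.
#'
#' @param hits Hit tibble.
#' @return The tibble with a `display_score` column.
#' @export
compute_display_score <- function(hits) {
  dplyr::mutate(hits, display_score = .data$subject_cov * .data$identity)
}
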