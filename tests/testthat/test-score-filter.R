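scored_hit <- function(start, end, priority = NULL, len = NULL,
                       spans_origin = FALSE, identity = 100, cov = 1,
                       kind = "nucleotide", id = "e1", tag = "lib") {
  len <- len %||% ((if (spans_origin) end + 1000 else end) - start)
  h <- tibble::tibble(
    entry_id = id, library_tag = tag, search_kind = kind,
    start = as.integer(start), end = as.integer(end), strand = 1L,
    identity = identity, align_length_nt = as.integer(len),
    subject_cov = cov, evalue = 1e-9, spans_origin = spans_origin)
  h <- compute_priority_score(h)
  if (!is.null(priority)) h$priority <- priority
  h
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the priority score is the three-term product", {
  h <- scored_hit(0, 100)
  expect_equal(h$priority, 100)
  h2 <- compute_priority_score(tibble::tibble(
    search_kind = "nucleotide", align_length_nt = 200L,
    identity = 98, subject_cov = 0.5))
  expect_equal(h2$priority, 98)
  cv <- compute_priority_score(tibble::tibble(
    search_kind = "covariance", align_length_nt = 85L,
    identity = 100, subject_cov = 1))
  expect_equal(cv$priority, 85)
  # the covariance override keeps such hits on the match-length scale:
  # an 85-base covariance hit outranks any shorter perfect nucleotide hit
  nt <- compute_priority_score(tibble::tibble(
    search_kind = "nucleotide", align_length_nt = 84L,
    identity = 100, subject_cov = 1))
  expect_gt(cv$priority, nt$priority)
})

test_that("trimmed_core shrinks by floor(len * trim) per side", {
  expect_equal(trimmed_core(0, 100, FALSE, 1000),
               list(start = 15, end = 85, spans_origin = FALSE))
  expect_equal(trimmed_core(10, 13, FALSE, 1000),
               list(start = 10, end = 13, spans_origin = FALSE))
  # circular interval of length 100 wrapping the origin
  expect_equal(trimmed_core(950, 50, TRUE, 1000),
               list(start = 965, end = 35, spans_origin = TRUE))
  # verified by rotating to a linear frame: shifting by +50 makes the
  # interval [0,100) with core [15,85), i.e. 965 and 35 after unshifting
  co <- trimmed_core(990, 90, TRUE, 1000)
  expect_equal(co$start, 5)   # 990 + 15 wraps past the origin
  expect_equal(co$end, 75)
  expect_false(co$spans_origin)
})

test_that("trimmed_core base-set oracle agrees across random intervals", {
  withr::with_seed(83, {
    L <- 500
    for (rep in 1:50) {
      start <- sample(0:(L - 1), 1)
      len <- sample(3:L, 1)
      uend <- start + len
      spans <- uend > L
      end <- if (spans) uend - L else uend
      trim <- sample(c(0, 0.1, 0.15, 0.3), 1)
      co <- trimmed_core(start, end, spans, L, trim)
      expect_equal(interval_bases(co$start, co$end, co$spans_origin, L),
                   core_bases(start, end, spans, L, trim))
    }
  })
})

test_that("the filter keeps or drops by intersection with the winner core", {
  single <- scored_hit(0, 100)
  expect_equal(nrow(resolve_overlaps(single, 1000, "circular")), 1)
  # a lower hit inside the core is dropped
  two <- dplyr::bind_rows(scored_hit(0, 100),
                          scored_hit(40, 60, id = "e2"))
  kept <- resolve_overlaps(two, 1000, "circular")
  expect_equal(kept$entry_id, "e1")
  # a lower hit touching only the trimmed flank is kept
  flank <- dplyr::bind_rows(scored_hit(0, 100),
                            scored_hit(0, 12, id = "e2"))
  kept2 <- resolve_overlaps(flank, 1000, "circular")
  expect_setequal(kept2$entry_id, c("e1", "e2"))
})

test_that("the filter matches the base-set oracle on random inputs", {
  withr::with_seed(101, {
    for (rep in 1:120) {
      L <- sample(c(60, 100, 250), 1)
      n <- sample(2:8, 1)
      circular <- rep %% 3 != 0
      hits <- random_hits(n, L, allow_wrap = circular)
      trim <- sample(c(0, 0.15, 0.25), 1)
      topo <- if (circular) "circular" else "linear"
      got <- resolve_overlaps(hits, L, topo, trim)
      want <- filter_oracle(hits, L, circular, trim)
      expect_equal(got$entry_id, want$entry_id)
    }
  })
})

test_that("the kept set is the unique scan-consistent subset", {
  # brute force over all subsets: exactly one subset is consistent with
  # the keep rule, and it is the filter's answer
  withr::with_seed(113, {
    for (rep in 1:25) {
      L <- 100
      n <- sample(3:6, 1)
      hits <- random_hits(n, L)
      got <- resolve_overlaps(hits, L, "circular", 0.15)
      ord <- order(-hits$priority, -hits$align_length_nt, hits$start,
                   hits$library_tag, hits$entry_id, method = "radix")
      sorted <- hits[ord, ]
      fulls <- lapply(seq_len(n), function(i)
        interval_bases(sorted$start[i], sorted$end[i],
                       sorted$spans_origin[i], L))
      cores <- lapply(seq_len(n), function(i)
        core_bases(sorted$start[i], sorted$end[i], sorted$spans_origin[i],
                   L, 0.15))
      consistent <- list()
      for (mask in 0:(2^n - 1)) {
        inset <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
        ok <- TRUE
        for (i in seq_len(n)) {
          blocked <- any(vapply(seq_len(i - 1), function(j) {
            inset[j] && length(intersect(fulls[[i]], cores[[j]])) > 0
          }, logical(1)))
          if (inset[i] == blocked) { ok <- FALSE; break }
        }
        if (ok) consistent[[length(consistent) + 1]] <- inset
      }
      expect_length(consistent, 1)
      expect_equal(sorted$entry_id[consistent[[1]]], got$entry_id)
    }
  })
})

test_that("filtering is idempotent and monotone in the winners", {
  withr::with_seed(127, {
    for (rep in 1:30) {
      L <- 200
      hits <- random_hits(sample(3:8, 1), L)
      kept <- resolve_overlaps(hits, L, "circular")
      expect_equal(resolve_overlaps(kept, L, "circular"), kept)
      # adding one hit never evicts a strictly higher-scoring kept hit
      extra <- random_hits(1, L)
      extra$entry_id <- "zzz"
      kept2 <- resolve_overlaps(dplyr::bind_rows(hits, extra), L, "circular")
      higher <- kept$entry_id[kept$priority > extra$priority]
      expect_true(all(higher %in% kept2$entry_id))
    }
  })
})

test_that("with trim 0 no kept hit overlaps a higher-scoring kept hit", {
  withr::with_seed(131, {
    for (rep in 1:20) {
      L <- 150
      hits <- random_hits(sample(4:8, 1), L)
      kept <- resolve_overlaps(hits, L, "circular", trim_frac = 0)
      bases <- lapply(seq_len(nrow(kept)), function(i)
        interval_bases(kept$start[i], kept$end[i], kept$spans_origin[i], L))
      for (i in seq_len(nrow(kept))) {
        for (j in seq_len(i - 1)) {
          expect_length(intersect(bases[[i]], bases[[j]]), 0)
        }
      }
    }
  })
})

test_that("kept lower hits never intersect a kept winner's core", {
  withr::with_seed(137, {
    for (rep in 1:20) {
      L <- 300
      hits <- random_hits(sample(4:8, 1), L)
      kept <- resolve_overlaps(hits, L, "circular")
      for (i in seq_len(nrow(kept))) {
        for (j in seq_len(i - 1)) {
          full <- interval_bases(kept$start[i], kept$end[i],
                                 kept$spans_origin[i], L)
          core <- core_bases(kept$start[j], kept$end[j],
                             kept$spans_origin[j], L, 0.15)
          expect_length(intersect(full, core), 0)
        }
      }
    }
  })
})

test_that("the fragment flag flips strictly at the coverage threshold", {
  covs <- c(0.80, 0.94, 0.9499, 0.95, 0.9501, 0.96, 1.0)
  h <- tibble::tibble(subject_cov = covs)
  out <- flag_fragment(h, 0.95)
  expect_equal(out$is_fragment, covs < 0.95)
  expect_equal(flag_fragment(h, 0.99)$is_fragment, covs < 0.99)
})

test_that("the display score is coverage times identity", {
  expect_equal(compute_display_score(tibble::tibble(
    subject_cov = 1, identity = 100))$display_score, 100)
  expect_equal(compute_display_score(tibble::tibble(
    subject_cov = 0.5, identity = 98))$display_score, 49)
  expect_equal(compute_display_score(tibble::tibble(
    subject_cov = 0.183, identity = 100))$display_score, 18.3)
})
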