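test_that("circular records are doubled; linear records are not", {
  circ <- prepare_working_sequence(sequence_record("c", "ATGC"))
  expect_equal(circ$working, "ATGCATGC")
  expect_equal(circ$plasmid_length, 4)
  lin <- prepare_working_sequence(sequence_record("l", "ATGC",
                                                  topology = "linear"))
  expect_equal(lin$working, "ATGC")
  single <- prepare_working_sequence(sequence_record("s", "A"))
  expect_equal(single$working, "AA")
  expect_equal(single$plasmid_length, 1)
})

test_that("the internal backend finds planted matches on both strands", {
  withr::with_seed(41, {
    entry <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    bg1 <- paste(sample(c("A", "C", "G", "T"), 37, TRUE), collapse = "")
    bg2 <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  })
  lib <- feature_library(
    tibble::tibble(entry_id = "f1", name = "f1", type_key = "misc_feature",
                   description = "", sequence = entry), "t")
  working <- paste0(bg1, entry, bg2)
  hits <- search_library(working, lib)
  hits <- hits[hits$identity >= 98, ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$q_start, 37L)
  expect_equal(hits$q_end, 157L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$subject_cov, 1)
  expect_equal(hits$strand, 1L)

  working_rc <- paste0(bg1, plasmidann:::revcomp(entry), bg2)
  hits_rc <- search_library(working_rc, lib)
  hits_rc <- hits_rc[hits_rc$identity >= 98, ]
  expect_equal(hits_rc$strand, -1L)
  expect_equal(hits_rc$q_start, 37L)
  expect_equal(hits_rc$identity, 100)
})

test_that("a single substitution yields 99% identity on a 100-base entry", {
  withr::with_seed(43, {
    entry <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    bg1 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    bg2 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  })
  chars <- strsplit(entry, "")[[1]]
  chars[50] <- setdiff(c("A", "C", "G", "T"), chars[50])[1]
  lib <- feature_library(
    tibble::tibble(entry_id = "f1", name = "f1", type_key = "misc_feature",
                   description = "", sequence = entry), "t")
  hits <- search_library(paste0(bg1, paste(chars, collapse = ""), bg2), lib)
  hits <- hits[which.max(hits$align_length_nt), ]
  expect_equal(hits$identity, 99.0)
  expect_equal(hits$align_length_nt, 100L)
})

test_that("internal backend matches the brute-force aligner oracle", {
  withr::with_seed(57, {
    for (rep in 1:40) {
      L <- sample(80:200, 1)
      el <- sample(25:60, 1)
      entry <- paste(sample(c("A", "C", "G", "T"), el, TRUE), collapse = "")
      bg <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      pos <- sample(seq_len(L - el), 1)
      chars <- strsplit(entry, "")[[1]]
      for (k in seq_len(sample(0:2, 1))) {
        i <- sample(el, 1)
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
      }
      subject <- paste0(substr(bg, 1, pos - 1), paste(chars, collapse = ""),
                        substr(bg, pos + el, L))
      o <- sw_oracle(entry, subject)
      h <- plasmidann:::iterated_local_alignments(entry, subject,
                                                  "nucleotide", 11, 22)
      expect_gt(nrow(h), 0)
      h <- h[which.max(h$raw_score), ]
      expect_equal(h$raw_score, o$score)
      expect_equal(h$s_start, o$s_start)
      expect_equal(h$s_end, o$s_end)
      expect_equal(h$nmatch, o$nmatch)
      expect_equal(h$ncols, o$ncols)
    }
  })
})

test_that("tabular rows convert coordinates, strand, and units", {
  lib <- feature_library(
    tibble::tibble(entry_id = "f1", name = "f1", type_key = "misc_feature",
                   description = "",
                   sequence = strrep("ACGTA", 24)), "t")  # length 120
  row <- "plas\tf1\t100.000\t120\t0\t0\t38\t157\t1\t120\t1e-60\t222\t120"
  h <- parse_tabular_hits(row, lib)
  expect_equal(h$q_start, 37L)
  expect_equal(h$q_end, 157L)
  expect_equal(h$strand, 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$subject_cov, 1.0)
  expect_equal(h$align_length_nt, 120L)

  # inverted query coordinates signal the minus strand and are swapped
  row2 <- "plas\tf1\t99.000\t100\t1\t0\t157\t38\t1\t100\t1e-40\t180\t120"
  h2 <- parse_tabular_hits(row2, lib)
  expect_equal(h2$strand, -1L)
  expect_equal(h2$q_start, 37L)
  expect_equal(h2$q_end, 157L)
  # inverted subject coordinates mean the same thing (blastn convention)
  row3 <- "plas\tf1\t99.000\t100\t1\t0\t38\t157\t100\t1\t1e-40\t180\t120"
  expect_equal(parse_tabular_hits(row3, lib)$strand, -1L)

  plib <- feature_library(
    tibble::tibble(entry_id = "p1", name = "p1", type_key = "CDS",
                   description = "",
                   sequence = strrep("MKTAYIAKQR", 4)), "pt",
    alphabet = "protein")  # 40 residues
  prow <- "plas\tp1\t100.000\t40\t0\t0\t10\t129\t1\t40\t1e-20\t90\t40"
  hp <- parse_tabular_hits(prow, plib)
  expect_equal(hp$align_length_nt, 120L)
  expect_equal(hp$subject_cov, 1.0)
})

test_that("malformed rows and unknown subjects are rejected with context", {
  lib <- feature_library(
    tibble::tibble(entry_id = "f1", name = "f1", type_key = "misc_feature",
                   description = "", sequence = strrep("ACGT", 10)), "t")
  expect_error(parse_tabular_hits("plas\tf1\t100\t10", lib), "row 1")
  good <- "plas\tf1\t100\t40\t0\t0\t1\t40\t1\t40\t1e-9\t70\t40"
  expect_error(parse_tabular_hits(paste(good, "plas\tzz\t100\t40\t0\t0\t1\t40\t1\t40\t1e-9\t70\t40",
                                        sep = "\n"), lib), "zz")
})

test_that("cmscan per-target tables parse with the score override", {
  lib <- feature_library(
    tibble::tibble(entry_id = "rna1", name = "rna1", type_key = "ncRNA",
                   description = "", sequence = strrep("ACGT", 25)), "rfam_like",
    search_kind = "covariance")
  tbl <- paste(
    "#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description",
    "rna1 RF00001 plas - cm 1 100 201 300 + no 1 0.5 0.0 85.2 1.2e-18 ! toy RNA",
    "rna1 RF00001 plas - cm 1 100 450 351 - no 1 0.5 0.0 42.0 2e-05 ! toy RNA",
    sep = "\n")
  h <- parse_tabular_hits(tbl, lib)
  expect_equal(nrow(h), 2)
  expect_equal(h$q_start, c(200L, 350L))
  expect_equal(h$q_end, c(300L, 450L))
  expect_equal(h$strand, c(1L, -1L))
  expect_equal(h$identity, c(100, 100))
  expect_equal(h$subject_cov, c(1, 1))
  expect_equal(h$evalue, c(1.2e-18, 2e-05))
  # covariance priority equals the hit length
  scored <- compute_priority_score(localize_hits(h, 1000, "linear"))
  expect_equal(scored$priority, c(100, 100))
})

test_that("cutoffs are boundary-exact and preserve order", {
  lib <- feature_library(
    tibble::tibble(entry_id = "f1", name = "f1", type_key = "misc_feature",
                   description = "", sequence = strrep("ACGT", 25)), "t")
  hits <- tibble::tibble(
    entry_id = "f1", library_tag = "t", search_kind = "nucleotide",
    q_start = c(0L, 10L, 20L, 30L), q_end = c(100L, 110L, 120L, 130L),
    strand = 1L,
    identity = c(97.9, 98.0, 99.5, 100),
    align_length_nt = 100L, subject_cov = 1,
    evalue = c(0.5, 0.5, 2.0, 1.0), spans_origin = FALSE)
  kept <- apply_cutoffs(hits, lib)
  expect_equal(kept$q_start, c(10L, 30L))  # 97.9 < 98 dropped; E 2.0 > 1 dropped
  expect_lte(nrow(kept), nrow(hits))

  sp <- feature_library(
    tibble::tibble(entry_id = "p1", name = "p1", type_key = "CDS",
                   description = "", sequence = strrep("MKTAYIAKQR", 4)),
    "swissprot_like", alphabet = "protein")
  hit <- hits[1, ]
  hit$identity <- 12.0
  hit$evalue <- 1e-5
  expect_equal(nrow(apply_cutoffs(hit, sp)), 1)
})

test_that("localization discards second-copy hits and wraps boundary hits", {
  base <- tibble::tibble(
    entry_id = "f1", library_tag = "t", search_kind = "nucleotide",
    strand = 1L, identity = 100, align_length_nt = 100L, subject_cov = 1,
    evalue = 1e-9, spans_origin = FALSE)
  h <- dplyr::bind_rows(
    dplyr::mutate(base, q_start = 1200L, q_end = 1300L),
    dplyr::mutate(base, q_start = 950L, q_end = 1050L),
    dplyr::mutate(base, q_start = 0L, q_end = 100L),
    dplyr::mutate(base, q_start = 1000L, q_end = 1100L))
  out <- localize_hits(h, 1000L, "circular")
  expect_equal(nrow(out), 2)  # both second-copy hits discarded
  wrap <- out[out$spans_origin, ]
  expect_equal(wrap$start, 950L)
  expect_equal(wrap$end, 50L)
  plain <- out[!out$spans_origin, ]
  expect_equal(plain$start, 0L)
  expect_equal(plain$end, 100L)
  # linear topology passes hits through unchanged
  lin <- localize_hits(h, 1000L, "linear")
  expect_equal(nrow(lin), 4)
  expect_equal(lin$start, h$q_start)
})

test_that("each planted feature survives localization exactly once", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      lib <- generate_toy_library(3, seed = rep * 7)
      toy <- plant_features(lib, toy_layout(lib$entries$entry_id),
                            seed = rep * 13)
      ws <- prepare_working_sequence(toy$record)
      raw <- search_library(ws$working, lib)
      cut <- apply_cutoffs(raw, lib)
      loc <- localize_hits(cut, ws$plasmid_length, "circular")
      # the doubled sequence yields two images per feature, one localized
      expect_equal(nrow(cut), 2 * nrow(toy$truth))
      expect_equal(nrow(loc), nrow(toy$truth))
      expect_setequal(loc$start, toy$truth$start)
    }
  })
})

test_that("cutoff order relative to localization does not matter", {
  for (seed in c(3, 14)) {
    lib <- generate_toy_library(4, seed = seed)
    toy <- plant_features(lib, toy_layout(lib$entries$entry_id[1:3],
                                          truncation_frac = c(1, 0.7, 1)),
                          seed = seed + 50, wrap_last = TRUE)
    ws <- prepare_working_sequence(toy$record)
    raw <- search_library(ws$working, lib)
    a <- localize_hits(apply_cutoffs(raw, lib), ws$plasmid_length, "circular")
    b <- apply_cutoffs(localize_hits(raw, ws$plasmid_length, "circular"), lib)
    expect_equal(dplyr::arrange(a, start, entry_id),
                 dplyr::arrange(b, start, entry_id))
  }
})

test_that("the external blastn backend agrees with the internal one", {
  lib <- generate_toy_library(3, seed = 7)
  toy <- plant_features(lib, toy_layout(lib$entries$entry_id,
                                        strand = c(1, -1, 1)), seed = 2)
  ws <- prepare_working_sequence(toy$record)
  internal <- localize_hits(
    apply_cutoffs(search_library(ws$working, lib), lib),
    ws$plasmid_length, "circular")
  external <- localize_hits(
    apply_cutoffs(search_library(ws$working, lib, search_backend("external")),
                  lib),
    ws$plasmid_length, "circular")
  key <- function(h) dplyr::arrange(
    dplyr::select(h, entry_id, start, end, strand, identity, subject_cov),
    entry_id)
  expect_equal(key(internal), key(external))
})

test_that("covariance libraries reject the internal backend", {
  lib <- feature_library(
    tibble::tibble(entry_id = "r1", name = "r1", type_key = "ncRNA",
                   description = "", sequence = strrep("ACGT", 10)), "rfam_like",
    search_kind = "covariance")
  expect_error(search_library("ACGTACGT", lib), "external or precomputed")
})
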