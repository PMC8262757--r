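# plasmidann

Feature annotation for engineered plasmids, in R.

Engineered plasmids are mosaics of reused parts: promoters, origins of
replication, resistance genes, fluorescent proteins — and *fragments* of
all of these, left behind by decades of cloning. Generic genome
annotation pipelines miss engineered parts, and raw homology search
drowns the user in dozens of overlapping, near-identical matches.
`plasmidann` annotates a single plasmid (or other construct) against
nucleotide and protein feature libraries and reports only the most
informative matches, including incomplete ones, for researchers who need
to know exactly what is on their construct.

## The method

For a plasmid of length *L*:

* **Circular handling.** The sequence is doubled before searching so a
  feature crossing the arbitrary linearization point is found as one
  contiguous match. Hits entirely inside the second copy are discarded;
  hits crossing the copy boundary get wrapped coordinates and are
  written as GenBank `join(a..L,1..b)` locations. Linear mode skips the
  doubling.
* **Priority score.** Every hit is scored as

  *s* = (match length, nt) × (percent identity / 100) × (fraction of the
  library feature covered),

  which favours long, near-perfect, complete matches where E-values or
  bit scores would rank a short perfect hit above the intended
  full-length feature. Covariance-model (ncRNA) hits have the identity
  and coverage terms fixed at 1, so their score equals their match
  length.
* **Trimmed-core overlap filter.** Hits are scanned in descending score
  order; a hit is kept iff its interval avoids the *core* of every
  already-kept hit — the winner's interval trimmed by 15% of its length
  on each side. The flanks tolerate genuinely overlapping features
  (e.g. *repA*/*repC* in the RSF1010 origin) while suppressing redundant
  variants of the same part.
* **Fragment flagging.** After filtering, hits covering less than 95% of
  their library feature are flagged as possible feature fragments — the
  cryptic relics the tool exists to surface.
* **Per-library cutoffs.** Nucleotide libraries: E ≤ 1, identity ≥ 98%.
  Translated (protein) libraries: E ≤ 0.001, identity ≥ 98%, or ≥ 10%
  for broad curated collections (`swissprot`-tagged). Covariance: E ≤ 1.

Search backends: a built-in iterated Smith–Waterman backend
(Biostrings; exhaustive at desk scale, six-frame translated search with
PAM30 for protein libraries), external BLAST+ (`blastn` / `blastx`), or
precomputed tabular hit files (BLAST `-outfmt 6` + `slen`, or `cmscan
--tblout` for covariance libraries).

A deterministic synthetic fixture generator (`generate_toy_library()`,
`plant_features()`) builds toy libraries and plasmids with exact ground
truth, so the whole pipeline is testable without downloading any real
database.

## Worked example

The package bundles a small synthetic library (four parts) and a
synthetic 875-bp circular example plasmid carrying three of them — one
planted across the origin as a 55% fragment:

```r
library(plasmidann)

lib <- load_library(system.file("extdata", "toylib", package = "plasmidann"))
rec <- read_sequence_input(system.file("extdata", "synthetic_example.fa",
                                       package = "plasmidann"))
report <- annotate(rec, lib)
#> [toylib] 11 raw -> 7 post-cutoff -> 3 localized hits
#> filter kept 3 of 3 pooled hits (1 fragment)
report
#> <annotation_report> synthetic_example (circular, 875 bp): 3 feature(s), 1 fragment(s)
#> # A tibble: 3 x 9
#>   name  start   end strand library_tag identity subject_cov priority is_fragment
#>   <chr> <int> <int>  <int> <chr>          <dbl>       <dbl>    <dbl> <lgl>
#> 1 orfB    483   685      1 toylib           100       1        202   FALSE
#> 2 promA   236   399      1 toylib           100       1        163   FALSE
#> 3 termD   793    83     -1 toylib           100       0.552     91.1 TRUE
```

Reading the table: `orfB` and `promA` are complete, perfect matches
(priority = their lengths, 202 and 163). `termD` was planted on the
minus strand across the origin (`start` 793 > `end` 83: the feature
wraps) covering only 55.2% of the library part, so it is flagged as a
fragment; its priority 91.1 = 165 × 1.00 × 0.552. `tidy(report)` returns
the hit tibble, `glance(report)` a one-row summary (here: fragment
occupancy 0.189 — 18.9% of plasmid bases lie under fragment
annotations), `autoplot(report)` a feature map, and `write_genbank()`,
`write_report_csv()`, `write_report_bed()`, `merge_annotations()` the
standard outputs.

The same run from the shell:

```sh
Rscript inst/scripts/plasmidann-annotate \
  --input inst/extdata/synthetic_example.fa \
  --libs inst/extdata/toylib \
  --out out.gbk --csv out.csv
```

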