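---
title: "Annotating engineered plasmids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating engineered plasmids: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidann)
```

## The problem

Engineered plasmids accumulate sequence by decades of cut-and-paste
cloning. Their maps are chronically incomplete: backbones carry promoters,
origins, and resistance genes nobody wrote down, plus *fragments* of
genes — relics of old junctions — that can still be transcribed or
translated with unintended consequences. Annotating a plasmid therefore
means more than finding best BLAST hits: among dozens of overlapping
matches to closely related parts, the most informative one must be chosen,
and incomplete matches must be surfaced rather than discarded.

`plasmidann` implements that annotation engine as a library plus a small
command line tool: homology search of one plasmid against user-supplied
feature libraries, circular-topology handling, a bespoke priority score, a
trimmed-interval greedy overlap filter, and fragment flagging, with
GenBank/CSV/BED output.

## The pipeline

For a record $P$ of length $L$ and libraries $\mathcal{D}_1 \ldots
\mathcal{D}_m$:

1. **Validate** — the sequence must be IUPAC DNA (`A,C,G,T` plus ambiguity
   codes; `U` is rejected because the accepted alphabet is DNA), at most
   50,000 bases by default; input files at most 1 MiB. Both limits are
   configuration, not hard-code (`pipeline_config()`).
2. **Double** — circular sequences are searched as $PP$ (length $2L$) so
   a feature crossing the arbitrary linearization point appears as one
   contiguous match. Linear records are searched as-is.
3. **Search** — each library is searched with a backend suited to its
   kind: nucleotide libraries by nucleotide alignment, protein libraries
   by six-frame translated alignment (robust to codon optimization and
   silent edits), and covariance-model (ncRNA) libraries by an external
   `cmscan` run or a precomputed hit table.
4. **Cutoffs** — per-library E-value and percent-identity cutoffs,
   defaulting to the published per-database configuration: nucleotide
   $E \le 1$, identity $\ge 98\%$; translated $E \le 0.001$, identity
   $\ge 98\%$ (or $\ge 10\%$ for broad curated-protein collections);
   covariance $E \le 1$, no identity cutoff.
5. **Localize** — hits lying entirely in the second copy
   ($q_{start} \ge L$) are images of first-copy hits and are discarded;
   hits crossing the copy boundary get wrapped coordinates
   (`spans_origin`); partial images of an origin-spanning hit that
   reappear at the copy boundary (same entry, same strand, circular
   interval contained in the longer hit) are likewise discarded; anything
   longer than one full turn is truncated to length $L$.
6. **Score** — each hit receives the priority
   $$s = \ell \cdot \frac{\mathrm{id}}{100} \cdot c,$$
   where $\ell$ is the match length in nucleotides (residue columns
   $\times 3$ for translated hits), $\mathrm{id}$ the percent identity,
   and $c$ the fraction of the library feature's length covered by the
   aligned subject span (capped at 1). This favours long, near-perfect,
   *complete* matches where raw E-values or bit scores would prefer a
   short perfect hit over the intended full-length feature.
7. **Filter** — hits are sorted by descending $s$ and scanned greedily. A
   hit is kept iff its full interval avoids the *trimmed core* of every
   already-kept hit: the winner's interval shrunk by
   $\lfloor 0.15\,\ell \rfloor$ bases on each side. The 15% flanks allow
   genuinely overlapping features (e.g. the *repA*/*repC* genes of the
   RSF1010 origin) to coexist while redundant variants of the same part
   are suppressed.
8. **Flag** — after filtering, hits with coverage $c < 0.95$ are marked
   as possible feature fragments.
9. **Report** — kept hits with metadata, the display score
   $c \cdot \mathrm{id}$ (a percentage), the configuration snapshot, and
   a library manifest; writable as GenBank (origin-spanning features as
   `join()` locations), CSV, or BED6, and mergeable into the input
   GenBank file with a `generated_by` qualifier separating predictions
   from pre-existing annotations.

### Score override for covariance hits

Covariance-model hits are detected by a model score threshold, not by
alignment to a concrete library sequence, so "identity" and "coverage"
have no direct meaning. Both terms are fixed at 1, making the priority
equal the match length in nucleotides — the same scale a perfect,
complete nucleotide hit of the same span would attain. A literal
constant score (e.g. "100%") would carry no length information and could
not rank against the three-term product; the length-bearing override is
the only interpretation that keeps covariance hits competitive on one
scale. Their display score renders as 100.

### Ambiguities resolved in the filter

Three choices in the overlap filter were genuinely open and are fixed as
follows:

* *Whose length is trimmed?* The **winner's**: the region covered by a
  higher-scoring match is trimmed by 15% of its own length on each side,
  and the lower-scoring hit is dropped only if it touches that core. The
  loser's interval is used **in full** (not trimmed).
* *Ties.* Scores can tie exactly (two identical-length perfect hits).
  The deterministic tie-break is: longer alignment first, then smaller
  start, then library tag, then entry id (byte order). Reproducibility
  requires some rule; this one prefers the more informative hit.
* *Circular intersection.* Intervals are compared on the circle by
  testing the loser's unwrapped interval against the winner's core and
  its images shifted by $\pm L$ — correct without a special-case
  geometry type.

The filter is applied **globally** across all libraries pooled, not per
library: overlap conflicts between, say, a nucleotide part and a protein
match must be resolved against each other.

## Backends

The **internal backend** finds local alignments by iterated
Smith–Waterman: `Biostrings::pairwiseAlignment()` computes the optimal
local alignment, its footprint on the working sequence is masked with a
character that scores $-1000$ against everything, and the alignment is
repeated until the score falls below the reporting floor. This recovers
*every* non-overlapping occurrence of an entry (including the second-copy
image produced by doubling) without heuristic seeding, and in particular
every exact occurrence with identity 100 and coverage 1. `min_anchor`
(11 nucleotide columns / 4 residue columns) is the minimum alignment
length reported.

Scoring is match $+2$ / mismatch $-3$ with affine gaps (open 10,
extend 2); translated mode uses PAM30 (open 10, extend 1), the matrix
choice suited to detecting near-identical protein matches. The raised
nucleotide gap-open penalty (BLASTN uses 5 for these rewards) reflects
the engine's target of $\ge 98\%$-identity, substitution-dominated
matches; single-base indel tolerance is retained but chance extensions
across feature boundaries become unprofitable. Internal E-values are a
rough Karlin–Altschul approximation ($\lambda = 0.625$, $K = 0.41$ for
DNA) used **only** against the per-library cutoff, never for ranking —
ranking is the priority score's job.

The **external backend** shells out to BLAST+ (`blastn -task blastn
-word_size 11`, or `blastx -matrix PAM30` for translated searches) and
parses the 13-column tabular output (`outfmt 6` plus `slen`); the
**precomputed backend** parses the same table, or a `cmscan --tblout`
per-target table for covariance libraries, from a file. Inverted
coordinate pairs (query or subject) signal the minus strand.

## The synthetic fixture generator

Because the real feature databases are large, licensed, or both, the
package ships a generator of toy libraries and plasmids with exact ground
truth, used by every end-to-end test:

* **Libraries** are uniform-random sequences, rejection-sampled so that
  no two entries — nor an entry and any reverse complement, nor an entry
  and its own reverse complement — share an exact 11-base run. Any
  spurious alignment able to pass the default cutoffs (identity
  $\ge 98\%$ with $E \le 1$) must contain an exact run of at least 11
  bases, so the screen guarantees that only planted copies can be
  recovered. No pair of entries shares a 30-base substring *a fortiori*.
* **Plasmids** concatenate (optionally truncated, reverse-complemented,
  point-mutated) copies of entries with random spacers (40–120 bases by
  default). Spacer DNA is screened against the library k-mer set,
  including windows across junctions and the circular origin.
* **Truncation** keeps the head or tail $\lceil f \cdot \ell \rceil$
  bases of a feature (so recovered coverage is never below the nominal
  fraction), emulating cloning relics; at least 20 bases are kept. The
  15 spacer bases flanking a truncation junction are constrained to
  mismatch the feature's continuation on the diagonal and both adjacent
  diagonals, so the local alignment provably ends exactly at the planted
  boundary.
* **Mutations** are substitutions only (exactly
  $\lfloor \ell \cdot \mathrm{rate} \rfloor$ positions, sampled without
  replacement), keeping truth intervals exact. An indel mode is
  deliberately absent from the defaults for the same reason.
* Everything is deterministic by seed; regenerating reproduces byte-identical
  output.

What the generator does **not** emulate: realistic base composition,
repeated backbones shared between plasmids, homologous part families with
97–99% mutual identity, or covariance-model statistics. Passing the
recovery suites therefore demonstrates the correctness of the coordinate
arithmetic, scoring, filtering, and flagging — not retrieval performance
on real, repetitive plasmid sequence.

## Numerical and edge-case choices

* Internal coordinates are 0-based half-open with strand $\pm 1$; GenBank
  output is 1-based inclusive. Origin-spanning features use the wrap
  convention `end <= start` with `spans_origin = TRUE` and are written as
  two-segment `join()` locations.
* Trimming uses `floor()` to whole bases — deterministic and
  conservative (cores stay slightly larger, filtering slightly
  stronger). A trim that would empty an interval keeps the single
  central base.
* Hits starting exactly at position $L$ are second-copy images (their
  first-copy twin starts at 0) and are discarded.
* Subject coverage is capped at 1 when gapped alignments make the
  aligned span exceed the feature length.
* A raw-text or FASTA input defaults to circular topology; a GenBank
  LOCUS topology word overrides the default; an explicit argument or CLI
  flag overrides both.
* Deduplication of library entries is exact string identity after
  uppercasing; reverse complements are *not* duplicates (collapsing
  them would silently merge distinct part records). Within a duplicate
  group the first entry survives.
* The Swiss-Prot-style annotation-score filter keeps entries with score
  $\ge 3$ and entries carrying no score at all — it targets libraries
  that have the field.
* Cutoffs are applied before localization; the two orders provably give
  the same surviving set (both predicates are per-hit), and the test
  suite asserts it on randomized inputs.

## Problem sizes used by the test and acceptance suites

The shipped suites run on desk-scale instances chosen to exercise every
code path while remaining quick: toy libraries of 3–5 entries of 150–400
bases, plasmids of roughly 0.7–1.5 kb, 100 seeded recovery instances, 50
rotation/wrap instances, 500 filter-oracle instances of up to 8 hits,
and 200 aligner-oracle instances with working sequences up to 200 bases.
The acceptance script (`scripts/acceptance.R`) re-runs the boundary
sweeps and a 50-plasmid synthetic fragment-prevalence batch from a single
seed and writes the resulting numbers as JSON.

## Known limitations

* The internal backend is exhaustive but quadratic; it is meant for
  desk-scale libraries (hundreds of entries), not half a million
  proteins. Point large libraries at the external BLAST+ backend.
* Covariance-model search is never reimplemented: without an external
  `cmscan` or a precomputed table, covariance libraries cannot be
  searched.
* Frameshifted protein fragments are reported per reading frame; the
  translated backend does not stitch frameshifted pieces into one hit.
* A hit table merged from a GenBank `join()` with more than two segments
  is represented by its bounding span on re-parse.
* The multi-record case (one file, several plasmids) is out of scope by
  design; one record per run.
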