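---
title: "Quantifying paused Pol II stability from stop-base profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paused Pol II stability from stop-base profiles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausenexus)
```

This vignette documents the models behind `pausenexus`, the parameters that
matter, and the design decisions taken where more than one reasonable choice
existed. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement model

ChIP-nexus reads report the boundaries of a protein–DNA footprint: after
lambda-exonuclease digestion, the 5′ end of each read is the base at which
the exonuclease stopped. For paused Pol II this produces two strand-separated
peaks straddling the pause site. The package's unit of data is therefore the
**stop-base profile**: per-position counts of read 5′ ends, kept separate by
strand (`build_profile()`), after two filters taken in this order:

* only uniquely aligned reads on the reference of interest
  (`filter_unique()`) — multi-mapping reads cannot be assigned a stop base;
* one read per (reference, position, strand, barcode) key (`dedup_reads()`)
  — reads sharing all four are PCR re-amplifications of one ligation event.
  The first occurrence is kept; selection among exact duplicates carries no
  information.

Profiles are normalized to reads per million using the **genome-aligned**
unique read count, not the plasmid count. Plasmid read counts depend on
transfection efficiency, which varies between constructs; genome reads do
not, and control/treated libraries from one transfection pool share a
plasmid:genome ratio. Dividing by genome reads therefore makes the treated /
control comparison independent of both depth and transfection efficiency —
a property the suite checks to 1e-12 on the deterministic part.

## Pausing stability and the decay law

Triptolide blocks transcription initiation, so no new Pol II reaches the
pause site and the remaining pause signal decays. Assuming first-order decay
with half-life $h$, the retained fraction after $t$ minutes is
$R = 2^{-t/h}$. The pipeline measures $R$ as the ratio of total Pol II
signal (`window_signal()`, both strands summed over a 301-bp window centred
on the TSS) between the treated and control library, and inverts to
$h = -t \ln 2 / \ln R$ (`estimate_halflife()`).

Numerical and reporting choices:

* **Window centre.** The TSS is the only landmark shared by all constructs,
  so the window is centred there; width defaults to 301 bp (odd, so the
  centre is a base). The window is clipped at reference edges.
* **Censoring.** As $R \to 1$ the inversion diverges; $R \ge 1$ (possible
  through noise) is reported as a right-censored half-life with an explicit
  bound of $5t$ and `censored = TRUE`, rather than a spuriously precise
  large number. $R \le 0$ is an error.
* **Retention above 1 is allowed** at the ratio level; censoring is applied
  only at inversion, so ratios remain honest inputs to replicate averaging.
* **Replicates.** `relative_stability()` forms the mutant/wild-type ratio
  per replicate pair (pairing by position in the vectors when lengths match,
  mean-of-wild-type denominator otherwise), then reports the mean and its
  standard error. Per-pair ratios make the SEM well defined; whether one
  should instead pool replicate reads first is not decidable from the
  measurement model, and the per-pair choice keeps replicate-to-replicate
  variation visible.
* **Known bias.** Normalizing both libraries to equal genome RPM ignores the
  genome-wide reduction of Pol II occupancy under triptolide, so retention
  ratios mildly underestimate the true change. No correction is applied;
  because the loss is shared across constructs, relative comparisons are
  preserved.
* **Initiation signal in the window.** The 301-bp window contains the
  initiation peak as well as the pause peak. Triptolide removes initiation
  signal entirely, so windowed retention underestimates pause retention at
  promoters with substantial initiation signal, and the back-calculated
  half-life is a conservative lower bound. Decay-recovery tests therefore
  simulate pause-only libraries when checking the closed form.

## Core promoter element annotation

Elements are called by positional IUPAC consensus matching
(`iupac_mismatches()`, `scan_element()`, `annotate_promoter()`), with at most
one mismatch, inside canonical windows:

| element | consensus | window (biological) |
|---|---|---|
| TATA box | `STATAWAWR` | fully inside −40..−20 |
| initiator | `TCAKTY` (A at +1) | anchored at −2..+4, no wiggle |
| pausing elements | `CSARCSSA`, `KCGGTTSK`, `KCGRWCG` | fully inside +15..+40 |

Biological coordinates have no zero: −1 directly precedes +1, and the +1
base is the TSS. All public windows are biological; internal sequence
offsets are 0-based, converted by `bio_to_offset()` / `offset_to_bio()`.

Decisions worth recording:

* The TATA window −40..−20 (the span used to define promoter classes) is
  reused for every analysis, rather than maintaining per-figure windows; a
  single consistent rule is easier to reason about, and the window is
  configurable (`default_config()`).
* The pausing-element window default +15..+40 brackets the "about 30 bp
  downstream" placement of DPE/MTE/pause-button motifs; exact per-motif
  spans differ between references, so the window is configurable per run.
* The initiator is anchored: a match must sit exactly at −2..+4. The single
  allowed mismatch may fall on any position including the +1 A — degenerate
  initiators mismatching at the A are a real feature of TATA promoters.
* Ties among window matches break by fewest mismatches, then smallest
  distance to the window centre; only the best match sets the `has_*` flag.
* `N` never matches any code (an unknown base cannot support a consensus
  call); promoters with `N` inside a scanned window are annotated but
  flagged (`n_in_window`).
* Two +2 semantics are deliberately exposed: `inr_variant` requires an
  initiator match (combination analyses), while `base_plus2` is the raw base
  regardless (class-level frequency analyses, which read the genomic base).

`group_by_combination()` implements both combination models: *mutually
exclusive* (a promoter carries exactly the group's elements and no other)
and *inclusive* (others allowed). Inclusive groups always contain their
exclusive counterparts, which the suite property-tests.

## Cohort statistics

* **Medians** are plain order-statistic medians (even `n`: mean of the two
  central values). Censored half-lives, when present in an input table,
  enter at their bound and are flagged — dropping them would bias stable
  groups downward, survival-aware estimation is out of scope.
* **Wilcoxon rank-sum** is implemented with midranks; the null distribution
  is enumerated exhaustively for pooled sizes ≤ 12 (exact even under ties),
  otherwise a normal approximation with tie-corrected variance and a 0.5
  continuity correction is used. The exact branch is property-tested against
  an independent enumeration oracle, the approximate branch against
  `wilcox.test`. Identical pooled values give p = 1 by convention. No
  multiple-testing correction is applied across combination pairs; the
  stratification reports raw p-values.
* **Class definitions**: TATA class = TATA match and half-life < 30 min;
  stably paused class = no TATA match and half-life ≥ 60 min. The classes
  are disjoint by construction and deliberately leave a middle ground
  unclassified.
* **G at +2** is compared between classes with a two-sided Fisher exact test
  on the 2×2 table — exact and assumption-free, the standard choice for a
  single 2×2 comparison.
* **Position frequency matrices** count A/C/G/T per column; information
  content is $2 + \sum_b f_b \log_2 f_b$ bits against a uniform background,
  with $0 \log 0 := 0$. No small-sample correction is applied by default
  (intended uses have hundreds of sequences per column).

## What the synthetic data emulates — and what it does not

The generator (`make_promoter()`, `simulate_cohort()`,
`simulate_nexus_reads()`, `simulate_qpcr()`) reproduces the statistical
structure the analysis relies on:

* element instances planted at canonical positions with a controlled
  mismatch count, on i.i.d. background of chosen GC content (default 0.4,
  typical of Drosophila promoter-proximal sequence);
* half-lives drawn from log-normals parameterised by the median per element
  combination — defaults are the exclusive-model medians for Drosophila
  Kc167 promoters (Inr-G 44, Inr-nonG 14, pausing element 18, TATA 13,
  TATA+Inr-G 59, TATA+Inr-nonG 11 minutes) with log-scale dispersion 0.5,
  which spans roughly a 2.7-fold interquartile range, a realistic spread for
  such cohorts;
* reads with a pause peak drawn Normal(+35, 4) truncated to +30..+50 and an
  initiation peak Normal(TSS, 2); each paused molecule reports a plus-strand
  stop base 10 bp upstream or a minus-strand stop base 10 bp downstream of
  its pause position (probability 0.5 each), a simplified footprint geometry
  that makes the strand-separated peaks straddle the pause site as observed;
* triptolide decay of expected pause reads by $2^{-t/h}$ and complete loss
  of initiation reads (a transient initiation increase at short-half-life
  promoters is representable via `triptolide_init_factor` but defaults to
  0 to keep the retention statistic interpretable);
* Poisson-realised counts, paired libraries sharing one transfection pool
  with a per-library `depth_factor`, PCR duplicates re-emitting a read with
  an identical (position, strand, barcode) key at rate 0.1, and barcodes
  composed of one of four fixed 4-mers (CTGA, TGAC, GACT, ACTG) and a random
  5-mer;
* qPCR Ct tables consistent with the relative-expression equations, with a
  plasmid copy-number excess that cancels in the estimator.

For cohort simulation the background is re-drawn (rejection sampling) until
the annotation engine recovers exactly the intended element set, so planted
group membership round-trips exactly in the exclusive model; without this,
background consensus hits (~1–10% per promoter depending on the window)
would blur planted group sizes.

Deliberately **not** modelled: base-calling errors, fragment-length and
chromatin effects, position-specific exonuclease stutter, replicate batch
effects, and FASTQ-level artefacts. Passing recovery tests therefore shows
the estimators are correct for the idealised generative model, not that they
are robust to every artefact of real libraries.

One consequence of the fixed barcode design is worth knowing: the composite
barcode space holds only 4 × 4⁵ = 4096 distinct barcodes, so at high
per-position molecule counts distinct molecules collide on the dedup key and
deduplication removes real signal, nonlinearly and more severely in the
deeper (control) library. This saturation exists in real ChIP-nexus too.
Simulation-based decay checks therefore run duplicate-free libraries and
skip deduplication; analyses of heavily saturated libraries should treat
retention ratios as biased.

## Problem sizes and determinism

All simulations accept an integer seed and restore the caller's RNG state;
identical seeds give byte-identical outputs. The test suite and the
acceptance script use desk-scale sizes chosen to make Monte-Carlo error
comfortably smaller than the tolerances being checked: 10,000 random windows
for the matcher oracle, 50 paired libraries of 10⁵ pause reads for decay
recovery, cohorts of 100 promoters per group for median recovery, and
490/132 sequences for the class-composition comparison (the class sizes of
the motivating Kc167 analysis). The matcher's exhaustive degeneracy counts
(4 initiator words, 16 TATA words) are enumerated over the full 4⁶ and 4⁹
word spaces.

## Known limitations

* Single-timepoint inversion cannot distinguish decay from redistribution;
  multi-timepoint decay-curve fitting is out of scope.
* Promoters are handled in sense orientation only; reverse-strand promoters
  must be reverse-complemented upstream.
* The annotation is consensus-based by design — no PWM scoring, no de-novo
  motif discovery — matching the classification rules it implements.
* Reads enter as a validated TSV dialect; BAM ingestion is intentionally
  isolated from the core and not required by any analysis here.
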