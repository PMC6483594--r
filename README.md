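# pausenexus

RNA polymerase II accumulates 30–50 bp downstream of many promoters before
being released into productive elongation. How stable that paused state is —
seconds or an hour — is a regulatory property of the promoter itself, and it
can be measured by blocking new initiation with triptolide and watching the
paused Pol II signal decay. `pausenexus` implements the computational side of
that experiment for ChIP-nexus data on reporter plasmids and genomic
promoters, for researchers analysing Pol II pausing in Drosophila (or any
system with comparable core promoter grammar).

The package covers four stages:

1. **Stop-base profiles.** ChIP-nexus reads mark protein–DNA crosslink
   boundaries at their 5′ ends ("stop bases"). From barcoded aligned reads
   the package filters unique alignments, removes PCR duplicates sharing an
   identical (position, strand, barcode) key, builds strand-separated
   per-base profiles, and normalizes to reads per million using the
   *genome*-aligned read count, so paired libraries from one transfection
   pool are directly comparable.
2. **Pausing stability.** For a control/triptolide library pair the total
   Pol II signal in a 301-bp window around the TSS (`Total_Pol_sig`) gives a
   retention ratio `R = sig_treated / sig_control`. Under first-order decay
   `R = 2^(−t/h)`, so a single timepoint `t` back-calculates the paused Pol
   II half-life `h = −t·ln2 / ln R`; `R ≥ 1` is reported as right-censored.
   Replicate-aware normalization to a wild-type construct gives relative
   stabilities with standard errors.
3. **Core promoter elements.** Promoters are annotated by positional IUPAC
   consensus matching with at most one mismatch: TATA box (`STATAWAWR`)
   fully inside −40..−20, initiator (`TCAKTY`, A at +1) anchored at −2..+4,
   and pausing elements (`CSARCSSA`, `KCGGTTSK`, `KCGRWCG`) inside +15..+40.
   The initiator is further split by the literal base at +2 (Inr-G vs
   Inr-nonG). Promoters are grouped by element combinations (mutually
   exclusive or inclusive models), stratified by paused Pol II half-life
   with Wilcoxon rank-sum comparisons, classified into TATA (< 30 min, TATA
   present) and stably paused (≥ 60 min, no TATA) classes, and summarised as
   position frequency matrices with per-column information content.
4. **Synthetic data.** A generator plants consensus elements into background
   sequence, draws half-lives from median-parameterised log-normals, emits
   ChIP-nexus-like reads (initiation peak at the TSS, pause peak at +30..+50
   decaying as `2^(−t/h)` under triptolide, Poisson counts, PCR duplicates,
   paired libraries sharing one transfection pool) and qPCR Ct tables — all
   with ground truth, so every estimator in the package is tested by
   parameter recovery.

## Worked example

Simulate a reporter with a true pausing half-life of 45 min, run the full
read-to-stability pipeline, and annotate a promoter:

```r
library(pausenexus)

truth  <- sim_truth("dve_reporter", list(), true_halflife_min = 45, treat_min = 60)
params <- sim_read_params(n_pause_reads = 5000, n_init_reads = 1000,
                          duplicate_rate = 0.1)
control <- simulate_nexus_reads(truth, params, "control", 0, seed = 101)
treated <- simulate_nexus_reads(truth, params, "triptolide", 60, seed = 102)

prep <- function(lib) {
  reads <- dedup_reads(filter_unique(lib$reads, "reporter"))
  normalize_rpm(build_profile(reads, "reporter", 1000L), lib$genome_read_count)
}
quantify_stability(prep(control), prep(treated), tss_index = 300L, treat_min = 60)
#> Paused Pol II stability: reporter
#>   Total Pol II signal  control 5844  treated 1979
#>   retention after 60 min triptolide: 0.339
#>   estimated half-life: 38.4 min
```

The retention (0.339) sits below the pause-only closed form
`2^(−60/45) = 0.397` because the 301-bp window also contains the initiation
peak, which triptolide removes; the windowed estimate is therefore a
conservative lower bound on the pausing half-life (38.4 vs 45 min here).
Libraries simulated without initiation signal recover the closed form to
Poisson precision.

```r
ann <- annotate_promoter("pG",
  make_promoter(list(element_spec("INR", -2, force_plus2 = "G"),
                     element_spec("PAUSE", 25)), seed = 5)$sequence,
  tss_index = 100L)
ann
#> Promoter annotation: pG
#>   TATA: FALSE  Inr: TRUE (variant G)  pausing element: TRUE  +2 base: G
#>   matches:
#>    kind consensus_id start_bio mismatches matched_seq
#> 1   INR       TCAKTY        -2          0      TCAGTT
#> 2 PAUSE     CSARCSSA        25          0    CCAGCCCA
#> 3 PAUSE     CSARCSSA        20          1    CCAAACCA
```

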