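#' Map RNA 5' ends relative to the TSS
#'
#' Histograms the 5'-end positions of plus-strand (sense) reads in biological
#' coordinates around the TSS, the readout of gene-specific 5' RNA
#' sequencing: reverse-transcriptase stop bases mark where transcripts start.
#' Minus-strand reads are counted only as a QC figure. The modal start
#' position breaks ties toward +1; `frac_within_k` is the fraction of 5' ends
#' within `k` bases of the +1 base.
#'
#' @param reads data.frame of deduplicated read records.
#' @param tss_index 0-based index of the +1 base on the reference.
#' @param k half-width in bases for `frac_within_k` (default 3).
#' @return List of class `start_site_histogram`: `counts` (named by
#'   biological position), `modal_position`, `frac_within_k`, `k`,
#'   `n_minus_strand`.
#' @export
map_5prime_starts <- function(reads, tss_index, k = 3L) {
  plus <- reads[reads$strand == "+", , drop = FALSE]
  if (nrow(plus) == 0L) stop("no plus-strand reads: cannot map RNA 5' ends")
  bio <- offset_to_bio(plus$five_prime_pos, tss_index)
  tab <- table(bio)
  pos <- as.integer(names(tab))
  counts <- as.integer(tab)
  best <- which(counts == max(counts))
  modal <- pos[best][which.min(abs(pos[best] - 1L))]
  within <- abs(plus$five_prime_pos - tss_index) <= k
  structure(list(counts = stats::setNames(counts, pos),
                 modal_position = modal,
                 frac_within_k = mean(within), k = as.integer(k),
                 n_minus_strand = sum(reads$strand == "-")),
            class = "start_site_histogram")
}

#' @export
print.start_site_histogram <- function(x, ...) {
  cat(sprintf("RNA 5'-end histogram: %d ends, modal position %+d, %.1f%% within %d bp of +1\n",
              sum(x$counts), x$modal_position, 100 * x$frac_within_k, x$k))
  if (x$n_minus_strand > 0) {
    cat(sprintf("  (QC: %d antisense reads ignored)\n", x$n_minus_strand))
  }
  invisible(x)
}

#' Reporter expression relative to RpL30 from qPCR Ct values
#'
#' Implements the copy-number-normalized relative-expression computation:
#' `GFP expression = 2^(Ct(GFP DNA) - Ct(GFP cDNA))`,
#' `RpL30 expression = 2^(Ct(RpL30 DNA) - Ct(RpL30 cDNA))`, and the relative
#' expression is their ratio. Dividing the cDNA signal by the DNA signal of
#' the same amplicon cancels the plasmid:genome copy-number difference; a
#' constant shift of all four Cts (plate offset) cancels as well.
#'
#' @param ct_gfp_dna,ct_gfp_cdna,ct_rpl30_dna,ct_rpl30_cdna Ct values; or a
#'   data.frame with columns of those names as first argument (rows =
#'   replicates).
#' @return Numeric vector of relative expression values (one per replicate).
#' @export
qpcr_relative_expression <- function(ct_gfp_dna, ct_gfp_cdna = NULL,
                                     ct_rpl30_dna = NULL, ct_rpl30_cdna = NULL) {
  if (is.data.frame(ct_gfp_dna)) {
    df <- ct_gfp_dna
    return(qpcr_relative_expression(df$ct_gfp_dna, df$ct_gfp_cdna,
                                    df$ct_rpl30_dna, df$ct_rpl30_cdna))
  }
  vals <- cbind(ct_gfp_dna, ct_gfp_cdna, ct_rpl30_dna, ct_rpl30_cdna)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  gfp <- 2^(ct_gfp_dna - ct_gfp_cdna)
  rpl30 <- 2^(ct_rpl30_dna - ct_rpl30_cdna)
  gfp / rpl30
}

#' Summarise qPCR replicates
#'
#' Per-replicate relative expression plus the geometric-mean summary over
#' biological replicates (Ct arithmetic is exponential, so the geometric
#' mean is the natural average).
#'
#' @param qpcr data.frame as from [simulate_qpcr()] or read from a Ct table.
#' @return List with `per_replicate` (numeric vector) and `geometric_mean`.
#' @export
summarize_qpcr <- function(qpcr) {
  per <- qpcr_relative_expression(qpcr)
  list(per_replicate = per, geometric_mean = exp(mean(log(per))))
}
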