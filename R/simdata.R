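# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means: use the current stream (for nested calls).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Specification of one planted core promoter element
#'
#' @param kind `"TATA"`, `"INR"` or `"PAUSE"`.
#' @param planted_offset biological position of the first consensus base;
#'   must keep the element inside the canonical window of its kind
#'   (TATA -40..-20, Inr anchored at -2, pausing elements +15..+40).
#' @param consensus_id which consensus of the kind to plant (default: the
#'   kind's first consensus).
#' @param planted_mismatches 0 or 1 mismatches to introduce.
#' @param force_plus2 optional literal base forced at biological +2 when the
#'   element covers it (the Inr-G / Inr-nonG control). A forced base outside
#'   the consensus code set consumes the single allowed mismatch.
#' @return List of class `element_spec`.
#' @export
element_spec <- function(kind, planted_offset, consensus_id = NULL,
                         planted_mismatches = 0L, force_plus2 = NULL) {
  kind <- match.arg(kind, c("TATA", "INR", "PAUSE"))
  cons <- element_consensi()[[kind]]
  if (is.null(consensus_id)) consensus_id <- names(cons)[1]
  if (!consensus_id %in% names(cons)) {
    stop("unknown consensus '", consensus_id, "' for kind ", kind)
  }
  if (!planted_mismatches %in% c(0L, 1L)) {
    stop("planted_mismatches must be 0 or 1")
  }
  win <- default_config()$windows[[c(TATA = "tata", INR = "inr", PAUSE = "pause")[kind]]]
  L <- nchar(cons[[consensus_id]])
  # containment check in a zero-free coordinate frame
  tssi <- 1000L
  o <- bio_to_offset(planted_offset, tssi)
  if (o < bio_to_offset(win[1], tssi) ||
      o + L - 1L > bio_to_offset(win[2], tssi)) {
    stop(kind, " planted at ", planted_offset,
         " does not lie fully inside its canonical window [",
         win[1], ",", win[2], "]")
  }
  structure(list(kind = kind, consensus_id = consensus_id,
                 consensus = unname(cons[[consensus_id]]),
                 planted_offset = as.integer(planted_offset),
                 planted_mismatches = as.integer(planted_mismatches),
                 force_plus2 = force_plus2),
            class = "element_spec")
}

# Draw one concrete instance of an IUPAC consensus; honours a forced base at
# a given 1-based position within the word and a mismatch budget.
.instantiate_consensus <- function(consensus, mismatches = 0L,
                                   force_pos = NULL, force_base = NULL) {
  k <- strsplit(consensus, "", fixed = TRUE)[[1]]
  word <- vapply(k, function(code) {
    s <- .IUPAC_SETS[[code]]
    s[sample.int(length(s), 1L)]
  }, character(1), USE.NAMES = FALSE)
  budget <- mismatches
  if (!is.null(force_pos)) {
    if (!force_base %in% .IUPAC_SETS[[k[force_pos]]]) {
      if (budget == 0L) {
        stop("forced base ", force_base, " conflicts with consensus code ",
             k[force_pos], " and no mismatch is allowed")
      }
      budget <- budget - 1L
    }
    word[force_pos] <- force_base
  }
  if (budget > 0L) {
    cand <- setdiff(seq_along(k), force_pos)
    pos <- cand[sample.int(length(cand), 1L)]
    word[pos] <- sample(setdiff(c("A", "C", "G", "T"), .IUPAC_SETS[[k[pos]]]), 1L)
  }
  paste(word, collapse = "")
}

#' Generate one synthetic promoter with planted elements
#'
#' Draws an i.i.d. background sequence with the given GC fraction and plants
#' each requested element instance at its biological offset: a 0-mismatch
#' element matches its consensus exactly, a 1-mismatch element at exactly one
#' position. Planted windows must fit inside the sequence and must not
#' overlap.
#'
#' @param spec list of [element_spec()] objects (may be empty).
#' @param length promoter length in bases (>= 120).
#' @param tss_index 0-based index of the +1 base.
#' @param gc background GC fraction in (0, 1).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return List with `sequence` (DNA string) and `truth` (list: `elements`,
#'   `gc_background`, `tss_index`).
#' @export
make_promoter <- function(spec, length = 201L, tss_index = 100L, gc = 0.5,
                          seed = NULL) {
  if (length < 120L) stop("promoter length must be >= 120")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    occupied <- integer(0)
    for (el in spec) {
      L <- nchar(el$consensus)
      o <- bio_to_offset(el$planted_offset, tss_index)
      idx <- o + seq_len(L)  # 1-based
      if (o < 0L || max(idx) > length) {
        stop(el$kind, " window at ", el$planted_offset, " out of bounds")
      }
      if (any(idx %in% occupied)) stop("planted element windows overlap")
      occupied <- c(occupied, idx)
      force_pos <- NULL
      force_base <- NULL
      if (!is.null(el$force_plus2)) {
        plus2_idx <- bio_to_offset(2L, tss_index) + 1L
        if (plus2_idx %in% idx) {
          force_pos <- match(plus2_idx, idx)
          force_base <- toupper(el$force_plus2)
        }
      }
      word <- .instantiate_consensus(el$consensus, el$planted_mismatches,
                                     force_pos, force_base)
      bases[idx] <- strsplit(word, "", fixed = TRUE)[[1]]
    }
    list(sequence = paste(bases, collapse = ""),
         truth = list(elements = spec, gc_background = gc,
                      tss_index = tss_index))
  })
}

#' Ground truth for one simulated promoter
#'
#' Records the planted elements, the true paused Pol II half-life and the
#' retention expected after `treat_min` minutes of blocked initiation,
#' `2^(-treat_min / true_halflife_min)`.
#'
#' @param promoter_id identifier.
#' @param elements list of [element_spec()] objects.
#' @param true_halflife_min true half-life, minutes (> 0).
#' @param treat_min treatment duration used for `expected_retention`.
#' @param gc_background background GC fraction.
#' @return List of class `sim_truth`.
#' @export
sim_truth <- function(promoter_id, elements, true_halflife_min,
                      treat_min = 60, gc_background = 0.5) {
  if (!is.finite(true_halflife_min) || true_halflife_min <= 0) {
    stop("true_halflife_min must be positive")
  }
  structure(list(promoter_id = promoter_id, elements = elements,
                 true_halflife_min = true_halflife_min,
                 expected_retention = 2^(-treat_min / true_halflife_min),
                 treat_min = treat_min, gc_background = gc_background),
            class = "sim_truth")
}

#' Printed median paused Pol II half-lives per element combination
#'
#' Defaults for the cohort simulator: median half-lives in minutes for
#' promoters carrying exactly the indicated elements (mutually exclusive
#' model) in Drosophila Kc167 cells.
#' @return Named numeric vector of medians (minutes).
#' @export
default_halflife_medians <- function() {
  c("Inr-G" = 44, "Inr-nonG" = 14, "pause" = 18, "TATA" = 13,
    "TATA+Inr-G" = 59, "TATA+Inr-nonG" = 11)
}

#' Draw a paused Pol II half-life for an element combination
#'
#' Half-lives are log-normal: positive, median-parameterised
#' (`meanlog = log(median)`), with log-scale standard deviation `dispersion`.
#'
#' @param combination_label label present in `median_table`.
#' @param median_table named vector of medians, minutes.
#' @param dispersion log-scale sd (> 0; the limit 0 returns the median).
#' @param seed integer seed or `NULL`.
#' @param n number of draws.
#' @return Numeric vector of half-lives in minutes.
#' @export
sample_halflife <- function(combination_label,
                            median_table = default_halflife_medians(),
                            dispersion = 0.5, seed = NULL, n = 1L) {
  if (!combination_label %in% names(median_table)) {
    stop("no median half-life for combination '", combination_label, "'")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  med <- median_table[[combination_label]]
  if (dispersion == 0) return(rep(med, n))
  with_seed(seed, stats::rlnorm(n, meanlog = log(med), sdlog = dispersion))
}

#' Parameters of the ChIP-nexus read simulator
#'
#' Defaults describe one reporter library: an initiation peak at the TSS and
#' a paused-Pol II peak at +30..+50 (centre +35). Each paused molecule's
#' exonuclease footprint reports a plus-strand stop base 10 bp upstream or a
#' minus-strand stop base 10 bp downstream of the pause position, so the
#' strand-separated peaks straddle the pause site. PCR duplicates re-emit a
#' read with an identical (position, strand, barcode) key. `depth_factor`
#' perturbs the sequencing depth of one library, jointly scaling plasmid and
#' genome reads, to exercise the normalization.
#'
#' @param n_pause_reads expected paused-Pol II read count under control.
#' @param n_init_reads expected initiation read count under control.
#' @param pause_center,pause_sd,pause_bounds biological centre, sd and
#'   inclusive truncation range of pause positions.
#' @param init_sd positional sd of initiation stop bases around the TSS.
#' @param footprint_halfwidth half-width of the exonuclease footprint, bases.
#' @param strand_split probability a molecule reports on the plus strand.
#' @param duplicate_rate probability a read is re-emitted as a PCR duplicate.
#' @param genome_reads expected unique genome-aligned reads per library.
#' @param depth_factor multiplicative depth perturbation of this library.
#' @param triptolide_init_factor fraction of initiation signal remaining
#'   under triptolide (default 0: initiation fully blocked).
#' @param reference,reference_length,tss_index reporter geometry: reference
#'   name, length, and 0-based TSS index.
#' @return List of class `sim_read_params`.
#' @export
sim_read_params <- function(n_pause_reads = 10000, n_init_reads = 2000,
                            pause_center = 35L, pause_sd = 4,
                            pause_bounds = c(30L, 50L), init_sd = 2,
                            footprint_halfwidth = 10L, strand_split = 0.5,
                            duplicate_rate = 0.1, genome_reads = 1e6,
                            depth_factor = 1, triptolide_init_factor = 0,
                            reference = "reporter", reference_length = 1000L,
                            tss_index = 300L) {
  stopifnot(n_pause_reads >= 0, n_init_reads >= 0, genome_reads >= 0,
            strand_split >= 0, strand_split <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            depth_factor > 0,
            pause_center >= pause_bounds[1], pause_center <= pause_bounds[2])
  structure(as.list(environment()), class = "sim_read_params")
}

.BARCODE_FIXED <- c("CTGA", "TGAC", "GACT", "ACTG")

.random_barcodes <- function(n) {
  if (n == 0L) return(character(0))
  fixed <- sample(.BARCODE_FIXED, n, replace = TRUE)
  tail5 <- do.call(paste0, replicate(5, sample(c("A", "C", "G", "T"), n,
                                               replace = TRUE),
                                     simplify = FALSE))
  paste0(fixed, tail5)
}

# Integer positions from a truncated, rounded normal (inclusive bounds, bio).
.rtruncnorm_int <- function(n, mean, sd, bounds) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(2 * (n - length(out)) + 10, mean, sd))
    x <- x[x >= bounds[1] & x <= bounds[2]]
    out <- c(out, as.integer(x))
  }
  out[seq_len(n)]
}

#' Simulate one reporter ChIP-nexus library
#'
#' Realised read counts are Poisson around the expected counts. Under
#' triptolide the expected paused-Pol II reads decay to
#' `n_pause_reads * 2^(-treat_min / true_halflife_min)` and initiation reads
#' drop to `triptolide_init_factor` of their control expectation (0 by
#' default: initiation is blocked). Pause positions are drawn from a normal
#' truncated to `pause_bounds`; each molecule emits a plus-strand stop base
#' at position - footprint_halfwidth with probability `strand_split`, else a
#' minus-strand stop base at position + footprint_halfwidth. PCR duplicates
#' are injected at `duplicate_rate` with identical (position, strand,
#' barcode).
#'
#' @param truth a [sim_truth()] object (provides `true_halflife_min`).
#' @param params a [sim_read_params()] object.
#' @param condition `"control"` or `"triptolide"`.
#' @param treat_min treatment duration, minutes (0 for control).
#' @param seed integer seed or `NULL`.
#' @return List with `reads` (data.frame of read records) and
#'   `genome_read_count` (integer).
#' @export
simulate_nexus_reads <- function(truth, params = sim_read_params(),
                                 condition = c("control", "triptolide"),
                                 treat_min = 0, seed = NULL) {
  condition <- match.arg(condition)
  if (treat_min < 0) stop("treat_min must be >= 0")
  if (condition == "control" && treat_min != 0) {
    stop("control libraries have treat_min = 0")
  }
  h <- truth$true_halflife_min
  retention <- if (condition == "triptolide") 2^(-treat_min / h) else 1
  init_scale <- if (condition == "triptolide") params$triptolide_init_factor else 1
  with_seed(seed, {
    n_pause <- stats::rpois(1, params$n_pause_reads * retention * params$depth_factor)
    n_init <- stats::rpois(1, params$n_init_reads * init_scale * params$depth_factor)

    pause_bio <- .rtruncnorm_int(n_pause, params$pause_center, params$pause_sd,
                                 params$pause_bounds)
    pause_off <- bio_to_offset(pause_bio, params$tss_index)
    plus <- stats::runif(n_pause) < params$strand_split
    pos <- ifelse(plus, pause_off - params$footprint_halfwidth,
                  pause_off + params$footprint_halfwidth)
    strand <- ifelse(plus, "+", "-")

    init_pos <- params$tss_index +
      as.integer(round(stats::rnorm(n_init, 0, params$init_sd)))
    pos <- c(pos, init_pos)
    strand <- c(strand, rep("+", n_init))
    pos <- pmin(pmax(pos, 0L), params$reference_length - 1L)

    n <- length(pos)
    reads <- data.frame(reference = rep(params$reference, n),
                        five_prime_pos = as.integer(pos), strand = strand,
                        barcode = .random_barcodes(n),
                        unique = rep(TRUE, n), stringsAsFactors = FALSE)
    if (params$duplicate_rate > 0 && n > 0) {
      dup <- stats::runif(n) < params$duplicate_rate
      reads <- rbind(reads, reads[dup, , drop = FALSE])
    }
    rownames(reads) <- NULL
    list(reads = reads,
         genome_read_count = stats::rpois(1, params$genome_reads * params$depth_factor))
  })
}

# element_spec lists for one combination label
.specs_for_label <- function(label) {
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  specs <- list()
  for (p in parts) {
    specs <- c(specs, list(switch(
      p,
      "TATA" = element_spec("TATA", planted_offset = -31L),
      "Inr-G" = element_spec("INR", planted_offset = -2L, force_plus2 = "G"),
      "Inr-nonG" = element_spec("INR", planted_offset = -2L, force_plus2 = "T"),
      "pause" = element_spec("PAUSE", planted_offset = 25L,
                             consensus_id = "CSARCSSA"),
      stop("unknown combination component '", p, "'")
    )))
  }
  specs
}

#' Simulate a promoter cohort with element-dependent half-lives
#'
#' Generates `n_per_group` promoters per combination label. Each promoter
#' carries exactly the elements of its label: background sequence is
#' re-drawn (rejection sampling) until the annotation engine recovers the
#' intended element set and nothing else, so planted group membership
#' round-trips exactly under the mutually exclusive model. Half-lives are
#' drawn per label with [sample_halflife()].
#'
#' @param n_per_group promoters per group (>= 1).
#' @param groups character vector of combination labels (names of
#'   `median_table`).
#' @param median_table,dispersion passed to [sample_halflife()].
#' @param seed integer seed or `NULL`.
#' @param length,tss_index,gc promoter geometry and background composition.
#' @param config annotation configuration used for the rejection step.
#' @return List with `sequences` (named character), `halflives` (data.frame
#'   `promoter_id`, `halflife_min`, `censored`), `truth` (data.frame
#'   `promoter_id`, `group`, `true_halflife_min`), and `tss_index`.
#' @export
simulate_cohort <- function(n_per_group, groups,
                            median_table = default_halflife_medians(),
                            dispersion = 0.5, seed = NULL,
                            length = 201L, tss_index = 100L, gc = 0.4,
                            config = default_config()) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  with_seed(seed, {
    seqs <- character(0)
    ids <- character(0)
    grp <- character(0)
    hls <- numeric(0)
    for (g in groups) {
      specs <- .specs_for_label(g)
      want <- sort(strsplit(g, "+", fixed = TRUE)[[1]])
      hl <- sample_halflife(g, median_table, dispersion, n = n_per_group)
      for (i in seq_len(n_per_group)) {
        id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", g), i)
        for (try in 1:100) {
          pr <- make_promoter(specs, length, tss_index, gc)
          ann <- annotate_promoter(id, pr$sequence, tss_index, config)
          got <- sort(.element_labels(ann$has_tata, ann$has_inr,
                                      ann$inr_variant, ann$has_pause))
          if (identical(got, want)) break
          if (try == 100) stop("could not realise combination '", g, "'")
        }
        seqs <- c(seqs, pr$sequence)
        ids <- c(ids, id)
        grp <- c(grp, g)
        hls <- c(hls, hl[i])
      }
    }
    names(seqs) <- ids
    list(sequences = seqs,
         halflives = data.frame(promoter_id = ids, halflife_min = hls,
                                censored = FALSE, stringsAsFactors = FALSE),
         truth = data.frame(promoter_id = ids, group = grp,
                            true_halflife_min = hls, stringsAsFactors = FALSE),
         tss_index = tss_index)
  })
}

#' Simulate a reporter qPCR Ct table
#'
#' Generates Ct values for GFP and RpL30 on DNA and cDNA templates such that
#' the relative-expression estimator recovers `true_relative_expression` in
#' (geometric-mean) expectation. The plasmid copy-number excess over the
#' genome shifts the GFP DNA and cDNA Cts together and cancels in the
#' estimator, emulating the copy-number normalization of the assay.
#'
#' @param true_relative_expression true reporter expression relative to
#'   RpL30 (> 0).
#' @param copy_number_ratio plasmid:genome copy ratio (> 0).
#' @param noise_sd_ct Gaussian sd added independently to each Ct value.
#' @param seed integer seed or `NULL`.
#' @param n_replicates biological replicates to emit.
#' @return data.frame with `replicate`, `ct_gfp_dna`, `ct_gfp_cdna`,
#'   `ct_rpl30_dna`, `ct_rpl30_cdna`.
#' @export
simulate_qpcr <- function(true_relative_expression, copy_number_ratio = 10,
                          noise_sd_ct = 0.2, seed = NULL, n_replicates = 3L) {
  if (true_relative_expression <= 0) stop("true_relative_expression must be > 0")
  if (copy_number_ratio <= 0) stop("copy_number_ratio must be > 0")
  if (noise_sd_ct < 0) stop("noise_sd_ct must be >= 0")
  ct_rpl30_dna <- 20
  ct_rpl30_cdna <- 18
  ct_gfp_dna <- ct_rpl30_dna - log2(copy_number_ratio)
  ct_gfp_cdna <- ct_gfp_dna -
    log2(true_relative_expression) - (ct_rpl30_dna - ct_rpl30_cdna)
  with_seed(seed, {
    jitter <- function(x) x + stats::rnorm(n_replicates, 0, noise_sd_ct)
    data.frame(replicate = seq_len(n_replicates),
               ct_gfp_dna = jitter(ct_gfp_dna),
               ct_gfp_cdna = jitter(ct_gfp_cdna),
               ct_rpl30_dna = jitter(ct_rpl30_dna),
               ct_rpl30_cdna = jitter(ct_rpl30_cdna))
  })
}
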