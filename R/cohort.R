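#' Stratify half-lives by element combination
#'
#' @param groups list of `combination_group` objects from
#'   [group_by_combination()].
#' @return data.frame with `label`, `n`, `median_min`, sorted by median
#'   descending (empty groups, with `NA` median, last).
#' @export
stratify <- function(groups) {
  if (length(groups) == 0) stop("no groups supplied")
  tab <- data.frame(
    label = vapply(groups, `[[`, character(1), "label"),
    n = vapply(groups, `[[`, integer(1), "n"),
    median_min = vapply(groups, `[[`, numeric(1), "median_min"),
    stringsAsFactors = FALSE
  )
  tab[order(-tab$median_min, na.last = TRUE), , drop = FALSE]
}

#' Wilcoxon rank-sum test (Mann-Whitney U)
#'
#' Two-sided rank-sum test with midranks for ties. For small samples
#' (`length(a) + length(b) <= exact_max`, default 12) the null distribution of
#' U is enumerated exhaustively over all assignments of the pooled midranks,
#' so the p-value is exact even under ties; otherwise a normal approximation
#' with tie-corrected variance and a 0.5 continuity correction is used. When
#' every pooled value is identical the p-value is 1 by convention.
#'
#' @param a,b numeric samples.
#' @param exact_max largest pooled size for which the exact enumeration runs.
#' @return List with `statistic` (U for sample `a`) and `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = u, p_value = 1))
  }
  mu <- m * n / 2
  if (N <= exact_max) {
    combos <- utils::combn(N, m)
    us <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(statistic = u, p_value = p))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-z)))
}

#' Define TATA and stably paused promoter classes
#'
#' A promoter is in the TATA class when it has a TATA box match and a paused
#' Pol II half-life below `tata_max_min` (default 30 min); it is in the
#' stably paused class when it lacks a TATA box and its half-life is at least
#' `stable_min_min` (default 60 min). The classes are disjoint by
#' construction and promoters may fall in neither.
#'
#' @param annotations list of `promoter_annotation` objects or an
#'   [annotation_table()] data.frame.
#' @param halflives data.frame with `promoter_id`, `halflife_min`.
#' @param tata_max_min,stable_min_min half-life thresholds in minutes.
#' @return List with `tata_class` and `stable_class`, each a character vector
#'   of promoter ids.
#' @export
define_classes <- function(annotations, halflives,
                           tata_max_min = 30, stable_min_min = 60) {
  tab <- if (is.data.frame(annotations)) annotations else annotation_table(annotations)
  tab <- merge(tab, halflives[, c("promoter_id", "halflife_min")],
               by = "promoter_id")
  list(
    tata_class = tab$promoter_id[tab$has_tata & tab$halflife_min < tata_max_min],
    stable_class = tab$promoter_id[!tab$has_tata & tab$halflife_min >= stable_min_min]
  )
}

#' Position frequency matrix with information content
#'
#' Counts A/C/G/T per position over a biological window across a set of
#' aligned promoter sequences (all anchored at their TSS). Sequences not
#' covering the window are excluded with a warning; an N base is excluded
#' from its column only. Per-column information content under a uniform
#' background is `2 + sum_b f_b log2 f_b` bits (0 log 0 := 0), the quantity a
#' sequence-logo plotter stacks.
#'
#' @param sequences character vector of promoter sequences.
#' @param tss_indices 0-based TSS index per sequence (recycled if length 1).
#' @param window_bio length-2 biological range, e.g. `c(-50, 50)` for a
#'   100-bp window around the TSS or `c(-2, 4)` for the initiator.
#' @return List of class `position_frequency_matrix`: `window_bio`,
#'   `positions_bio`, `counts` (4 x L, rows A/C/G/T), `n_sequences`,
#'   `info_content` (bits per column).
#' @export
pfm_and_logo <- function(sequences, tss_indices, window_bio) {
  if (length(tss_indices) == 1L) {
    tss_indices <- rep(tss_indices, length(sequences))
  }
  stopifnot(length(tss_indices) == length(sequences))
  pos_bio <- setdiff(seq.int(window_bio[1], window_bio[2]), 0L)
  L <- length(pos_bio)
  rows <- lapply(seq_along(sequences), function(i) {
    off <- bio_to_offset(pos_bio, tss_indices[i])
    if (min(off) < 0 || max(off) > nchar(sequences[i]) - 1L) return(NULL)
    strsplit(toupper(sequences[i]), "", fixed = TRUE)[[1]][off + 1L]
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " sequence(s) do not cover the window; excluded")
    rows <- rows[!dropped]
  }
  if (length(rows) == 0) stop("no sequence covers the requested window")
  mat <- do.call(rbind, rows)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(factor(mat[, j], levels = c("A", "C", "G", "T")), nbins = 4)
  }, integer(4))
  rownames(counts) <- c("A", "C", "G", "T")
  colnames(counts) <- pos_bio
  ic <- apply(counts, 2, function(cl) {
    tot <- sum(cl)
    if (tot == 0) return(0)
    f <- cl[cl > 0] / tot
    2 + sum(f * log2(f))
  })
  structure(list(window_bio = window_bio, positions_bio = pos_bio,
                 counts = counts, n_sequences = length(rows),
                 info_content = ic),
            class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, ...) {
  cat(sprintf("Position frequency matrix, %d sequences, window %+d..%+d\n",
              x$n_sequences, x$window_bio[1], x$window_bio[2]))
  cat(sprintf("  information content: %.2f-%.2f bits (mean %.2f)\n",
              min(x$info_content), max(x$info_content), mean(x$info_content)))
  invisible(x)
}

#' Write a PFM as a logo-plotter matrix
#'
#' Emits a TSV of per-position base frequencies (rows A/C/G/T) consumable by
#' standard logo plotters.
#'
#' @param pfm a `position_frequency_matrix`.
#' @param path output path.
#' @export
write_pfm <- function(pfm, path) {
  freq <- sweep(pfm$counts, 2, pmax(1, colSums(pfm$counts)), "/")
  utils::write.table(cbind(base = rownames(freq), as.data.frame(freq)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare G frequency at +2 between two promoter classes
#'
#' Reads the literal base at biological +2 of every sequence in each class,
#' computes the per-class proportion of G, and tests association with a
#' two-sided Fisher exact test on the 2x2 table (G / not-G by class).
#'
#' @param class_a,class_b character vectors of promoter sequences.
#' @param tss_a,tss_b 0-based TSS index per sequence (recycled if length 1).
#' @return List with `prop_a`, `prop_b`, `p_value`.
#' @export
g2_frequency_test <- function(class_a, class_b, tss_a, tss_b) {
  if (length(class_a) == 0 || length(class_b) == 0) {
    stop("both classes must be non-empty")
  }
  base_at2 <- function(seqs, tss) {
    if (length(tss) == 1L) tss <- rep(tss, length(seqs))
    off <- bio_to_offset(rep(2L, length(seqs)), tss)
    substr(toupper(seqs), off + 1L, off + 1L)
  }
  ga <- base_at2(class_a, tss_a) == "G"
  gb <- base_at2(class_b, tss_b) == "G"
  tab <- matrix(c(sum(ga), sum(!ga), sum(gb), sum(!gb)), nrow = 2)
  list(prop_a = mean(ga), prop_b = mean(gb),
       p_value = stats::fisher.test(tab)$p.value)
}
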