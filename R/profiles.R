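#' Strand-separated stop-base profile
#'
#' A `stop_base_profile` holds, for one reference sequence, the number of
#' read 5' ends (exonuclease stop bases) at every position, separately for
#' the plus and minus strand, together with normalization metadata.
#'
#' @param reference reference name.
#' @param length reference length in bases.
#' @param plus_counts,minus_counts numeric vectors of length `length`.
#' @param normalized has reads-per-million normalization been applied?
#' @param norm_factor RPM divisor used (genome_read_count / 1e6), or `NA`.
#' @param genome_read_count unique genome-aligned read count of the library.
#' @return Object of class `stop_base_profile`.
#' @export
stop_base_profile <- function(reference, length, plus_counts, minus_counts,
                              normalized = FALSE, norm_factor = NA_real_,
                              genome_read_count = NA_integer_) {
  stopifnot(base::length(plus_counts) == length,
            base::length(minus_counts) == length,
            all(plus_counts >= 0), all(minus_counts >= 0))
  if (normalized) stopifnot(is.finite(norm_factor), norm_factor > 0)
  structure(list(reference = reference, length = length,
                 plus_counts = plus_counts, minus_counts = minus_counts,
                 normalized = normalized, norm_factor = norm_factor,
                 genome_read_count = genome_read_count),
            class = "stop_base_profile")
}

#' @export
print.stop_base_profile <- function(x, ...) {
  cat(sprintf("Stop-base profile on '%s' (%d bp)\n", x$reference, x$length))
  cat(sprintf("  plus strand: %s  minus strand: %s  total: %s\n",
              format(sum(x$plus_counts)), format(sum(x$minus_counts)),
              format(sum(x$plus_counts) + sum(x$minus_counts))))
  cat(sprintf("  normalized: %s", x$normalized))
  if (x$normalized) cat(sprintf(" (RPM divisor %.6g)", x$norm_factor))
  cat("\n")
  invisible(x)
}

#' Plot a stop-base profile
#'
#' Plus-strand signal is drawn upward in red and minus-strand signal downward
#' in blue, the conventional rendering for strand-separated stop-base data.
#'
#' @param x a `stop_base_profile`.
#' @param xlim positions to show (default whole reference).
#' @param ... passed to [graphics::plot()].
#' @method plot stop_base_profile
#' @export
plot.stop_base_profile <- function(x, xlim = c(0, x$length - 1), ...) {
  pos <- seq.int(0, x$length - 1)
  sel <- pos >= xlim[1] & pos <= xlim[2]
  ylim <- range(0, x$plus_counts[sel], -x$minus_counts[sel])
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "position (0-based)",
                 ylab = "stop-base signal", main = x$reference, ...)
  graphics::segments(pos[sel], 0, pos[sel], x$plus_counts[sel], col = "red")
  graphics::segments(pos[sel], 0, pos[sel], -x$minus_counts[sel], col = "blue")
  graphics::abline(h = 0, col = "grey40")
  invisible(x)
}

#' Keep uniquely aligned reads on one reference
#'
#' @param reads data.frame of read records (see [read_reads()]).
#' @param reference reference name to retain.
#' @return Filtered data.frame, input order preserved.
#' @export
filter_unique <- function(reads, reference) {
  reads[reads$unique & reads$reference == reference, , drop = FALSE]
}

#' Remove PCR duplicates by barcode
#'
#' Reads sharing an identical (reference, 5'-end position, strand, barcode)
#' key are PCR duplicates of one ligation event; only the first occurrence is
#' kept. Reads at the same position and strand with different barcodes are
#' independent molecules and are all retained. Idempotent.
#'
#' @param reads data.frame of read records.
#' @return Deduplicated data.frame, input order preserved.
#' @export
dedup_reads <- function(reads) {
  key <- paste(reads$reference, reads$five_prime_pos, reads$strand,
               reads$barcode, sep = "\r")
  reads[!duplicated(key), , drop = FALSE]
}

#' Build a stop-base profile from reads
#'
#' Counts read 5' ends per position and strand. Reads are expected to be
#' already filtered to unique alignments on `reference` and deduplicated.
#'
#' @param reads data.frame of read records.
#' @param reference reference name stored in the profile.
#' @param length reference length; all positions must be `< length`.
#' @param genome_read_count optional library-size metadata carried along for
#'   later normalization.
#' @return A raw (unnormalized) [stop_base_profile].
#' @export
build_profile <- function(reads, reference, length,
                          genome_read_count = NA_integer_) {
  if (nrow(reads) && any(reads$five_prime_pos >= length)) {
    stop("read position >= reference length (", length, ")")
  }
  count_strand <- function(strand) {
    pos <- reads$five_prime_pos[reads$strand == strand]
    tabulate(pos + 1L, nbins = length)
  }
  stop_base_profile(reference, length,
                    plus_counts = count_strand("+"),
                    minus_counts = count_strand("-"),
                    genome_read_count = genome_read_count)
}

#' Reads-per-million normalization
#'
#' Divides every count by `genome_read_count / 1e6`. The denominator is the
#' library's unique genome-aligned read count — not the plasmid-aligned
#' count — so that paired libraries from one transfection pool become
#' directly comparable regardless of transfection efficiency.
#'
#' @param profile a raw [stop_base_profile].
#' @param genome_read_count unique genome-aligned reads of the library;
#'   defaults to the count stored in the profile.
#' @return Normalized [stop_base_profile] with `norm_factor` recorded.
#' @export
normalize_rpm <- function(profile, genome_read_count = profile$genome_read_count) {
  stopifnot(inherits(profile, "stop_base_profile"))
  if (profile$normalized) stop("profile is already normalized")
  if (!is.finite(genome_read_count) || genome_read_count <= 0) {
    stop("genome_read_count must be positive")
  }
  f <- genome_read_count / 1e6
  stop_base_profile(profile$reference, profile$length,
                    profile$plus_counts / f, profile$minus_counts / f,
                    normalized = TRUE, norm_factor = f,
                    genome_read_count = as.integer(genome_read_count))
}

#' Pearson correlation between two profiles
#'
#' Correlates the concatenated plus- and minus-strand signal of two profiles
#' inside a window of 0-based positions, the standard way to compare
#' replicate or condition profiles.
#'
#' @param a,b [stop_base_profile] objects on references of equal length.
#' @param window length-2 vector of 0-based positions (inclusive); default
#'   whole reference.
#' @return Pearson correlation in \[-1, 1\].
#' @export
profile_correlation <- function(a, b, window = c(0L, a$length - 1L)) {
  stopifnot(inherits(a, "stop_base_profile"), inherits(b, "stop_base_profile"))
  if (a$length != b$length) stop("profiles have different reference lengths")
  if (window[1] < 0 || window[2] >= a$length || window[1] > window[2]) {
    stop("window out of bounds")
  }
  i <- seq.int(window[1] + 1L, window[2] + 1L)
  va <- c(a$plus_counts[i], a$minus_counts[i])
  vb <- c(b$plus_counts[i], b$minus_counts[i])
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("degenerate profile: constant signal in window, correlation undefined")
  }
  stats::cor(va, vb)
}
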