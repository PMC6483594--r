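#' Total Pol II signal in a promoter window
#'
#' Sums the plus- and minus-strand signal of a normalized profile over an
#' odd-width window centred on a position (the reporter TSS by default
#' convention), clipped to the reference bounds. With the default width of
#' 301 bp this is the total Pol II signal statistic used for stability
#' quantification.
#'
#' @param profile a normalized [stop_base_profile].
#' @param center 0-based window centre.
#' @param width odd window width in bases (default 301).
#' @return Summed signal (numeric scalar).
#' @export
window_signal <- function(profile, center, width = 301L) {
  stopifnot(inherits(profile, "stop_base_profile"))
  if (width %% 2 == 0 || width <= 0) stop("width must be odd and positive")
  if (!profile$normalized) stop("profile must be RPM-normalized first")
  half <- (width - 1L) %/% 2L
  lo <- max(0L, center - half)
  hi <- min(profile$length - 1L, center + half)
  i <- seq.int(lo + 1L, hi + 1L)
  sum(profile$plus_counts[i]) + sum(profile$minus_counts[i])
}

#' Triptolide retention ratio
#'
#' Ratio of total Pol II signal in the triptolide-treated library over the
#' paired control library from the same transfection pool. Because both
#' libraries share one plasmid:genome ratio, the ratio of RPM-normalized
#' signals cancels transfection efficiency and sequencing depth, leaving the
#' fraction of paused Pol II retained after treatment. Values above 1 can
#' occur through noise and are returned as-is.
#'
#' @param sig_treated,sig_control total Pol II signal of the treated and
#'   control libraries (same window, both normalized).
#' @return `sig_treated / sig_control`.
#' @export
retention_ratio <- function(sig_treated, sig_control) {
  if (!is.finite(sig_control) || sig_control <= 0) {
    stop("control signal must be positive (unusable control library)")
  }
  sig_treated / sig_control
}

#' Stability of a mutant promoter relative to wild type
#'
#' Combines per-replicate retention ratios into a wild-type-relative
#' stability. When the mutant and wild-type replicate lists have equal length
#' they are treated as paired by experiment (same transfection date) and each
#' replicate contributes `mutant / wt`; otherwise every mutant replicate is
#' divided by the mean wild-type ratio. The result is the mean of the
#' per-replicate relative values with its standard error; the wild type
#' evaluated against itself gives exactly 1.
#'
#' @param mutant_ratios,wt_ratios numeric vectors of per-replicate retention
#'   ratios.
#' @return List with `relative_to_wt` and `sem` (sd / sqrt(n); 0 for n = 1).
#' @export
relative_stability <- function(mutant_ratios, wt_ratios) {
  if (length(mutant_ratios) == 0 || length(wt_ratios) == 0) {
    stop("need at least one replicate per promoter")
  }
  rel <- if (length(mutant_ratios) == length(wt_ratios)) {
    mutant_ratios / wt_ratios
  } else {
    mutant_ratios / mean(wt_ratios)
  }
  sem <- if (length(rel) > 1) stats::sd(rel) / sqrt(length(rel)) else 0
  list(relative_to_wt = mean(rel), sem = sem)
}

#' Back-calculate a paused Pol II half-life from one timepoint
#'
#' Under first-order decay the retained fraction after `treat_min` minutes of
#' blocked initiation is 2^(-t/h), so h = -t * ln 2 / ln(retention). A
#' retention at or above 1 carries no decay information and yields a
#' right-censored estimate, reported as a lower bound of `5 * treat_min` with
#' `censored = TRUE` (an explicit reporting convention: retention near 1
#' makes the half-life unbounded).
#'
#' @param retention retained signal fraction (> 0).
#' @param treat_min treatment duration in minutes (> 0).
#' @return List with `halflife_min` (minutes) and `censored` (logical).
#' @export
estimate_halflife <- function(retention, treat_min) {
  if (!is.finite(treat_min) || treat_min <= 0) stop("treat_min must be positive")
  if (!is.finite(retention) || retention <= 0) {
    stop("retention must be positive to invert the decay law")
  }
  if (retention >= 1) {
    return(list(halflife_min = 5 * treat_min, censored = TRUE))
  }
  list(halflife_min = -treat_min * log(2) / log(retention), censored = FALSE)
}

#' Full stability quantification for one construct
#'
#' Convenience wrapper: windows the control and treated profiles at the TSS,
#' forms the retention ratio and back-calculates the half-life.
#'
#' @param control,treated normalized [stop_base_profile] objects from one
#'   transfection pool.
#' @param tss_index 0-based TSS position used as the window centre.
#' @param treat_min triptolide treatment duration, minutes.
#' @param width odd signal window width (default 301).
#' @param construct_id identifier carried into the result.
#' @return Object of class `stability_result`: `construct_id`, `treat_min`,
#'   `total_sig_control`, `total_sig_treated`, `retention_ratio`,
#'   `est_halflife_min`, `censored`.
#' @export
quantify_stability <- function(control, treated, tss_index, treat_min,
                               width = 301L, construct_id = control$reference) {
  sc <- window_signal(control, tss_index, width)
  st <- window_signal(treated, tss_index, width)
  ratio <- retention_ratio(st, sc)
  hl <- estimate_halflife(ratio, treat_min)
  structure(list(construct_id = construct_id, treat_min = treat_min,
                 total_sig_control = sc, total_sig_treated = st,
                 retention_ratio = ratio,
                 est_halflife_min = hl$halflife_min, censored = hl$censored),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Paused Pol II stability:", x$construct_id, "\n")
  cat(sprintf("  Total Pol II signal  control %.4g  treated %.4g\n",
              x$total_sig_control, x$total_sig_treated))
  cat(sprintf("  retention after %g min triptolide: %.3f\n",
              x$treat_min, x$retention_ratio))
  cat(sprintf("  estimated half-life: %s%.3g min\n",
              if (x$censored) ">= " else "", x$est_halflife_min))
  invisible(x)
}
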