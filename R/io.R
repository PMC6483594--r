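#' Default pipeline configuration
#'
#' Bundles the motif definitions and numeric settings the pipeline uses:
#' consensus sequences per element kind, biological scan windows (TATA fully
#' inside -40..-20; initiator anchored at -2..+4; pausing elements fully
#' inside +15..+40), the one-mismatch allowance, the 301-bp window for total
#' Pol II signal, and the half-life thresholds defining the TATA (< 30 min)
#' and stably paused (>= 60 min) promoter classes.
#'
#' @param ... named overrides merged over the defaults (one level deep).
#' @return A list with components `motifs`, `windows`, `max_mm`,
#'   `signal_window_width`, `class_thresholds`, `treat_min`.
#' @export
default_config <- function(...) {
  cfg <- list(
    motifs = element_consensi(),
    windows = list(tata = c(-40L, -20L), inr = c(-2L, 4L), pause = c(15L, 40L)),
    max_mm = 1L,
    signal_window_width = 301L,
    class_thresholds = list(tata_max_min = 30, stable_min_min = 60),
    treat_min = 60
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  stopifnot(cfg$signal_window_width %% 2 == 1, cfg$signal_window_width > 0,
            cfg$class_thresholds$tata_max_min > 0,
            cfg$class_thresholds$stable_min_min > 0)
  cfg
}

#' Read and write pipeline configuration as YAML
#'
#' @param path file path.
#' @param config configuration list as from [default_config()].
#' @return `load_config()` returns a configuration list with defaults filled
#'   in for keys the file omits.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased; ids are the first whitespace-delimited token of
#' each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (empty for an empty file, with
#'   a warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA record at line ", nonblank[1], " of ", path,
         ": expected '>' header")
  }
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) stop("refusing to write an empty FASTA map")
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.READ_COLS <- c("reference", "five_prime_pos", "strand", "barcode", "unique")

#' Read and write aligned stop-base read tables
#'
#' The read dialect is a TSV with header columns `reference`,
#' `five_prime_pos` (0-based position of the read 5' end on the reference),
#' `strand` (`+` or `-`), `barcode`, and `unique` (logical: uniquely
#' aligned). Validation failures report the offending data row.
#'
#' @param path TSV file path.
#' @return data.frame of read records.
#' @export
read_reads <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.READ_COLS, names(df))
  if (length(missing_cols)) {
    stop("read table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, .READ_COLS]
  df$five_prime_pos <- suppressWarnings(as.integer(df$five_prime_pos))
  df$unique <- as.logical(df$unique)
  validate_reads(df)
  df
}

#' @rdname read_reads
#' @param reads data.frame of read records.
#' @export
write_reads <- function(reads, path) {
  validate_reads(reads)
  utils::write.table(reads[, .READ_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_reads
#' @export
validate_reads <- function(reads) {
  bad <- which(!(reads$strand %in% c("+", "-")))
  if (length(bad)) stop("invalid strand at row ", bad[1],
                        ": '", reads$strand[bad[1]], "' (must be + or -)")
  bad <- which(is.na(reads$five_prime_pos) | reads$five_prime_pos < 0)
  if (length(bad)) stop("invalid five_prime_pos at row ", bad[1],
                        " (must be a non-negative integer)")
  bad <- which(is.na(reads$barcode) | !nzchar(reads$barcode))
  if (length(bad)) stop("empty barcode at row ", bad[1])
  if (any(is.na(reads$unique))) {
    stop("invalid unique flag at row ", which(is.na(reads$unique))[1])
  }
  invisible(reads)
}

#' Write a strand-separated stop-base profile as bedGraph
#'
#' Plus-strand counts are written as positive values to `path_plus` and
#' minus-strand counts as negative values to `path_minus`, mirroring the
#' above/below-axis plotting convention for strand-separated stop-base
#' profiles. Intervals are 0-based half-open; runs of zeros are omitted, so an
#' all-zero profile yields empty data sections.
#'
#' @param profile a [stop_base_profile] object.
#' @param path_plus,path_minus output paths for the two strands.
#' @export
write_bedgraph <- function(profile, path_plus, path_minus) {
  stopifnot(inherits(profile, "stop_base_profile"))
  emit <- function(counts, sign, path) {
    i <- which(counts != 0)
    lines <- if (length(i)) {
      sprintf("%s\t%d\t%d\t%s", profile$reference, i - 1L, i,
              format(sign * counts[i], trim = TRUE, scientific = FALSE))
    } else character(0)
    writeLines(lines, path)
  }
  emit(profile$plus_counts, 1, path_plus)
  emit(profile$minus_counts, -1, path_minus)
  invisible(c(path_plus, path_minus))
}

#' Read a paused Pol II half-life table
#'
#' TSV with columns `promoter_id`, `halflife_min` (minutes, > 0) and an
#' optional logical `censored` column (TRUE marks a right-censored value, i.e.
#' a lower bound). Duplicate promoter ids and non-positive half-lives are
#' rejected.
#'
#' @param path TSV file path.
#' @return data.frame with `promoter_id`, `halflife_min`, `censored`.
#' @export
read_halflife_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("promoter_id", "halflife_min") %in% names(df))) {
    stop("half-life table needs columns promoter_id and halflife_min")
  }
  if (is.null(df$censored)) df$censored <- FALSE
  df$censored <- as.logical(df$censored)
  dup <- duplicated(df$promoter_id)
  if (any(dup)) stop("duplicate promoter_id: ", df$promoter_id[which(dup)[1]])
  bad <- which(!is.finite(df$halflife_min) | df$halflife_min <= 0)
  if (length(bad)) stop("non-positive half-life at row ", bad[1],
                        " (", df$promoter_id[bad[1]], ")")
  df[, c("promoter_id", "halflife_min", "censored")]
}

#' @rdname read_halflife_table
#' @param halflives data.frame with `promoter_id`, `halflife_min`, optionally
#'   `censored`.
#' @export
write_halflife_table <- function(halflives, path) {
  if (is.null(halflives$censored)) halflives$censored <- FALSE
  utils::write.table(halflives[, c("promoter_id", "halflife_min", "censored")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
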