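#' IUPAC degenerate nucleotide codes
#'
#' Base sets for the standard IUPAC nucleotide alphabet. `N` in a *query*
#' sequence never matches any code (an undetermined base cannot be scored as
#' a consensus match); `N` in a consensus matches any of A/C/G/T.
#' @keywords internal
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Count mismatches of a sequence against an IUPAC consensus
#'
#' A position matches when the sequence base is a member of the set denoted by
#' the consensus code at that position (e.g. `K` = \{G,T\}, `Y` = \{C,T\}).
#' An `N` base in the sequence never matches.
#'
#' @param seq DNA string over \{A,C,G,T,N\} (case-insensitive).
#' @param consensus IUPAC consensus string of the same length.
#' @return Integer number of mismatching positions.
#' @examples
#' iupac_mismatches("TCAGTT", "TCAKTY")  # 0
#' iupac_mismatches("TAAGTC", "TCAKTY")  # 1
#' @export
iupac_mismatches <- function(seq, consensus) {
  seq <- toupper(seq)
  consensus <- toupper(consensus)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (length(s) != length(k)) {
    stop("sequence and consensus must have equal length (",
         length(s), " vs ", length(k), ")")
  }
  bad <- setdiff(unique(s), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("invalid sequence base(s): ", paste(bad, collapse = ", "))
  if (!all(k %in% names(.IUPAC_SETS))) {
    stop("invalid IUPAC code(s) in consensus: ",
         paste(setdiff(unique(k), names(.IUPAC_SETS)), collapse = ", "))
  }
  mm <- 0L
  for (i in seq_along(s)) {
    if (s[i] == "N" || !(s[i] %in% .IUPAC_SETS[[k[i]]])) mm <- mm + 1L
  }
  mm
}

# Vectorised scanner support: per-position match matrix for a consensus over a
# character vector of single bases. Rows = consensus positions.
.iupac_match_matrix <- function(bases, consensus) {
  k <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  vapply(seq_along(k),
         function(i) bases %in% .IUPAC_SETS[[k[i]]],
         logical(length(bases)))
}
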