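#' Biological promoter coordinates
#'
#' Promoter positions are reported in the biological convention used for core
#' promoter elements: the first transcribed base is +1 and the base directly
#' upstream is -1; there is no position 0. Internally all sequences and read
#' positions are 0-based. `bio_to_offset()` and `offset_to_bio()` convert
#' between the two given `tss_index`, the 0-based index of the +1 base in the
#' sequence.
#'
#' @param pos integer vector of biological positions (no zero allowed).
#' @param offset integer vector of 0-based sequence offsets.
#' @param tss_index 0-based index of the +1 base.
#' @return `bio_to_offset()` returns 0-based offsets; `offset_to_bio()`
#'   returns biological positions.
#' @examples
#' bio_to_offset(c(-2, -1, 1, 2), tss_index = 10)
#' offset_to_bio(8:11, tss_index = 10)
#' @export
bio_to_offset <- function(pos, tss_index) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) {
    stop("biological positions have no zero (-1 directly precedes +1)")
  }
  ifelse(pos > 0L, tss_index + pos - 1L, tss_index + pos)
}

#' @rdname bio_to_offset
#' @export
offset_to_bio <- function(offset, tss_index) {
  offset <- as.integer(offset)
  ifelse(offset >= tss_index, offset - tss_index + 1L, offset - tss_index)
}

# Enumerate the 0-based start offsets at which a motif of length `len` lies
# fully inside the biological window [win[1], win[2]].
window_start_offsets <- function(win, len, tss_index) {
  stopifnot(length(win) == 2L, win[1] <= win[2])
  o1 <- bio_to_offset(win[1], tss_index)
  o2 <- bio_to_offset(win[2], tss_index)
  last <- o2 - len + 1L
  if (last < o1) return(integer(0))
  seq.int(o1, last)
}
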