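#' Core promoter element consensus sequences
#'
#' The canonical Drosophila core promoter element consensi used throughout:
#' the TATA box (STATAWAWR), the initiator (TCAKTY, with the A at +1), and
#' three downstream pausing-element motifs (CSARCSSA, KCGGTTSK, KCGRWCG;
#' DPE/MTE/pause-button family).
#'
#' @return Named list with components `TATA`, `INR`, `PAUSE`, each a named
#'   character vector of IUPAC consensi keyed by consensus id.
#' @export
element_consensi <- function() {
  list(
    TATA  = c(STATAWAWR = "STATAWAWR"),
    INR   = c(TCAKTY = "TCAKTY"),
    PAUSE = c(CSARCSSA = "CSARCSSA", KCGGTTSK = "KCGGTTSK", KCGRWCG = "KCGRWCG")
  )
}

#' Scan a promoter window for a consensus element
#'
#' Slides the consensus over every start position at which it lies fully
#' inside the biological window and keeps matches with at most `max_mm`
#' mismatches. Matches are ordered best first: fewest mismatches, then
#' smallest distance of the match start from the window centre.
#'
#' @param sequence promoter DNA string (sense strand).
#' @param tss_index 0-based index of the +1 base in `sequence`.
#' @param kind element kind label, one of `"TATA"`, `"INR"`, `"PAUSE"`.
#' @param consensus IUPAC consensus string; may be a named length-1 vector
#'   (the name is used as `consensus_id`).
#' @param window_bio length-2 biological position range; the match must lie
#'   fully inside it.
#' @param max_mm maximum mismatches allowed (default 1).
#' @param consensus_id id recorded for the consensus; defaults to the name of
#'   `consensus` or the consensus string itself.
#' @return data.frame with columns `kind`, `consensus_id`, `start_bio`,
#'   `mismatches`, `matched_seq`; zero rows when nothing matches.
#' @export
scan_element <- function(sequence, tss_index, kind, consensus, window_bio,
                         max_mm = 1L, consensus_id = NULL) {
  sequence <- toupper(sequence)
  if (is.null(consensus_id)) {
    consensus_id <- if (!is.null(names(consensus))) names(consensus)[1] else unname(consensus)
  }
  consensus <- unname(consensus)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- nchar(consensus)
  n <- length(bases)
  o1 <- bio_to_offset(window_bio[1], tss_index)
  o2 <- bio_to_offset(window_bio[2], tss_index)
  if (o1 < 0L || o2 > n - 1L) {
    stop("window [", window_bio[1], ",", window_bio[2],
         "] falls outside the sequence")
  }
  starts <- window_start_offsets(window_bio, L, tss_index)
  if (length(starts) == 0L) {
    return(.empty_matches())
  }
  mat <- .iupac_match_matrix(bases, consensus)  # n x L
  mm <- vapply(starts, function(o) {
    idx <- o + seq_len(L)  # 1-based rows
    L - sum(mat[cbind(idx, seq_len(L))])
  }, integer(1))
  keep <- mm <= max_mm
  if (!any(keep)) return(.empty_matches())
  starts <- starts[keep]
  mm <- mm[keep]
  centre <- (o1 + (o2 - L + 1L)) / 2
  ord <- order(mm, abs(starts - centre), starts)
  data.frame(
    kind = kind,
    consensus_id = consensus_id,
    start_bio = offset_to_bio(starts[ord], tss_index),
    mismatches = mm[ord],
    matched_seq = vapply(starts[ord],
                         function(o) substr(sequence, o + 1L, o + L),
                         character(1)),
    stringsAsFactors = FALSE
  )
}

.empty_matches <- function() {
  data.frame(kind = character(0), consensus_id = character(0),
             start_bio = integer(0), mismatches = integer(0),
             matched_seq = character(0), stringsAsFactors = FALSE)
}

#' Annotate a promoter with core promoter elements
#'
#' Scans one sense-strand promoter sequence for a TATA box fully inside the
#' upstream window (default biological -40..-20), an initiator anchored at
#' -2..+4 (the A of TCAKTY at +1; the single allowed mismatch may fall on any
#' position including the A), and the three pausing-element consensi inside a
#' configurable downstream window (default +15..+40). The initiator variant is
#' classified by the literal base at +2: `"G"` when an initiator match is
#' present with a G at +2, `"nonG"` when present without it, `"absent"` when
#' no initiator matched. The raw +2 base is recorded unconditionally so
#' class-level base-frequency analyses do not depend on an initiator call.
#'
#' @param promoter_id identifier carried into the annotation.
#' @param sequence promoter DNA string.
#' @param tss_index 0-based index of the +1 base.
#' @param config pipeline configuration, see [default_config()].
#' @return Object of class `promoter_annotation`: a list with
#'   `promoter_id`, `sequence`, `tss_index`, `matches` (data.frame),
#'   `has_tata`, `has_inr`, `has_pause`, `inr_variant`, `base_plus2`,
#'   `n_in_window` (TRUE when any scanned window contains an N).
#' @export
annotate_promoter <- function(promoter_id, sequence, tss_index,
                              config = default_config()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  need_lo <- bio_to_offset(config$windows$tata[1], tss_index)
  need_hi <- max(bio_to_offset(4, tss_index),
                 bio_to_offset(config$windows$pause[2], tss_index))
  if (need_lo < 0L || need_hi > n - 1L) {
    stop("sequence too short for configured scan windows (promoter ",
         promoter_id, ")")
  }
  cons <- config$motifs
  max_mm <- config$max_mm

  tata <- scan_element(sequence, tss_index, "TATA", cons$TATA[1],
                       config$windows$tata, max_mm)
  inr <- scan_element(sequence, tss_index, "INR", cons$INR[1],
                      config$windows$inr, max_mm)
  pause <- do.call(rbind, lapply(names(cons$PAUSE), function(id) {
    scan_element(sequence, tss_index, "PAUSE", cons$PAUSE[id],
                 config$windows$pause, max_mm, consensus_id = id)
  }))
  pause <- pause[order(pause$mismatches), , drop = FALSE]

  matches <- rbind(tata, inr, pause)
  rownames(matches) <- NULL

  plus2 <- substr(sequence, bio_to_offset(2, tss_index) + 1L,
                  bio_to_offset(2, tss_index) + 1L)
  has_inr <- nrow(inr) > 0L
  inr_variant <- if (!has_inr) "absent" else if (plus2 == "G") "G" else "nonG"

  win_seq <- function(win) {
    substr(sequence, bio_to_offset(win[1], tss_index) + 1L,
           bio_to_offset(win[2], tss_index) + 1L)
  }
  n_in_window <- grepl("N", paste0(win_seq(config$windows$tata),
                                   win_seq(config$windows$inr),
                                   win_seq(config$windows$pause)), fixed = TRUE)

  structure(list(
    promoter_id = promoter_id,
    sequence = sequence,
    tss_index = tss_index,
    matches = matches,
    has_tata = nrow(tata) > 0L,
    has_inr = has_inr,
    has_pause = nrow(pause) > 0L,
    inr_variant = inr_variant,
    base_plus2 = plus2,
    n_in_window = n_in_window
  ), class = "promoter_annotation")
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat("Promoter annotation:", x$promoter_id, "\n")
  cat(sprintf("  TATA: %s  Inr: %s (variant %s)  pausing element: %s  +2 base: %s\n",
              x$has_tata, x$has_inr, x$inr_variant, x$has_pause, x$base_plus2))
  if (nrow(x$matches)) {
    cat("  matches:\n")
    print(x$matches)
  }
  invisible(x)
}

#' Tabulate a list of promoter annotations
#'
#' @param annotations list of `promoter_annotation` objects.
#' @return data.frame with one row per promoter: `promoter_id`, `has_tata`,
#'   `has_inr`, `inr_variant`, `base_plus2`, `has_pause`, `n_in_window`.
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(promoter_id = a$promoter_id, has_tata = a$has_tata,
               has_inr = a$has_inr, inr_variant = a$inr_variant,
               base_plus2 = a$base_plus2, has_pause = a$has_pause,
               n_in_window = a$n_in_window, stringsAsFactors = FALSE)
  }))
}

# Element-label set carried by one annotated promoter.
.element_labels <- function(has_tata, has_inr, inr_variant, has_pause) {
  labs <- character(0)
  if (has_tata) labs <- c(labs, "TATA")
  if (has_inr && inr_variant == "G") labs <- c(labs, "Inr-G")
  if (has_inr && inr_variant == "nonG") labs <- c(labs, "Inr-nonG")
  if (has_pause) labs <- c(labs, "pause")
  labs
}

#' Group promoters by core-promoter-element combination
#'
#' Forms every singleton and pair over \{TATA, Inr-G, Inr-nonG, pause\}
#' (the Inr-G/Inr-nonG pair is impossible and omitted) and assigns promoters
#' under one of two models. In the mutually `"exclusive"` model a promoter
#' belongs to a group only when it carries exactly the group's elements and no
#' other scored element; in the `"inclusive"` model it must carry the group's
#' elements but additional elements are allowed. Every group joins the
#' promoters' paused Pol II half-lives for downstream stratification.
#'
#' @param annotations list of `promoter_annotation` objects, or a data.frame
#'   as returned by [annotation_table()].
#' @param halflives data.frame with `promoter_id` and `halflife_min`
#'   (see [read_halflife_table()]).
#' @param mode `"exclusive"` or `"inclusive"`.
#' @return List of `combination_group` lists with fields `label`, `elements`,
#'   `mode`, `member_ids`, `halflives_min`, `median_min`, `n`.
#' @export
group_by_combination <- function(annotations, halflives,
                                 mode = c("exclusive", "inclusive")) {
  mode <- match.arg(mode)
  tab <- if (is.data.frame(annotations)) annotations else annotation_table(annotations)
  tab <- merge(tab, halflives[, c("promoter_id", "halflife_min")],
               by = "promoter_id")
  labsets <- lapply(seq_len(nrow(tab)), function(i) {
    .element_labels(tab$has_tata[i], tab$has_inr[i], tab$inr_variant[i],
                    tab$has_pause[i])
  })

  universe <- c("TATA", "Inr-G", "Inr-nonG", "pause")
  singles <- lapply(universe, identity)
  pairs <- utils::combn(universe, 2, simplify = FALSE)
  pairs <- Filter(function(p) !setequal(p, c("Inr-G", "Inr-nonG")), pairs)
  combos <- c(singles, pairs)

  lapply(combos, function(el) {
    member <- vapply(labsets, function(s) {
      if (mode == "exclusive") setequal(s, el) else all(el %in% s)
    }, logical(1))
    hl <- tab$halflife_min[member]
    structure(list(
      label = paste(el, collapse = "+"),
      elements = el,
      mode = mode,
      member_ids = tab$promoter_id[member],
      halflives_min = hl,
      median_min = if (length(hl)) stats::median(hl) else NA_real_,
      n = sum(member)
    ), class = "combination_group")
  })
}
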