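#' Scoring parameters for inverted-repeat detection
#'
#' The scheme mirrors the EMBOSS einverted scoring: a flat score per
#' complementary column, a penalty per mismatched column, a linear penalty
#' per gapped column, a reporting threshold, and a cap on the total span of
#' the repeat (left-arm start to right-arm end).
#'
#' @param match score per complementary (Watson-Crick) column; default 3.
#' @param mismatch score per non-complementary column; default -4.
#' @param gap_penalty penalty subtracted per gapped column; default 12.
#' @param min_score minimum report score; default 10.
#' @param max_extent maximum repeat span in nt; default 500.
#' @param max_arm_overlap redundancy-suppression threshold: a lower-scoring
#'   repeat is discarded when either of its arms overlaps the corresponding
#'   arm of an accepted repeat by more than this fraction of its length.
#' @return A list of class `repeat_params`.
#' @export
repeat_params <- function(match = 3L, mismatch = -4L, gap_penalty = 12L,
                          min_score = 10L, max_extent = 500L,
                          max_arm_overlap = 0.5) {
  stopifnot(match > 0, mismatch < 0, gap_penalty > 0, min_score > 0,
            max_extent >= 2)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_penalty = as.integer(gap_penalty),
                 min_score = as.integer(min_score),
                 max_extent = as.integer(max_extent),
                 max_arm_overlap = max_arm_overlap),
            class = "repeat_params")
}

#' Find inverted repeats capable of forming hairpins
#'
#' Runs a banded local dynamic program between the sequence and its reverse
#' complement (self-pairing forbidden: the left arm always ends before the
#' right arm starts).  Every reported repeat satisfies
#' `score = match * n_match + mismatch * n_mismatch - gap_penalty * n_gap`,
#' spans at most `max_extent` nt, and scores at least `min_score`.  Reports
#' are non-redundant: repeats are accepted in order of decreasing score and a
#' candidate is dropped when either arm overlaps a previously accepted
#' repeat's corresponding arm by more than `max_arm_overlap`.
#'
#' @param genome a [genome_record()] (or plain nucleotide string).
#' @param params a [repeat_params()] object.
#' @return data.frame sorted by `left_start` with columns `left_start`,
#'   `left_end`, `right_start`, `right_end`, `score`, `n_match`,
#'   `n_mismatch`, `n_gap`, `loop_len`, `aln_left`, `aln_right`.  The
#'   alignment strings are gapped arm sequences, the right arm written
#'   3'->5' so that columns align.
#' @export
find_inverted_repeats <- function(genome, params = repeat_params()) {
  seq <- if (inherits(genome, "genome_record")) genome$seq else normalize_seq(genome)
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      score = integer(), n_match = integer(),
                      n_mismatch = integer(), n_gap = integer(),
                      loop_len = integer(), aln_left = character(),
                      aln_right = character(), stringsAsFactors = FALSE)
  if (nchar(seq) < 10L) {
    warning("genome shorter than 10 nt; no repeats reported")
    return(empty)
  }
  .find_inverted_repeats_cpp(seq, params$match, params$mismatch,
                             params$gap_penalty, params$min_score,
                             params$max_extent, params$max_arm_overlap)
}

#' Select hairpin candidate windows from inverted repeats
#'
#' Retains repeats whose full span (left-arm start to right-arm end) lies
#' within `span_band` and extracts the spanned sequence as the folding
#' window.  Windows with identical intervals are deduplicated.
#'
#' @param repeats data.frame from [find_inverted_repeats()].
#' @param genome the same [genome_record()] the repeats were found on.
#' @param span_band numeric length-2: minimum and maximum window length in
#'   nt.  The default (60, 150) operationalizes a ~120-nt precursor target.
#' @return data.frame with columns `start`, `end`, `length`, `seq`, and the
#'   originating repeat's `score`.
#' @export
select_windows <- function(repeats, genome, span_band = c(60L, 150L)) {
  stopifnot(inherits(genome, "genome_record"), length(span_band) == 2L)
  span <- repeats$right_end - repeats$left_start + 1L
  keep <- which(span >= span_band[1L] & span <= span_band[2L])
  out <- data.frame(start = repeats$left_start[keep],
                    end = repeats$right_end[keep],
                    length = span[keep],
                    score = repeats$score[keep],
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("start", "end")])
  out <- out[!dup, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$seq <- vapply(seq_len(nrow(out)), function(k)
    extract_interval(genome, out$start[k], out$end[k]), "")
  rownames(out) <- NULL
  out[, c("start", "end", "length", "seq", "score")]
}
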