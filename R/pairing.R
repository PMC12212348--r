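#' Insert-size model (Welford's online algorithm)
#'
#' One-pass mean/standard-deviation/variance of observed insert sizes, as
#' accumulated during alignment from the first pairs whose mates align
#' uniquely.  `sd` uses the n-1 denominator.
#'
#' @param inserts numeric vector of insert sizes (outer distances).
#' @return list(count, mean, M2, sd, var) with class `pm_insert_model`.
#' @export
insert_size_model <- function(inserts) {
  m <- cpp_welford(as.numeric(inserts))
  structure(m, class = "pm_insert_model")
}

#' @export
print.pm_insert_model <- function(x, ...) {
  cat(sprintf("insert-size model: n = %d, mean = %.2f, sd = %.2f\n",
              as.integer(x$count), x$mean, x$sd))
  invisible(x)
}

#' Single-end mapping quality
#'
#' BWA-style MAPQ:
#' `Q = min(60, 6.02 * (s1 - s2) * i / (4 * m1) - 4.343 * ln(n + 1))` with
#' the confidence term `i = 1 - (m1 * l - s1) / ((m1 + m2) * l)` clamped to
#' \[0, 1\] (4.343 is 10/ln 10, so the n term is `10 * log10(n + 1)`).  The
#' result is truncated to an integer and clamped to \[0, 60\].
#'
#' @param s1 best alignment score.
#' @param s2 second-best alignment score (0 when absent).
#' @param n number of distinct secondary scores within the fixed range of
#'   `s1` (see [count_secondary_scores()]).
#' @param read_len read length l.
#' @param scheme a [scoring_scheme()].
#' @return Integer MAPQ in \[0, 60\].
#' @export
mapq_single <- function(s1, s2, n, read_len, scheme = scoring_scheme()) {
  cpp_mapq_single(s1, s2, as.integer(n), as.integer(read_len),
                  scheme$match, scheme$mismatch)
}

#' Paired-end mapping quality of one mate
#'
#' `Qi = min(max(Q, min(Q', Q + 40)), 6.02 * (s1p - s2p) / m1)`: a mate with
#' low single-end MAPQ is elevated by a confident paired alignment, by at
#' most 40, and the result is capped by the paired score gap.  Truncated and
#' clamped to \[0, 60\].
#'
#' @param Q single-end MAPQ of the mate.
#' @param Qp paired MAPQ (the single-end formula applied to paired scores).
#' @param s1p,s2p best and second-best paired alignment scores.
#' @param scheme a [scoring_scheme()].
#' @return Integer MAPQ in \[0, 60\].
#' @export
mapq_paired <- function(Q, Qp, s1p, s2p, scheme = scoring_scheme()) {
  cpp_mapq_paired(as.integer(Q), as.integer(Qp), s1p, s2p, scheme$match)
}

#' Count distinct secondary scores near the best score
#'
#' @param scores secondary alignment scores (the best score excluded).
#' @param s1 best score.
#' @param window_fraction scores `s` with `s < s1` and
#'   `s >= window_fraction * s1` are counted (distinct values).
#' @return Integer n for the MAPQ formula.
#' @export
count_secondary_scores <- function(scores, s1, window_fraction = 0.8) {
  cpp_count_secondary(as.numeric(scores), s1, window_fraction)
}

#' Select the best mate-pair combination
#'
#' Among candidate alignments of the two mates, picks the combination on
#' the same contig, on opposite strands, whose outer distance lies within
#' mean +/- 4 sd of the insert model (a hard constraint, bounds inclusive),
#' maximising the score sum.  When no combination qualifies the read pair
#' falls back to an anchor/orphan state.
#'
#' @param cand1,cand2 data.frames with `contig`, `pos` (1-based), `span`
#'   (reference bases consumed), `strand` (0 forward / 1 reverse), `score`.
#' @param model a `pm_insert_model`.
#' @return list(i, j, s1p, s2p): 1-based row indices into the candidate
#'   frames (0 when no valid combination), and the best/second paired
#'   scores.
#' @export
pair_select <- function(cand1, cand2, model) {
  cpp_pair_select(as.integer(cand1$contig), as.integer(cand1$pos - 1L),
                  as.integer(cand1$span), as.integer(cand1$strand),
                  as.numeric(cand1$score),
                  as.integer(cand2$contig), as.integer(cand2$pos - 1L),
                  as.integer(cand2$span), as.integer(cand2$strand),
                  as.numeric(cand2$score),
                  model$mean, model$sd)
}
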