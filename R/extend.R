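#' Base-level alignment of a chained read against a target window
#'
#' Anchors contribute exact-match segments; the gaps between consecutive
#' anchors are aligned with global affine-gap dynamic programming, and the
#' flanks are extended from the outermost anchors towards the read ends,
#' soft-clipping where the extension score would go negative.  The total
#' score is the sum of the parts.
#'
#' @param read character scalar (oriented).
#' @param window character scalar, the target window the anchors refer to.
#' @param anchors data.frame with `x` (1-based read start), `y` (1-based
#'   window start), `len`; must be colinear exact matches.
#' @param scheme a [scoring_scheme()].
#' @return list(score, pos = 1-based window start of the alignment, cigar,
#'   op, len).
#' @export
fill_between_anchors <- function(read, window, anchors, scheme = scoring_scheme()) {
  stopifnot(nrow(anchors) >= 1)
  r <- cpp_fill_between(charToRaw(toupper(read)), charToRaw(toupper(window)),
                        as.integer(anchors$x - 1L), as.integer(anchors$y - 1L),
                        as.integer(anchors$len), scheme)
  list(score = r$score, pos = r$win_start + 1L,
       cigar = ops_to_cigar(r$op, r$len), op = r$op, len = r$len)
}

#' Re-score a CIGAR from scratch
#'
#' Recomputes the affine-gap score of an alignment from its CIGAR, read and
#' target window; used as a consistency check against the score reported by
#' the aligner.  `M` operations are re-classified by character comparison;
#' explicit `=`/`X` operations are verified.
#'
#' @param cigar CIGAR string (ops over M, =, X, I, D, S).
#' @param read character scalar; the window alignment must start at
#'   `window` position 1.
#' @param window character scalar.
#' @param scheme a [scoring_scheme()].
#' @return Integer score.
#' @export
score_cigar <- function(cigar, read, window, scheme = scoring_scheme()) {
  ops <- cigar_to_ops(cigar)
  if (length(ops$op) == 0) stop("empty CIGAR")
  cpp_score_cigar(ops$op, ops$len, charToRaw(toupper(read)),
                  charToRaw(toupper(window)), scheme)
}

#' Global affine-gap alignment of two sequences
#'
#' @param a,b character scalars.
#' @param scheme a [scoring_scheme()].
#' @return list(score, cigar).
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  r <- cpp_gotoh_global(charToRaw(toupper(a)), charToRaw(toupper(b)), scheme)
  list(score = r$score, cigar = ops_to_cigar(r$op, r$len))
}
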