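#' Parse a CIGAR string into operation vectors
#'
#' @param cigar CIGAR string, e.g. `"5S20M2D75M"`.
#' @return list(op = character vector, len = integer vector).
#' @export
cigar_to_ops <- function(cigar) {
  if (cigar == "*" || nchar(cigar) == 0) return(list(op = character(0), len = integer(0)))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1, nchar(toks) - 1L)))
}

#' Format operation vectors as a CIGAR string
#'
#' @param op character vector of CIGAR operators.
#' @param len integer vector of lengths.
#' @return CIGAR string.
#' @export
ops_to_cigar <- function(op, len) {
  if (length(op) == 0) return("*")
  paste0(len, op, collapse = "")
}

#' Lift a haplotype position to the reference
#'
#' Positions inside a haplotype insertion anchor to the reference position
#' the insertion is attached to.
#'
#' @param lift a `pm_liftmap`.
#' @param pos 1-based haplotype position(s).
#' @return 1-based reference position(s); NA when not covered.
#' @export
lift_position <- function(lift, pos) {
  vapply(pos, function(p) {
    r <- cpp_lift_point(lift$hs, lift$rs, lift$len, lift$kind, as.integer(p - 1L))
    if (r < 0) NA_integer_ else r + 1L
  }, integer(1))
}

#' Map a reference position back to the haplotype
#'
#' Inverse of [lift_position()] on match segments; positions inside a
#' reference stretch deleted from the haplotype return NA.
#'
#' @param lift a `pm_liftmap`.
#' @param pos 1-based reference position(s).
#' @return 1-based haplotype position(s) or NA.
#' @export
invert_lift_position <- function(lift, pos) {
  mt <- lift[lift$kind == 0L, , drop = FALSE]
  vapply(pos, function(p) {
    p0 <- p - 1L
    hit <- which(mt$rs <= p0 & p0 < mt$rs + mt$len)
    if (length(hit) == 0) NA_integer_
    else mt$hs[hit[1]] + (p0 - mt$rs[hit[1]]) + 1L
  }, integer(1))
}

#' Lift an alignment from haplotype to reference coordinates
#'
#' The CIGAR is rewritten by intersecting its operations with the lift-map
#' segments: read bases over haplotype insertions become insertions relative
#' to the reference, and reference stretches deleted from the haplotype
#' introduce deletion operations.  The alignment score is preserved.  An
#' alignment without any reference-anchored base (entirely inside a
#' haplotype insertion) is returned unchanged with `liftable = FALSE`.
#'
#' @param aln list with `pos` (1-based haplotype start), `cigar`, and
#'   optionally `score`.
#' @param lift a `pm_liftmap`.
#' @return list(liftable, pos (1-based reference start), cigar, score,
#'   contig).
#' @export
lift_alignment <- function(aln, lift) {
  ops <- cigar_to_ops(aln$cigar)
  res <- cpp_lift_ops(lift$hs, lift$rs, lift$len, lift$kind,
                      as.integer(aln$pos - 1L), ops$op, ops$len)
  if (!res$liftable) {
    return(list(liftable = FALSE, pos = aln$pos, cigar = aln$cigar,
                score = aln$score, contig = NA_character_))
  }
  list(liftable = TRUE, pos = res$ref_start + 1L,
       cigar = ops_to_cigar(res$op, res$len), score = aln$score,
       contig = attr(lift, "contig"))
}

#' Deduplicate alignments that lift to the same reference position
#'
#' Among alignments of one read, only the highest-scoring alignment is
#' retained per (contig, position, strand); ties keep the first.
#'
#' @param alns data.frame with columns `contig`, `pos`, `strand`, `score`.
#' @return The retained rows, ordered by decreasing score.
#' @export
dedup_lifted <- function(alns) {
  if (nrow(alns) == 0) return(alns)
  ord <- order(-alns$score, alns$contig, alns$pos, alns$strand)
  alns <- alns[ord, , drop = FALSE]
  key <- paste(alns$contig, alns$pos, alns$strand)
  alns[!duplicated(key), , drop = FALSE]
}
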