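#' Colinear chaining of anchors on one (haplotype, strand)
#'
#' Dynamic-programming chaining in the minimap2 style:
#' `f(j) = max(l_j, max_i f(i) + min(dy, dx, l_j) - gap(|dy - dx|))` over
#' predecessors with `x_i < x_j`, `y_i < y_j` and both gaps at most
#' `max_gap`, where `gap(d) = c1*d + c2*log2(d)` for `d > 0` and 0
#' otherwise.  Chains are extracted best-first and are anchor-disjoint.
#'
#' @param anchors data.frame with `x` (read start), `y` (target start),
#'   `len`; any coordinate base, used consistently.
#' @param cfg a [chain_config()].
#' @return list of chains: list(anchors = row indices into `anchors`,
#'   score).
#' @export
chain_anchors <- function(anchors, cfg = chain_config()) {
  if (nrow(anchors) == 0) return(list())
  r <- cpp_chain_anchors(as.integer(anchors$x), as.integer(anchors$y),
                         as.integer(anchors$len), cfg$c1, cfg$c2,
                         cfg$max_gap, 0.0, cfg$max_chains)
  lapply(seq_along(r$chains), function(i)
    list(anchors = r$chains[[i]], score = r$scores[i]))
}

#' Select the top-scoring chains
#'
#' Drops chains below `min_chain_score` and keeps the `max_chains` highest
#' scoring ones; ties are broken deterministically by (haplotype, position).
#'
#' @param chains list of chains, each carrying `score` and optionally
#'   `doc`/`y` fields used for tie-breaking.
#' @param cfg a [chain_config()].
#' @return The selected chains, ordered by decreasing score.
#' @export
select_chains <- function(chains, cfg = chain_config()) {
  if (length(chains) == 0) return(chains)
  scores <- vapply(chains, `[[`, numeric(1), "score")
  keep <- scores >= cfg$min_chain_score
  chains <- chains[keep]; scores <- scores[keep]
  if (length(chains) == 0) return(chains)
  doc <- vapply(chains, function(ch) as.integer(ch$doc %||% 0L), integer(1))
  y <- vapply(chains, function(ch) as.integer(ch$y %||% 0L), integer(1))
  ord <- order(-scores, doc, y)
  chains[ord][seq_len(min(length(chains), cfg$max_chains))]
}

#' Chain uniqueness heuristic
#'
#' In processing order, a chain is discarded iff its (score, lifted
#' reference position of the leftmost MEM) pair equals that of an earlier
#' chain; disabled chains pass through untouched.
#'
#' @param chains list of chains carrying `score` and `leftmost_lifted_pos`.
#' @param cfg a [chain_config()] (`uniqueness_filter` toggles the heuristic).
#' @return The retained chains in their original order.
#' @export
uniqueness_filter <- function(chains, cfg = chain_config()) {
  if (!cfg$uniqueness_filter || length(chains) <= 1) return(chains)
  key <- vapply(chains, function(ch)
    paste(ch$score, ch$leftmost_lifted_pos), character(1))
  chains[!duplicated(key)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
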