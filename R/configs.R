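#' Alignment scoring scheme
#'
#' Match gain and penalties used by gap-filling extension, orphan recovery
#' and the mapping-quality formulas.  A gap of length g costs
#' `gap_open + g * gap_extend`.
#'
#' @param match match score (m1), default 2.
#' @param mismatch mismatch penalty (m2, positive), default 4.
#' @param gap_open gap opening penalty, default 4.
#' @param gap_extend per-base gap extension penalty, default 2.
#' @return A list with class `pm_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = 4L, gap_open = 4L,
                           gap_extend = 2L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "pm_scheme")
}

#' MEM seeding configuration
#'
#' @param min_mem_len minimum MEM length kept as a seed (default 25 bp).
#' @param split_threshold MEMs strictly longer than this are split into two
#'   half-MEMs that are re-located independently (default 50 bp).
#' @param max_occ_per_genome per-genome cap on the occurrences kept for one
#'   MEM (default 1000); a sample's two haplotypes count as one genome.
#' @param freq_filter drop seeds that hold at least `freq_fraction` of all
#'   occurrences found for the read (default on, fraction 0.5).
#' @param freq_fraction see `freq_filter`.
#' @param orientation_filter drop the strand whose seeds are on average
#'   shorter when the strand means differ by at least `orientation_gap`
#'   (default on, gap 50 bp).
#' @param orientation_gap see `orientation_filter`.
#' @return A list with class `pm_seeding_config`.
#' @export
seeding_config <- function(min_mem_len = 25L, split_threshold = 50L,
                           max_occ_per_genome = 1000L, freq_filter = TRUE,
                           freq_fraction = 0.5, orientation_filter = TRUE,
                           orientation_gap = 50L) {
  stopifnot(min_mem_len > 0, split_threshold > 0, max_occ_per_genome > 0,
            freq_fraction > 0, orientation_gap > 0)
  structure(list(min_mem_len = as.integer(min_mem_len),
                 split_threshold = as.integer(split_threshold),
                 max_occ_per_genome = as.integer(max_occ_per_genome),
                 freq_filter = isTRUE(freq_filter),
                 freq_fraction = freq_fraction,
                 orientation_filter = isTRUE(orientation_filter),
                 orientation_gap = as.integer(orientation_gap)),
            class = "pm_seeding_config")
}

#' Colinear chaining configuration
#'
#' @param min_chain_score chains scoring below this are dropped (default 40).
#' @param max_chains number of top chains taken to full alignment (default 5).
#' @param max_gap maximum read/target gap between chained anchors (default
#'   500 bp).
#' @param uniqueness_filter discard a chain whose (score, lifted position of
#'   the leftmost MEM) equals that of an earlier chain (default on).
#' @param c1,c2 gap cost constants: `gap(d) = c1*d + c2*log2(d)` for d > 0.
#' @return A list with class `pm_chain_config`.
#' @export
chain_config <- function(min_chain_score = 40, max_chains = 5L, max_gap = 500L,
                         uniqueness_filter = TRUE, c1 = 0.12, c2 = 0.5) {
  stopifnot(min_chain_score > 0, max_chains > 0, max_gap > 0, c1 >= 0, c2 >= 0)
  structure(list(min_chain_score = min_chain_score,
                 max_chains = as.integer(max_chains),
                 max_gap = as.integer(max_gap),
                 uniqueness_filter = isTRUE(uniqueness_filter),
                 c1 = c1, c2 = c2),
            class = "pm_chain_config")
}

#' Full alignment configuration
#'
#' Bundles seeding, chaining, scoring and pairing knobs for [pm_align()].
#'
#' @param seeding a [seeding_config()].
#' @param chaining a [chain_config()].
#' @param scheme a [scoring_scheme()].
#' @param orphan_recovery rescue the unaligned mate of a pair by aligning it
#'   within mu +/- 4 sigma of its anchor (default on).
#' @param orphan_floor_frac a recovered orphan must score at least
#'   `orphan_floor_frac * match * read_length` (default 0.5).
#' @param max_insert_pairs pairs used for insert-size estimation (default
#'   1000 uniquely aligning pairs).
#' @param secondary_fraction secondary scores at or above this fraction of
#'   the best score are counted in the MAPQ `n` term (default 0.8).
#' @param emit_eqx emit `=`/`X` CIGAR operators instead of `M`.
#' @return A flat named list with class `pm_align_config`, consumed by the
#'   alignment pipeline.
#' @export
align_config <- function(seeding = seeding_config(), chaining = chain_config(),
                         scheme = scoring_scheme(), orphan_recovery = TRUE,
                         orphan_floor_frac = 0.5, max_insert_pairs = 1000L,
                         secondary_fraction = 0.8, emit_eqx = FALSE) {
  cfg <- c(unclass(seeding),
           list(min_chain_score = chaining$min_chain_score,
                max_chains = chaining$max_chains,
                max_gap = chaining$max_gap,
                uniqueness_filter = chaining$uniqueness_filter,
                chain_c1 = chaining$c1, chain_c2 = chaining$c2),
           unclass(scheme),
           list(orphan_recovery = isTRUE(orphan_recovery),
                orphan_floor_frac = orphan_floor_frac,
                max_insert_pairs = as.integer(max_insert_pairs),
                secondary_fraction = secondary_fraction,
                emit_eqx = isTRUE(emit_eqx)))
  structure(cfg, class = "pm_align_config")
}
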