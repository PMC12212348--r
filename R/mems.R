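#' Matching statistics of a read against an indexed text
#'
#' Two passes: a backward pass over the read using the r-index and
#' thresholds finds, for every read position, a text position where the
#' longest matching prefix starting there occurs; a forward pass measures
#' the lengths by direct character comparison (random access).  `N` in the
#' read never matches any text character, and read characters never match
#' text `N`.
#'
#' @param read character scalar over A/C/G/T/N (lower case tolerated).
#' @param idx a `pm_rindex`.
#' @return list(len, pos): per read position, the length of the longest
#'   prefix occurring in the text and a 0-based text position of one such
#'   occurrence (-1 where the length is 0).
#' @export
matching_statistics <- function(read, idx) {
  stopifnot(nchar(read) > 0)
  rd <- charToRaw(normalize_read_chars(read))
  cpp_matching_statistics(idx$cpp, rd)
}

normalize_read_chars <- function(read) {
  read <- toupper(read)
  gsub("[^ACGT]", "N", read)
}

#' Extract MEM starts from matching statistics
#'
#' Position i starts a MEM iff `len[i] >= min_mem_len` and the length did
#' not decrease from the previous position (`i == 1` or
#' `len[i-1] <= len[i]`), which makes the reported match left-maximal.
#'
#' @param ms matching statistics (list with `len`).
#' @param cfg a [seeding_config()].
#' @return data.frame(start, len) with 1-based read starts.
#' @export
extract_mems <- function(ms, cfg = seeding_config()) {
  r <- cpp_extract_mems(ms$len, cfg$min_mem_len)
  data.frame(start = r$start, len = r$len)
}

#' Split long MEMs into two half-MEMs
#'
#' MEMs strictly longer than `split_threshold` are replaced by two adjacent
#' halves (first ceiling(L/2), then floor(L/2)) covering the original; the
#' halves are re-located independently by [locate_seeds()].
#'
#' @param mems data.frame(start, len).
#' @param cfg a [seeding_config()].
#' @return data.frame(start, len) after splitting.
#' @export
split_long_mems <- function(mems, cfg = seeding_config()) {
  out_start <- integer(0); out_len <- integer(0)
  for (k in seq_len(nrow(mems))) {
    L <- mems$len[k]
    if (L > cfg$split_threshold) {
      h1 <- (L + 1L) %/% 2L
      out_start <- c(out_start, mems$start[k], mems$start[k] + h1)
      out_len <- c(out_len, h1, L - h1)
    } else {
      out_start <- c(out_start, mems$start[k])
      out_len <- c(out_len, L)
    }
  }
  data.frame(start = out_start, len = out_len)
}

#' Locate seed occurrences with the per-genome cap
#'
#' Occurrences are enumerated from the backward-search toehold (descending
#' row order) and converted to (document, local) coordinates; per input
#' genome at most `max_occ_per_genome` occurrences are kept, in enumeration
#' order, and the uncapped total is recorded.
#'
#' @param seeds data.frame(start, len) on one read orientation.
#' @param read the oriented read (character scalar).
#' @param idx a `pm_rindex` built over a `pm_pangenome_text`.
#' @param cfg a [seeding_config()].
#' @return A list of seed records: list(start, len, occ =
#'   data.frame(doc, local 1-based), occ_total_uncapped).
#' @export
locate_seeds <- function(seeds, read, idx, cfg = seeding_config()) {
  pt <- idx$pg
  if (is.null(pt)) stop("index has no document layout")
  read <- normalize_read_chars(read)
  genomes <- match(pt$genome_of_doc, unique(pt$genome_of_doc))
  out <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    s0 <- seeds$start[k]; L <- seeds$len[k]
    seq <- substr(read, s0, s0 + L - 1L)
    rng <- pattern_range(idx, seq)
    if (rng$lo >= rng$hi) stop("seed string absent from the index (not a MEM?)")
    gpos <- cpp_locate(idx$cpp, rng$lo, rng$hi, rng$toehold) # enumeration order
    docs <- findInterval(gpos, pt$doc_start)
    local <- gpos - pt$doc_start[docs]
    ok <- local + L <= pt$doc_len[docs]
    docs <- docs[ok]; local <- local[ok]
    gcount <- integer(max(genomes))
    keep <- logical(length(docs))
    for (i in seq_along(docs)) {
      g <- genomes[docs[i]]
      if (gcount[g] < cfg$max_occ_per_genome) {
        gcount[g] <- gcount[g] + 1L
        keep[i] <- TRUE
      }
    }
    occ <- data.frame(doc = docs[keep], local = local[keep] + 1L)
    occ <- occ[order(occ$doc, occ$local), , drop = FALSE]
    rownames(occ) <- NULL
    out[[k]] <- list(start = s0, len = L, occ = occ,
                     occ_total_uncapped = rng$hi - rng$lo)
  }
  out
}

#' MEM frequency filter
#'
#' A seed is removed iff its occurrence count is at least `freq_fraction`
#' of the total occurrence count over all the read's seeds (both strands
#' pooled).  A read with exactly one seed is left untouched.
#'
#' @param seeds list of seed records carrying `occ` data.frames.
#' @param cfg a [seeding_config()].
#' @return The surviving seeds (coordinates and occurrence lists unchanged).
#' @export
frequency_filter <- function(seeds, cfg = seeding_config()) {
  if (!cfg$freq_filter || length(seeds) <= 1) return(seeds)
  counts <- vapply(seeds, function(s) nrow(s$occ), integer(1))
  total <- sum(counts)
  if (total == 0) return(seeds)
  kept <- seeds[counts < cfg$freq_fraction * total]
  if (length(kept) == 0) seeds else kept
}

#' MEM orientation filter
#'
#' When the mean seed lengths of the two strands differ by at least
#' `orientation_gap`, the strand with the smaller mean is dropped.  A strand
#' without seeds never causes the other to be dropped.
#'
#' @param fwd,rc seed record lists for the forward and reverse-complement
#'   orientation.
#' @param cfg a [seeding_config()].
#' @return list(fwd, rc) after filtering.
#' @export
orientation_filter <- function(fwd, rc, cfg = seeding_config()) {
  if (!cfg$orientation_filter || length(fwd) == 0 || length(rc) == 0)
    return(list(fwd = fwd, rc = rc))
  mf <- mean(vapply(fwd, `[[`, numeric(1), "len"))
  mr <- mean(vapply(rc, `[[`, numeric(1), "len"))
  if (abs(mf - mr) >= cfg$orientation_gap) {
    if (mf < mr) fwd <- list() else rc <- list()
  }
  list(fwd = fwd, rc = rc)
}

#' Per-read MEM statistics CSV
#'
#' One row per read: per-strand MEM counts, mean and maximum MEM length,
#' and total occurrence counts before capping and after each filter stage.
#'
#' @param reads data.frame with `id` and `seq` columns.
#' @param idx a `pm_rindex` over a pangenome text.
#' @param cfg a [seeding_config()].
#' @param path optional output CSV path.
#' @return The statistics data.frame, invisibly written to `path` if given.
#' @export
mem_stats_csv <- function(reads, idx, cfg = seeding_config(), path = NULL) {
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    seq <- normalize_read_chars(reads$seq[i])
    per_strand <- lapply(c(fwd = seq, rc = revcomp(seq)), function(rd) {
      ms <- matching_statistics(rd, idx)
      mems <- split_long_mems(extract_mems(ms, cfg), cfg)
      if (nrow(mems) == 0) list() else locate_seeds(mems, rd, idx, cfg)
    })
    per_strand$fwd <- lapply(per_strand$fwd, function(s) { s$strand <- "fwd"; s })
    per_strand$rc <- lapply(per_strand$rc, function(s) { s$strand <- "rc"; s })
    all_seeds <- c(per_strand$fwd, per_strand$rc)
    lens <- vapply(all_seeds, `[[`, numeric(1), "len")
    occ_cap <- sum(vapply(all_seeds, function(s) nrow(s$occ), integer(1)))
    occ_raw <- sum(vapply(all_seeds, `[[`, numeric(1), "occ_total_uncapped"))
    freq <- frequency_filter(all_seeds, cfg)
    strands <- vapply(freq, `[[`, character(1), "strand")
    of <- orientation_filter(freq[strands == "fwd"], freq[strands == "rc"], cfg)
    occ_freq <- sum(vapply(freq, function(s) nrow(s$occ), integer(1)))
    final <- c(of$fwd, of$rc)
    occ_final <- sum(vapply(final, function(s) nrow(s$occ), integer(1)))
    data.frame(read_id = reads$id[i],
               fwd_mems = length(per_strand$fwd),
               rc_mems = length(per_strand$rc),
               mean_mem_len = if (length(lens)) mean(lens) else 0,
               max_mem_len = if (length(lens)) max(lens) else 0L,
               occ_uncapped = occ_raw, occ_after_cap = occ_cap,
               occ_after_freq = occ_freq, occ_after_orientation = occ_final)
  })
  stats <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), fwd_mems = integer(), rc_mems = integer(),
               mean_mem_len = numeric(), max_mem_len = numeric(),
               occ_uncapped = numeric(), occ_after_cap = integer(),
               occ_after_freq = integer(), occ_after_orientation = integer())
  if (!is.null(path)) write.csv(stats, path, row.names = FALSE)
  invisible(stats)
}

#' Reverse complement
#'
#' @param seq character vector of DNA sequences.
#' @return Reverse complements; non-ACGT characters become N.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    s <- chartr("ACGTacgt", "TGCATGCA", s)
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
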