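#' Simulation configuration
#'
#' The defaults describe the synthetic world the package is exercised on: a
#' 100 kb single-contig reference with a small amount of duplicated sequence
#' (so that multi-mapping reads and the low end of the MAPQ spectrum exist,
#' as in real genomes), 20 haplotypes carrying Bernoulli SNPs at 1e-3 per
#' base and geometric-length indels at 1e-4 per base, and Illumina-like
#' 2 x 100 bp pairs with a normal insert-size distribution and 0.2%
#' substitution errors.
#'
#' @param ref_length reference length in bp.
#' @param n_haplotypes number of haplotypes (must be even; two per sample).
#' @param snp_rate per-base SNP probability per haplotype.
#' @param indel_rate per-base indel probability per haplotype.
#' @param max_indel_len maximum indel length (geometric lengths are capped).
#' @param read_length read length in bp.
#' @param n_pairs number of read pairs.
#' @param insert_mean,insert_sd normal insert-size (outer distance) model.
#' @param subst_error_rate per-base substitution sequencing error rate.
#' @param repeat_fraction fraction of the reference covered by duplicated
#'   segments.
#' @param repeat_unit length of each duplicated segment.
#' @param seed integer seed fixing all randomness.
#' @return list with class `pm_sim_config`.
#' @export
sim_config <- function(ref_length = 100000L, n_haplotypes = 20L,
                       snp_rate = 0.001, indel_rate = 0.0001,
                       max_indel_len = 10L, read_length = 100L,
                       n_pairs = 10000L, insert_mean = 350, insert_sd = 50,
                       subst_error_rate = 0.002, repeat_fraction = 0.02,
                       repeat_unit = 500L, seed = 42L) {
  stopifnot(ref_length > 0, n_haplotypes >= 2, n_haplotypes %% 2 == 0,
            snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            subst_error_rate >= 0, subst_error_rate <= 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  structure(as.list(environment()), class = "pm_sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a pangenome: reference, phased VCF and haplotypes
#'
#' Generates a random reference (with some duplicated segments), then per
#' haplotype draws Bernoulli SNPs and geometric-length indels; events whose
#' reference spans would overlap on one haplotype are dropped (the stated
#' resampling policy for overlapping indels).  All events are merged into
#' phased VCF records (two haplotypes per sample), and the haplotype
#' sequences plus lift maps are built by the generator's own event walk --
#' independently of [apply_variants()], so the round trip through the
#' pangenome builder is a meaningful check.
#'
#' @param cfg a [sim_config()].
#' @return list(ref, variants, gt, samples, haplotypes, cfg); `haplotypes`
#'   is a list of `pm_haplotype` objects.
#' @export
simulate_pangenome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  L <- cfg$ref_length
  refv <- sample(BASES, L, replace = TRUE)
  n_rep <- floor(L * cfg$repeat_fraction / cfg$repeat_unit / 2) # src+dst pairs
  for (k in seq_len(n_rep)) {
    src <- sample.int(L - cfg$repeat_unit, 1L)
    dst <- sample.int(L - cfg$repeat_unit, 1L)
    refv[dst:(dst + cfg$repeat_unit - 1L)] <- refv[src:(src + cfg$repeat_unit - 1L)]
  }
  ref <- setNames(paste(refv, collapse = ""), "chr1")

  # per-haplotype events: list of data.frames (pos, ref, alt)
  events <- vector("list", cfg$n_haplotypes)
  for (h in seq_len(cfg$n_haplotypes)) {
    snp_pos <- which(runif(L) < cfg$snp_rate)
    indel_pos <- which(runif(L) < cfg$indel_rate)
    indel_pos <- indel_pos[indel_pos > 1 & indel_pos < L - 2L * cfg$max_indel_len]
    ev <- data.frame(pos = integer(0), ref = character(0), alt = character(0))
    if (length(snp_pos)) {
      refb <- refv[snp_pos]
      altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), character(1))
      ev <- rbind(ev, data.frame(pos = snp_pos, ref = refb, alt = altb))
    }
    for (p in indel_pos) {
      ilen <- min(1L + rgeom(1L, 0.5), cfg$max_indel_len)
      if (runif(1) < 0.5) { # insertion after the anchor base
        ins <- paste(sample(BASES, ilen, replace = TRUE), collapse = "")
        ev <- rbind(ev, data.frame(pos = p, ref = refv[p],
                                   alt = paste0(refv[p], ins)))
      } else {              # deletion of ilen bases after the anchor
        ev <- rbind(ev, data.frame(
          pos = p, ref = paste(refv[p:(p + ilen)], collapse = ""),
          alt = refv[p]))
      }
    }
    if (nrow(ev)) {
      ev <- ev[order(ev$pos), , drop = FALSE]
      span_end <- ev$pos + nchar(ev$ref) - 1L
      keep <- rep(TRUE, nrow(ev))
      last_end <- 0L
      for (i in seq_len(nrow(ev))) {
        if (ev$pos[i] <= last_end) keep[i] <- FALSE
        else last_end <- span_end[i]
      }
      ev <- ev[keep, , drop = FALSE]
    }
    events[[h]] <- ev
  }

  # merge events into VCF records keyed by (pos, ref)
  keys <- unique(do.call(rbind, lapply(events, function(e) e[c("pos", "ref")])))
  if (is.null(keys)) keys <- data.frame(pos = integer(0), ref = character(0))
  keys <- keys[order(keys$pos, keys$ref), , drop = FALSE]
  key_id <- paste(keys$pos, keys$ref)
  alts <- vector("list", nrow(keys))
  hap_allele <- matrix(0L, nrow(keys), cfg$n_haplotypes)
  for (h in seq_len(cfg$n_haplotypes)) {
    e <- events[[h]]
    if (!nrow(e)) next
    ki <- match(paste(e$pos, e$ref), key_id)
    for (j in seq_along(ki)) {
      k <- ki[j]
      hit <- match(e$alt[j], alts[[k]])
      if (is.na(hit)) {
        alts[[k]] <- c(alts[[k]], e$alt[j])
        hit <- length(alts[[k]])
      }
      hap_allele[k, h] <- hit
    }
  }
  variants <- data.frame(chrom = rep("chr1", nrow(keys)), pos = keys$pos,
                         ref = keys$ref, stringsAsFactors = FALSE)
  variants$alts <- alts
  n_samples <- cfg$n_haplotypes %/% 2L
  samples <- sprintf("sim%02d", seq_len(n_samples))
  gt <- matrix("", nrow(keys), n_samples, dimnames = list(NULL, samples))
  for (s in seq_len(n_samples))
    gt[, s] <- paste(hap_allele[, 2L * s - 1L], hap_allele[, 2L * s], sep = "|")

  # generator-side haplotype construction (event walk over the reference)
  haplotypes <- vector("list", cfg$n_haplotypes)
  for (h in seq_len(cfg$n_haplotypes)) {
    e <- events[[h]]
    sample_id <- samples[(h + 1L) %/% 2L]
    phase <- 2L - (h %% 2L)
    pieces <- character(0)
    hs <- rs <- ln <- kd <- integer(0)
    ref_c <- 0L; hap_c <- 0L; mh <- 0L; mr <- 0L
    m_hs <- m_rs <- m_ln <- integer(0)
    for (i in seq_len(nrow(e))) {
      p0 <- e$pos[i] - 1L
      nr <- nchar(e$ref[i]); na <- nchar(e$alt[i])
      pieces <- c(pieces, substr(ref, ref_c + 1L, p0), e$alt[i])
      hap_c <- hap_c + (p0 - ref_c)
      anchored <- min(nr, na)
      if (na > nr) {
        if (hap_c + anchored > mh) {
          m_hs <- c(m_hs, mh); m_rs <- c(m_rs, mr)
          m_ln <- c(m_ln, hap_c + anchored - mh)
        }
        hs <- c(hs, hap_c + anchored); rs <- c(rs, p0 + anchored)
        ln <- c(ln, na - anchored); kd <- c(kd, 1L)
        mh <- hap_c + na; mr <- p0 + anchored
      } else if (na < nr) {
        if (hap_c + anchored > mh) {
          m_hs <- c(m_hs, mh); m_rs <- c(m_rs, mr)
          m_ln <- c(m_ln, hap_c + anchored - mh)
        }
        hs <- c(hs, hap_c + anchored); rs <- c(rs, p0 + anchored)
        ln <- c(ln, nr - anchored); kd <- c(kd, 2L)
        mh <- hap_c + anchored; mr <- p0 + nr
      }
      hap_c <- hap_c + na
      ref_c <- p0 + nr
    }
    pieces <- c(pieces, substr(ref, ref_c + 1L, L))
    hap_c <- hap_c + (L - ref_c)
    if (hap_c > mh) {
      m_hs <- c(m_hs, mh); m_rs <- c(m_rs, mr); m_ln <- c(m_ln, hap_c - mh)
    }
    segs <- data.frame(hs = c(m_hs, hs), rs = c(m_rs, rs), len = c(m_ln, ln),
                       kind = c(rep(0L, length(m_hs)), kd))
    segs <- segs[order(segs$hs, -segs$kind), , drop = FALSE]
    rownames(segs) <- NULL
    lift <- structure(segs, class = c("pm_liftmap", "data.frame"))
    attr(lift, "hap_len") <- hap_c
    attr(lift, "ref_len") <- L
    attr(lift, "contig") <- "chr1"
    haplotypes[[h]] <- structure(
      list(id = paste0(sample_id, "#", phase),
           contigs = setNames(paste(pieces, collapse = ""), "chr1"),
           liftmaps = setNames(list(lift), "chr1")),
      class = "pm_haplotype")
  }

  list(ref = ref, variants = variants, gt = gt, samples = samples,
       haplotypes = haplotypes, cfg = cfg)
}

#' Simulate Illumina-like paired reads with ground truth
#'
#' Fragments are drawn uniformly over uniformly-chosen haplotypes with a
#' normal outer-distance model; FR orientation, substitution errors only
#' (which keeps the truth positions exact).  The ground-truth reference
#' position of each mate is the generator's own lift of its leftmost
#' haplotype position.
#'
#' @param sim result of [simulate_pangenome()].
#' @param cfg a [sim_config()] (usually `sim$cfg`).
#' @return list(reads1, reads2, truth): the read data.frames carry `id`,
#'   `seq`, `qual`; `truth` has one row per mate with `id`, `mate`, `hap`,
#'   `hap_pos`, `contig`, `ref_pos`, `strand`.
#' @export
simulate_reads <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_pairs
  rl <- cfg$read_length
  haps <- sim$haplotypes
  hap_len <- vapply(haps, function(h) nchar(h$contigs[[1]]), integer(1))
  if (any(hap_len < rl)) stop("read length exceeds a haplotype length")
  hap_i <- sample.int(length(haps), n, replace = TRUE)
  frag <- pmax(rl, pmin(round(rnorm(n, cfg$insert_mean, cfg$insert_sd)),
                        hap_len[hap_i]))
  start <- vapply(seq_len(n), function(i)
    sample.int(hap_len[hap_i[i]] - frag[i] + 1L, 1L), integer(1))
  fwd_frag <- runif(n) < 0.5

  add_errors <- function(seqs) {
    vapply(seqs, function(s) {
      v <- strsplit(s, "")[[1]]
      err <- which(runif(length(v)) < cfg$subst_error_rate)
      if (length(err))
        v[err] <- vapply(v[err], function(b) sample(setdiff(BASES, b), 1L),
                         character(1))
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }

  left_seq <- character(n); right_seq <- character(n)
  for (i in seq_len(n)) {
    hseq <- haps[[hap_i[i]]]$contigs[[1]]
    left_seq[i] <- substr(hseq, start[i], start[i] + rl - 1L)
    right_seq[i] <- substr(hseq, start[i] + frag[i] - rl, start[i] + frag[i] - 1L)
  }
  # FR pair: mate 1 sits at the fragment 5' end on the fragment strand
  r1_seq <- ifelse(fwd_frag, left_seq, revcomp(right_seq))
  r2_seq <- ifelse(fwd_frag, revcomp(right_seq), left_seq)
  r1_pos <- ifelse(fwd_frag, start, start + frag - rl)
  r2_pos <- ifelse(fwd_frag, start + frag - rl, start)
  r1_strand <- ifelse(fwd_frag, "+", "-")
  r2_strand <- ifelse(fwd_frag, "-", "+")
  r1_seq <- add_errors(r1_seq)
  r2_seq <- add_errors(r2_seq)

  ids <- sprintf("sim_%06d", seq_len(n))
  qual <- strrep("I", rl)
  lift1 <- vapply(seq_len(n), function(i)
    lift_position(haps[[hap_i[i]]]$liftmaps[[1]], r1_pos[i]), integer(1))
  lift2 <- vapply(seq_len(n), function(i)
    lift_position(haps[[hap_i[i]]]$liftmaps[[1]], r2_pos[i]), integer(1))
  hap_ids <- vapply(haps, `[[`, character(1), "id")
  truth <- data.frame(
    id = rep(ids, 2L), mate = rep(c(1L, 2L), each = n),
    hap = hap_ids[c(hap_i, hap_i)],
    hap_pos = c(r1_pos, r2_pos), contig = "chr1",
    ref_pos = c(lift1, lift2), strand = c(r1_strand, r2_strand),
    stringsAsFactors = FALSE)
  list(reads1 = data.frame(id = ids, seq = r1_seq, qual = qual,
                           stringsAsFactors = FALSE),
       reads2 = data.frame(id = ids, seq = r2_seq, qual = qual,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Score alignments against simulation ground truth
#'
#' A read is a true positive when mapped within `tolerance` bp of its
#' ground-truth reference position (positions of soft-clipped alignments
#' are adjusted by the leading clip), a false positive when mapped further
#' away (or to the wrong contig), and a false negative when unmapped.
#'
#' @param sam a SAM path or the result of [read_sam()].
#' @param truth truth data.frame from [simulate_reads()].
#' @param tolerance positional tolerance in bp (default 10).
#' @return list(precision, recall, tp, fp, fn, n, zero_denominator):
#'   `precision = TP/(TP+FP)`; `recall = TP/(TP+FP+FN)`, i.e. the fraction
#'   of all reads placed correctly, so a mis-mapped read counts against
#'   both metrics (the usual aligner-benchmark convention).  An empty
#'   denominator reports 1 and sets `zero_denominator`.
#' @export
score_alignments <- function(sam, truth, tolerance = 10) {
  if (is.character(sam)) sam <- read_sam(sam)
  rec <- sam$records
  rec <- rec[bitwAnd(rec$flag, 0x900L) == 0L, , drop = FALSE] # primary only
  mate <- ifelse(bitwAnd(rec$flag, 0x80L) > 0L, 2L, 1L)
  key <- paste(rec$qname, mate)
  tkey <- paste(truth$id, truth$mate)
  ti <- match(key, tkey)
  if (anyNA(ti)) stop("SAM contains reads absent from the truth set")
  mapped <- bitwAnd(rec$flag, 0x4L) == 0L
  lead_clip <- vapply(rec$cigar, function(cg) {
    if (cg == "*") return(0L)
    m <- regmatches(cg, regexpr("^\\d+S", cg))
    if (length(m) && nchar(m)) as.integer(sub("S", "", m)) else 0L
  }, integer(1), USE.NAMES = FALSE)
  adj <- rec$pos - lead_clip
  tp <- mapped & rec$rname == truth$contig[ti] &
    abs(adj - truth$ref_pos[ti]) <= tolerance
  fp <- mapped & !tp
  fn <- !mapped
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  total <- TP + FP + FN
  list(precision = if (TP + FP > 0) TP / (TP + FP) else 1,
       recall = if (total > 0) TP / total else 1,
       tp = TP, fp = FP, fn = FN, n = nrow(rec),
       zero_denominator = (TP + FP == 0) || (total == 0))
}
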