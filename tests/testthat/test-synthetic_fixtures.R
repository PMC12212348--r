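# Synthetic pangenome/read generator and the evaluation module.

test_that("zero mutation rates reproduce the reference in every haplotype", {
  cfg <- sim_config(ref_length = 3000L, n_haplotypes = 4L, snp_rate = 0,
                    indel_rate = 0, n_pairs = 5L, seed = 3L,
                    repeat_fraction = 0)
  sim <- simulate_pangenome(cfg)
  for (h in sim$haplotypes)
    expect_identical(unname(h$contigs[["chr1"]]), unname(sim$ref[["chr1"]]))
  expect_equal(nrow(sim$variants), 0L)
})

test_that("fixed seeds give byte-identical generator output", {
  cfg <- sim_config(ref_length = 4000L, n_haplotypes = 4L, n_pairs = 30L,
                    seed = 5L)
  a <- simulate_pangenome(cfg)
  b <- simulate_pangenome(cfg)
  expect_identical(a$ref, b$ref)
  expect_identical(a$gt, b$gt)
  expect_identical(simulate_reads(a, cfg)$reads1$seq,
                   simulate_reads(b, cfg)$reads1$seq)
})

test_that("error-free reads are exact haplotype substrings at truth positions", {
  cfg <- sim_config(ref_length = 5000L, n_haplotypes = 4L, n_pairs = 40L,
                    subst_error_rate = 0, seed = 6L)
  sim <- simulate_pangenome(cfg)
  rd <- simulate_reads(sim, cfg)
  hap_ids <- vapply(sim$haplotypes, `[[`, character(1), "id")
  for (i in seq_len(nrow(rd$truth))) {
    tr <- rd$truth[i, ]
    h <- sim$haplotypes[[match(tr$hap, hap_ids)]]$contigs[["chr1"]]
    seq <- if (tr$mate == 1L) rd$reads1$seq[rd$reads1$id == tr$id]
           else rd$reads2$seq[rd$reads2$id == tr$id]
    if (tr$strand == "-") seq <- revcomp(seq)
    expect_identical(substr(h, tr$hap_pos, tr$hap_pos + cfg$read_length - 1L),
                     seq)
  }
})

test_that("constant inserts give constant fragment placement", {
  cfg <- sim_config(ref_length = 5000L, n_haplotypes = 2L, n_pairs = 50L,
                    insert_mean = 300, insert_sd = 0, subst_error_rate = 0,
                    snp_rate = 0, indel_rate = 0, seed = 8L,
                    repeat_fraction = 0)
  sim <- simulate_pangenome(cfg)
  rd <- simulate_reads(sim, cfg)
  t1 <- rd$truth[rd$truth$mate == 1L, ]
  t2 <- rd$truth[rd$truth$mate == 2L, ]
  expect_true(all(abs(t2$hap_pos - t1$hap_pos) + cfg$read_length == 300))
})

test_that("the realised substitution rate is within 3 binomial SDs", {
  cfg <- sim_config(ref_length = 5000L, n_haplotypes = 2L, n_pairs = 500L,
                    snp_rate = 0, indel_rate = 0, subst_error_rate = 0.01,
                    seed = 9L, repeat_fraction = 0)
  sim <- simulate_pangenome(cfg)
  rd <- simulate_reads(sim, cfg)
  ref <- sim$ref[["chr1"]]
  nerr <- 0L
  for (i in seq_len(nrow(rd$truth))) {
    tr <- rd$truth[i, ]
    seq <- if (tr$mate == 1L) rd$reads1$seq[rd$reads1$id == tr$id]
           else rd$reads2$seq[rd$reads2$id == tr$id]
    if (tr$strand == "-") seq <- revcomp(seq)
    truthseq <- substr(ref, tr$hap_pos, tr$hap_pos + cfg$read_length - 1L)
    nerr <- nerr + sum(strsplit(seq, "")[[1]] != strsplit(truthseq, "")[[1]])
  }
  nbase <- 2L * cfg$n_pairs * cfg$read_length
  expect_gte(nbase, 1e5)
  sd3 <- 3 * sqrt(nbase * 0.01 * 0.99)
  expect_lt(abs(nerr - nbase * 0.01), sd3)
})

test_that("score_alignments counts TP/FP/FN by the 10 bp convention", {
  truth <- data.frame(id = sprintf("r%d", 1:4), mate = 1L, hap = "h",
                      hap_pos = 1L, contig = "c", ref_pos = c(100L, 200L,
                                                             300L, 400L),
                      strand = "+")
  rec <- data.frame(
    qname = truth$id, flag = c(0L, 0L, 0L, 4L), rname = c("c", "c", "c", "*"),
    pos = c(105L, 340L, 12L, 0L), mapq = 60L,
    cigar = c("100M", "100M", "10S90M", "*"), rnext = "*", pnext = 0L,
    tlen = 0L, seq = strrep("A", 100), qual = "*", tags = "")
  # r1: within 10 bp (TP); r2: 140 bp off (FP); r3: soft-clip adjusted
  # position 12 - 10 = 2 vs truth 300 (FP... make it a TP at 300):
  rec$pos[3] <- 308L  # adjusted 308 - 10 = 298, within 10 of 300 (TP)
  sc <- score_alignments(list(records = rec), truth)
  expect_equal(sc$tp, 2L)
  expect_equal(sc$fp, 1L)
  expect_equal(sc$fn, 1L)
  expect_equal(sc$precision, 2 / 3)
  expect_equal(sc$recall, 2 / 4)
  # everything unmapped: precision degenerates to 1 with the flag raised
  rec2 <- rec
  rec2$flag <- 4L
  sc2 <- score_alignments(list(records = rec2), truth)
  expect_equal(sc2$recall, 0)
  expect_equal(sc2$precision, 1)
  expect_true(sc2$zero_denominator)
  # unknown reads are rejected
  rec3 <- rec
  rec3$qname[1] <- "stranger"
  expect_error(score_alignments(list(records = rec3), truth), "absent")
})

test_that("generator lift maps agree with the pipeline's liftover", {
  fix <- small_sim(seed = 61L)
  sim <- fix$sim
  hap_ids <- vapply(sim$haplotypes, `[[`, character(1), "id")
  paths <- write_sim_files(sim)
  vc <- read_vcf_gt(paths$vcf)
  set.seed(62)
  for (h in sample(seq_along(hap_ids), 2)) {
    built <- apply_variants(sim$ref, vc, sub("#.*", "", hap_ids[h]),
                            as.integer(sub(".*#", "", hap_ids[h])))
    pos <- sample.int(nchar(sim$haplotypes[[h]]$contigs[[1]]) - 10L, 50L)
    expect_equal(lift_position(built$liftmaps[[1]], pos),
                 lift_position(sim$haplotypes[[h]]$liftmaps[[1]], pos))
  }
})
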