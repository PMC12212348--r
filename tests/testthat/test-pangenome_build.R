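# Haplotype materialisation, pangenome text layout, lift maps and liftover.

ref50 <- setNames(paste(rep(c("ACGTG", "TTCAG"), 5), collapse = ""), "c1")

make_vcf <- function(variants, gt_values, sample = "s1") {
  gt <- matrix(gt_values, ncol = 1, dimnames = list(NULL, sample))
  list(variants = variants, gt = gt, samples = sample)
}

test_that("all-reference genotypes reproduce the reference identically", {
  v <- data.frame(chrom = "c1", pos = 5L, ref = "G", stringsAsFactors = FALSE)
  v$alts <- list("T")
  hap <- apply_variants(ref50, make_vcf(v, "0|0"), "s1", 1L)
  expect_identical(unname(hap$contigs[["c1"]]), unname(ref50[["c1"]]))
  lm <- hap$liftmaps[["c1"]]
  expect_equal(nrow(lm), 1L)
  expect_equal(lm$kind, 0L)
  expect_equal(lm$len, 50L)
})

test_that("a SNP changes the sequence but not the coordinates", {
  v <- data.frame(chrom = "c1", pos = 7L, ref = substr(ref50[["c1"]], 7, 7),
                  stringsAsFactors = FALSE)
  v$alts <- list("A")
  hap <- apply_variants(ref50, make_vcf(v, "1|0"), "s1", 1L)
  expect_equal(nchar(hap$contigs[["c1"]]), 50L)
  expect_equal(substr(hap$contigs[["c1"]], 7, 7), "A")
  expect_equal(nrow(hap$liftmaps[["c1"]]), 1L)  # still a single match segment
  # phase 2 carries the reference allele
  hap2 <- apply_variants(ref50, make_vcf(v, "1|0"), "s1", 2L)
  expect_identical(unname(hap2$contigs[["c1"]]), unname(ref50[["c1"]]))
})

test_that("a deletion shifts downstream coordinates by interval arithmetic", {
  # delete reference positions 11-12: VCF anchor at 10, REF 3 bp, ALT 1 bp
  v <- data.frame(chrom = "c1", pos = 10L,
                  ref = substr(ref50[["c1"]], 10, 12), stringsAsFactors = FALSE)
  v$alts <- list(substr(ref50[["c1"]], 10, 10))
  hap <- apply_variants(ref50, make_vcf(v, "1|1"), "s1", 1L)
  expect_equal(nchar(hap$contigs[["c1"]]), 48L)
  lm <- hap$liftmaps[["c1"]]
  # haplotype position 20 lifts to reference position 22
  expect_equal(lift_position(lm, 20L), 22L)
  expect_equal(lift_position(lm, 10L), 10L)  # before the deletion: identity
  # round trip through the inverse on match segments
  expect_equal(invert_lift_position(lm, 22L), 20L)
  expect_true(is.na(invert_lift_position(lm, 11L))) # deleted base: no image
})

test_that("an insertion anchors inserted bases and maps around them", {
  v <- data.frame(chrom = "c1", pos = 20L,
                  ref = substr(ref50[["c1"]], 20, 20), stringsAsFactors = FALSE)
  v$alts <- list(paste0(substr(ref50[["c1"]], 20, 20), "GGG"))
  hap <- apply_variants(ref50, make_vcf(v, "1|1"), "s1", 1L)
  expect_equal(nchar(hap$contigs[["c1"]]), 53L)
  lm <- hap$liftmaps[["c1"]]
  expect_equal(lift_position(lm, 20L), 20L)
  expect_equal(lift_position(lm, 21L), 21L)  # inside the insertion: anchors
                                             # to the next reference base
  expect_equal(lift_position(lm, 24L), 21L)  # first base after it
})

test_that("lift maps tile the haplotype and reconstruct it from the reference", {
  fix <- small_sim()
  for (h in fix$sim$haplotypes[1:2]) {
    lm <- h$liftmaps[[1]]
    hapseq <- h$contigs[[1]]
    cons <- lm[lm$kind != 2L, , drop = FALSE]
    cons <- cons[order(cons$hs), , drop = FALSE]
    expect_equal(cons$hs, c(0L, head(cons$hs + cons$len, -1L))) # no gaps
    expect_equal(sum(cons$len), nchar(hapseq))
    # match segments preserve coordinates: outside SNP sites the sequence is
    # the reference (SNPs live inside match segments by design, so compare
    # mismatch counts against the haplotype's SNP load rather than verbatim)
    mt <- lm[lm$kind == 0L, , drop = FALSE]
    mism <- 0L
    for (i in seq_len(nrow(mt))) {
      a <- strsplit(substr(hapseq, mt$hs[i] + 1L, mt$hs[i] + mt$len[i]), "")[[1]]
      b <- strsplit(substr(fix$sim$ref[[1]], mt$rs[i] + 1L,
                           mt$rs[i] + mt$len[i]), "")[[1]]
      mism <- mism + sum(a != b)
    }
    expect_lte(mism, nchar(hapseq) * fix$cfg$snp_rate * 5) # SNPs only
  }
})

test_that("round trip: lifting then inverse-lifting is the identity on match segments", {
  fix <- small_sim()
  lm <- fix$sim$haplotypes[[1]]$liftmaps[[1]]
  set.seed(31)
  mt <- lm[lm$kind == 0L, , drop = FALSE]
  pos <- unlist(lapply(seq_len(min(nrow(mt), 20)), function(i)
    mt$hs[i] + sample.int(mt$len[i], 1L)))  # 1-based inside a match segment
  lifted <- lift_position(lm, pos)
  expect_equal(invert_lift_position(lm, lifted), pos)
  expect_true(all(diff(lift_position(lm, sort(pos))) >= 0)) # monotone
})

test_that("variant application is rejected on malformed input", {
  v <- data.frame(chrom = "c1", pos = 5L, ref = "T", stringsAsFactors = FALSE)
  v$alts <- list("A")
  expect_error(apply_variants(ref50, make_vcf(v, "1|1"), "s1", 1L), "REF allele")
  v2 <- data.frame(chrom = "c1", pos = 5L, ref = "G", stringsAsFactors = FALSE)
  v2$alts <- list("T")
  expect_error(apply_variants(ref50, make_vcf(v2, "0/1"), "s1", 1L), "unphased")
  # overlapping records: first kept, second skipped with a warning
  v3 <- data.frame(chrom = "c1", pos = c(10L, 11L),
                   ref = c(substr(ref50[["c1"]], 10, 12),
                           substr(ref50[["c1"]], 11, 11)),
                   stringsAsFactors = FALSE)
  v3$alts <- list(substr(ref50[["c1"]], 10, 10), "A")
  expect_warning(hap <- apply_variants(ref50, make_vcf(v3, c("1|1", "1|1")),
                                       "s1", 1L), "overlapping")
  expect_equal(nchar(hap$contigs[["c1"]]), 48L)
})

test_that("pangenome text layout matches the documented concatenation", {
  mk_hap <- function(id, seq) structure(
    list(id = id, contigs = setNames(seq, "c"),
         liftmaps = setNames(list(identity_liftmap(nchar(seq), "c")), "c")),
    class = "pm_haplotype")
  pt1 <- build_pangenome_text(list(mk_hap("a#1", "ACGT")),
                              include_reference = FALSE)
  expect_equal(length(pt1$text), 5L)          # ACGT + terminator
  expect_equal(pt1$doc_start, 0L)
  pt2 <- build_pangenome_text(list(mk_hap("a#1", strrep("A", 10)),
                                   mk_hap("a#2", strrep("C", 20))),
                              include_reference = FALSE)
  expect_equal(pt2$doc_start, c(0L, 11L))     # one separator in between
  expect_equal(global_to_local(pt2, 11L), list(doc = 2L, local = 0L))
  expect_equal(local_to_global(pt2, 2L, 0L), 11L)
  expect_error(global_to_local(pt2, 10L), "not a sequence position")
  expect_error(build_pangenome_text(list(), include_reference = FALSE),
               "no haplotypes")
})

test_that("alignment liftover rewrites CIGARs across indels", {
  # variant-free window: identity
  lm0 <- identity_liftmap(50L, "c1")
  a0 <- lift_alignment(list(pos = 5L, cigar = "20M", score = 40), lm0)
  expect_true(a0$liftable)
  expect_equal(a0$pos, 5L)
  expect_equal(a0$cigar, "20M")
  expect_equal(a0$score, 40)

  # read spanning the 2-bp deletion: all-match on the haplotype becomes =D=
  v <- data.frame(chrom = "c1", pos = 10L,
                  ref = substr(ref50[["c1"]], 10, 12), stringsAsFactors = FALSE)
  v$alts <- list(substr(ref50[["c1"]], 10, 10))
  hap <- apply_variants(ref50, make_vcf(v, "1|1"), "s1", 1L)
  lm <- hap$liftmaps[["c1"]]
  a1 <- lift_alignment(list(pos = 6L, cigar = "10M", score = 20), lm)
  expect_true(a1$liftable)
  expect_equal(a1$pos, 6L)
  expect_equal(a1$cigar, "5M2D5M")

  # read spanning an insertion gains I ops relative to the reference
  vi <- data.frame(chrom = "c1", pos = 20L,
                   ref = substr(ref50[["c1"]], 20, 20), stringsAsFactors = FALSE)
  vi$alts <- list(paste0(substr(ref50[["c1"]], 20, 20), "GGG"))
  hapi <- apply_variants(ref50, make_vcf(vi, "1|1"), "s1", 1L)
  a2 <- lift_alignment(list(pos = 18L, cigar = "10M", score = 20),
                       hapi$liftmaps[["c1"]])
  expect_equal(a2$cigar, "3M3I4M")

  # alignment entirely inside the insertion has no reference anchor
  a3 <- lift_alignment(list(pos = 21L, cigar = "3M", score = 6),
                       hapi$liftmaps[["c1"]])
  expect_false(a3$liftable)
})

test_that("same-position dedup keeps the higher score", {
  alns <- data.frame(contig = "c1", pos = c(100L, 100L, 150L),
                     strand = c(0L, 0L, 0L), score = c(180, 195, 120))
  kept <- dedup_lifted(alns)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$score[kept$pos == 100L], 195)
})

test_that("the emitted VCF applied through the builder reproduces the generator haplotypes", {
  fix <- small_sim()
  paths <- write_sim_files(fix$sim)
  vc <- read_vcf_gt(paths$vcf)
  for (h in seq_along(fix$sim$haplotypes)) {
    sample <- fix$sim$samples[(h + 1L) %/% 2L]
    phase <- 2L - (h %% 2L)
    built <- apply_variants(fix$sim$ref, vc, sample, phase)
    expect_identical(unname(built$contigs[["chr1"]]),
                     unname(fix$sim$haplotypes[[h]]$contigs[["chr1"]]),
                     label = paste("haplotype", h))
    expect_equal(as.data.frame(built$liftmaps[["chr1"]]),
                 as.data.frame(fix$sim$haplotypes[[h]]$liftmaps[["chr1"]]))
  }
})
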