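# Insert-size model, pair selection, orphan-recovery floor, MAPQ formulas.

test_that("Welford model matches the two-pass formulas", {
  m0 <- insert_size_model(rep(300, 5))
  expect_equal(m0$mean, 300)
  expect_equal(m0$sd, 0)
  m1 <- insert_size_model(c(290, 300, 310))
  expect_equal(m1$mean, 300)
  expect_equal(m1$sd, 10)
  set.seed(901)
  for (rep in 1:1000) {
    x <- rnorm(sample(2:60, 1), mean = runif(1, 100, 500), sd = runif(1, 0, 60))
    m <- insert_size_model(x)
    expect_equal(m$mean, mean(x), tolerance = 1e-9)
    expect_equal(m$sd, two_pass_sd(x), tolerance = 1e-9)
  }
})

test_that("single-end MAPQ reproduces the analytic examples", {
  sch <- test_scheme()
  expect_equal(mapq_single(200, 200, 0, 100, sch), 0L)   # zero gap
  expect_equal(mapq_single(200, 0, 0, 100, sch), 60L)    # huge gap caps at 60
  # m1=2, m2=4, l=100, s1=200 (i=1), s2=150, n=1:
  # floor(6.02*50/8 - 4.343*ln 2) = floor(34.61) = 34
  expect_equal(mapq_single(200, 150, 1, 100, sch), 34L)
})

test_that("MAPQ is monotone, bounded, and the paired elevation is capped", {
  sch <- test_scheme()
  q <- outer(seq(0, 200, by = 10), 0:5, function(gap, n)
    mapply(function(g, nn) mapq_single(200, 200 - g, nn, 100, sch), gap, n))
  expect_true(all(q >= 0 & q <= 60))
  expect_true(all(apply(q, 2, diff) >= 0))   # nondecreasing in the gap
  expect_true(all(apply(q, 1, diff) <= 0))   # nonincreasing in n
  # Eq. 3 behaviour
  expect_equal(mapq_paired(20, 20, 400, 200, sch), 20L)  # Q' = Q collapses
  expect_equal(mapq_paired(0, 60, 400, 200, sch), 40L)   # elevation <= Q + 40
  expect_equal(mapq_paired(30, 60, 400, 400, sch), 0L)   # s1p = s2p: cap 0
  for (Q in c(0L, 10L, 35L)) {
    for (Qp in c(0L, 30L, 60L)) {
      qi <- mapq_paired(Q, Qp, 400, 0, sch)
      expect_lte(qi, Q + 40L)
      expect_gte(qi, min(Q, qi)) # never below the outer cap floor
    }
  }
})

test_that("count_secondary_scores counts distinct scores in the window", {
  expect_equal(count_secondary_scores(numeric(0), 200, 0.8), 0L)
  expect_equal(count_secondary_scores(c(190, 190, 150), 200, 0.8), 1L)
  expect_equal(count_secondary_scores(c(200, 200), 200, 0.8), 0L) # not strict secondaries
  expect_equal(count_secondary_scores(c(199, 180, 161, 159), 200, 0.8), 3L)
})

test_that("pair selection enforces the insert window as a hard constraint", {
  model <- insert_size_model(c(290, 300, 310))
  c1 <- data.frame(contig = 0L, pos = 1000L, span = 100L, strand = 0L,
                   score = 200)
  # two mate-2 candidates: higher-scoring combo outside the window loses
  c2 <- data.frame(contig = c(0L, 0L), pos = c(1201L, 2000L),
                   span = c(100L, 100L), strand = c(1L, 1L),
                   score = c(150, 190))
  sel <- pair_select(c1, c2, model)
  expect_equal(sel$i, 1L)
  expect_equal(sel$j, 1L)          # insert 300 wins despite lower sum
  expect_equal(sel$s1p, 350)
  # no combination in the window: orphan state
  c2b <- c2[2, , drop = FALSE]
  sel2 <- pair_select(c1, c2b, model)
  expect_equal(sel2$i, 0L)
  # window edge mu + 4 sigma is inclusive
  m2 <- insert_size_model(c(290, 300, 310))    # sd 10 -> window [260, 340]
  c2c <- data.frame(contig = 0L, pos = 1240L, span = 100L, strand = 1L,
                    score = 180)               # outer = exactly 340
  sel3 <- pair_select(c1, c2c, m2)
  expect_equal(sel3$i, 1L)
  # same strand never pairs
  c2d <- data.frame(contig = 0L, pos = 1201L, span = 100L, strand = 0L,
                    score = 180)
  expect_equal(pair_select(c1, c2d, model)$i, 0L)
})

test_that("orphan recovery rescues an error-free mate inside the window", {
  fix <- small_sim(seed = 21L)
  sim <- fix$sim
  paths <- write_sim_files(sim)
  idx <- pm_build_index(paths$ref, paths$vcf)
  # fragments from haplotype 1 at known positions, mate2 = rc downstream
  h <- sim$haplotypes[[1]]$contigs[[1]]
  n <- 40
  set.seed(22)
  starts <- sample(1000:6000, n)
  r1 <- data.frame(id = sprintf("p%03d", 1:n),
                   seq = substring(h, starts, starts + 99L),
                   qual = strrep("I", 100))
  mate2 <- substring(h, starts + 200L, starts + 299L)
  r2 <- data.frame(id = r1$id, seq = revcomp(mate2), qual = strrep("I", 100))
  # corrupt mate 2 of the last 5 pairs so badly that seeding cannot find it,
  # while staying recoverable by window alignment (10% scattered errors)
  corrupt <- function(s) {
    v <- strsplit(s, "")[[1]]
    at <- seq(3, length(v), by = 10)
    v[at] <- vapply(v[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                    character(1))
    paste(v, collapse = "")
  }
  set.seed(23)
  r2$seq[36:40] <- vapply(r2$seq[36:40], corrupt, character(1))
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  res_off <- pm_align(idx, f1, f2, cfg = align_config(orphan_recovery = FALSE))
  res_on <- pm_align(idx, f1, f2, cfg = align_config(orphan_recovery = TRUE))
  mapped_off <- sum(bitwAnd(res_off$records$flag, 4L) == 0L)
  mapped_on <- sum(bitwAnd(res_on$records$flag, 4L) == 0L)
  expect_gt(mapped_on, mapped_off)          # -u strictly increases alignment
  expect_equal(mapped_on, 2L * n)           # every corrupted mate recovered
  # the recovered mates are placed at their true positions
  rec <- res_on$records
  m2rec <- rec[bitwAnd(rec$flag, 0x80L) > 0L, ]
  m2rec <- m2rec[match(r1$id, m2rec$qname), ]
  lm <- sim$haplotypes[[1]]$liftmaps[[1]]
  truth2 <- lift_position(lm, starts + 200L)
  expect_true(all(abs(m2rec$pos - truth2) <= 10))
})
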