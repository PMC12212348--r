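# Gap-filling extension and CIGAR re-scoring.

test_that("a perfect single-anchor alignment is all-match with score m1*l", {
  set.seed(801)
  win <- random_dna(60)
  rd <- substr(win, 11, 40)
  aln <- fill_between_anchors(rd, win,
                              data.frame(x = 1L, y = 11L, len = 30L))
  expect_equal(aln$cigar, "30=")
  expect_equal(aln$score, 2L * 30L)
  expect_equal(aln$pos, 11L)
  expect_equal(score_cigar(aln$cigar, rd, substr(win, aln$pos, 60)), aln$score)
})

test_that("two anchors separated by one mismatch give =X= and m1*(l-1)-m2", {
  set.seed(802)
  win <- random_dna(50)
  rd <- substr(win, 1, 31)
  mid <- substr(rd, 16, 16)
  substr(rd, 16, 16) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  aln <- fill_between_anchors(rd, win,
                              data.frame(x = c(1L, 17L), y = c(1L, 17L),
                                         len = c(15L, 15L)))
  expect_equal(aln$cigar, "15=1X15=")
  expect_equal(aln$score, 2L * 30L - 4L)
})

test_that("anchored score equals full-matrix global alignment on small gaps", {
  set.seed(803)
  sch <- test_scheme()
  for (rep in 1:60) {
    win <- random_dna(30)
    rd <- win
    # plant a small internal mutation between two intact 9 bp flancs
    kind <- sample(c("sub", "del", "ins"), 1)
    if (kind == "sub") {
      at <- sample(10:20, 1)
      substr(rd, at, at) <- sample(c("A", "C", "G", "T"), 1)
    } else if (kind == "del") {
      cut <- sample(2:6, 1)
      rd <- paste0(substr(rd, 1, 12), substr(rd, 13 + cut, 30))
    } else {
      ins <- random_dna(sample(2:6, 1))
      rd <- paste0(substr(rd, 1, 12), ins, substr(rd, 13, 30))
    }
    m <- nchar(rd)
    anchors <- data.frame(x = c(1L, m - 8L), y = c(1L, 22L), len = c(9L, 9L))
    ok <- all(substr(rd, 1, 9) == substr(win, 1, 9),
              substr(rd, m - 8, m) == substr(win, 22, 30))
    if (!ok) next
    aln <- fill_between_anchors(rd, win, anchors, sch)
    expect_equal(aln$score, affine_global_oracle(rd, win),
                 label = paste("kind:", kind))
    expect_equal(score_cigar(aln$cigar, rd,
                             substr(win, aln$pos, nchar(win)), sch),
                 aln$score)
  }
})

test_that("flanks extend to the read ends and soft-clip hopeless tails", {
  set.seed(804)
  win <- random_dna(80)
  core <- substr(win, 31, 60)
  junk <- strrep("A", 12)
  rd <- paste0(junk, core)  # left flank cannot extend into the window
  aln <- fill_between_anchors(rd, win,
                              data.frame(x = 13L, y = 31L, len = 30L))
  expect_match(aln$cigar, "S.*=$|S30=$")
  ops <- cigar_to_ops(aln$cigar)
  expect_equal(ops$op[1], "S")
  # window truncation at haplotype bounds soft-clips the overhang
  rd2 <- paste0(core, "TTTT")
  aln2 <- fill_between_anchors(rd2, substr(win, 31, 60),
                               data.frame(x = 1L, y = 1L, len = 30L))
  expect_equal(aln2$cigar, "30=4S")
})

test_that("score_cigar validates and rescoring examples hold", {
  rd <- strrep("A", 100)
  win <- strrep("A", 110)
  expect_equal(score_cigar("100M", rd, win), 200L)
  expect_equal(score_cigar("50M2D50M", rd, win), 200L - 8L)  # 4 + 2*2
  expect_error(score_cigar("", rd, win), "empty CIGAR")
  expect_error(score_cigar("101M", rd, win), "overruns|consume")
  expect_error(score_cigar("99M", rd, win), "consume")
})

test_that("CIGAR/score consistency holds on random anchored alignments", {
  set.seed(805)
  sch <- test_scheme()
  for (rep in 1:40) {
    win <- random_dna(120)
    rd <- substr(win, 21, 80)
    v <- strsplit(rd, "")[[1]]
    at <- sample(10:50, 3)
    v[at] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    rd <- paste(v, collapse = "")
    # anchor on an intact stretch found by scanning
    runs <- which(v == strsplit(substr(win, 21, 80), "")[[1]])
    anchor_at <- runs[which(diff(runs, lag = 7) == 7)[1]]
    if (is.na(anchor_at)) next
    aln <- fill_between_anchors(rd, win,
                                data.frame(x = anchor_at,
                                           y = 20L + anchor_at, len = 8L), sch)
    expect_equal(score_cigar(aln$cigar, rd,
                             substr(win, aln$pos, nchar(win)), sch),
                 aln$score)
  }
})
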