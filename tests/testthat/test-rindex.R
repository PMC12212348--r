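# r-index: construction, count/locate vs naive suffix-array oracles,
# LF walk, threshold jumps, random access.

test_that("classic examples build the expected run-length BWT", {
  idx1 <- build_rindex("aaaa$")
  expect_equal(rindex_bwt(idx1), "aaaa$")
  expect_equal(idx1$r, 2L)

  idx2 <- build_rindex("abracadabra$")
  expect_equal(rindex_bwt(idx2), naive_bwt("abracadabra$"))
  expect_equal(rindex_bwt(idx2), "ard$rcaaaabb")
  expect_equal(idx2$r, 8L)
})

test_that("sampled SA values sit at run boundaries of the naive SA", {
  set.seed(501)
  for (rep in 1:5) {
    s <- paste0(random_dna(1000), "$")
    idx <- build_rindex(s)
    sa <- naive_sa(s)
    expect_lte(idx$r, nchar(s))
    cpp <- idx$cpp
    expect_equal(cpp$sa_first, sa[cpp$run_start + 1L])
    expect_equal(cpp$sa_last, sa[cpp$run_start + cpp$run_len])
  }
})

test_that("backward_step matches naive counting and handles edge cases", {
  idx <- build_rindex("abracadabra$")
  # terminator: full range stepped with $ has width 1
  r <- backward_step(idx, init_range(idx), "$")
  expect_equal(r$hi - r$lo, 1L)
  # pattern abra: final range width 2
  rng <- pattern_range(idx, "abra")
  expect_equal(rng$hi - rng$lo, 2L)
  # absent character: empty range
  r2 <- backward_step(idx, init_range(idx), "z")
  expect_equal(r2$lo, r2$hi)
})

test_that("count/locate equal the naive suffix-array oracle on random texts", {
  set.seed(502)
  for (rep in 1:100) {
    n <- sample(50:2000, 1)
    s <- paste0(random_dna(n), "$")
    idx <- build_rindex(s)
    for (k in 1:50) {
      plen <- sample(1:12, 1)
      if (runif(1) < 0.7) { # substring of the text: guaranteed occurrences
        st <- sample(seq_len(max(1, n - plen)), 1)
        pat <- substr(s, st, st + plen - 1L)
      } else pat <- random_dna(plen)
      got <- locate_occurrences(idx, pat)
      expect_equal(got, naive_occurrences(s, pat))
    }
  }
})

test_that("locating the terminator returns the final position", {
  s <- "GATTACA$"
  idx <- build_rindex(s)
  expect_equal(locate_occurrences(idx, "$"), nchar(s) - 1L)
})

test_that("LF walk from the terminator row spells the reversed text", {
  s <- "mississippi$"
  idx <- build_rindex(s)
  n <- nchar(s)
  bwt <- rindex_bwt(idx)
  row <- 0L
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- substr(bwt, row + 1L, row + 1L)
    row <- lf_step(idx, row)
  }
  # the walk emits text[n-1], text[n-2], ..., text[0]: the terminator comes
  # out last because BWT[row of "$"] is the character preceding it
  expect_equal(paste(out, collapse = ""),
               paste0(paste(rev(strsplit(substr(s, 1, n - 1), "")[[1]]),
                            collapse = ""), "$"))
  expect_equal(row, 0L) # the walk is a full cycle
})

test_that("random access returns the stored text", {
  s <- "abracadabra$"
  idx <- build_rindex(s)
  expect_equal(rindex_access(idx, c(0L, 6L, 11L)), c("a", "d", "$"))
  set.seed(503)
  pos <- sample(0:(nchar(s) - 1L), 8)
  expect_equal(paste(rindex_access(idx, pos), collapse = ""),
               paste(substring(s, pos + 1L, pos + 1L), collapse = ""))
  expect_error(rindex_access(idx, nchar(s)), "range")
})

test_that("threshold jump lands on the unique run when a char has one run", {
  # in aaaa$ the 'a' run is unique: any failing row jumps into it
  idx <- build_rindex("aaaa$")
  # the only row where extension with 'a' can fail is the terminator run
  j <- threshold_jump(idx, 4L, "a")
  expect_true(j$found)
  bw <- strsplit(rindex_bwt(idx), "")[[1]]
  expect_equal(bw[j$row + 1L], "a")
  # absent character signals exhaustion
  expect_false(threshold_jump(idx, 0L, "z")$found)
})

test_that("pfp and direct construction yield identical index content", {
  set.seed(504)
  s <- paste0(random_dna(1500), "$")
  direct <- build_rindex(s)
  via_pfp <- build_rindex(s, via = "pfp", w = 4, p = 30)
  for (f in c("n", "r", "run_char", "run_start", "run_len", "sa_first",
              "sa_last", "cr_thresh", "phi_key", "phi_val"))
    expect_identical(direct$cpp[[f]], via_pfp$cpp[[f]], label = f)
})

test_that("malformed texts are rejected", {
  expect_error(build_rindex("abc"), "terminator")   # no unique minimum at end
  expect_error(build_rindex("a$b$"), "terminator")  # terminator not unique
})
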