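# Matching statistics, MEM extraction/splitting, occurrence location and
# the seed filters.

test_that("matching statistics reproduce the worked examples", {
  idx <- index_of("GATTACAT#GATTAGAT#GATTACCAT")
  # read equal to a 6 bp text substring: full-length first statistic
  ms1 <- matching_statistics("GATTAC", idx)
  expect_equal(ms1$len[1], 6L)
  # TACC occurs, TACCG does not
  ms2 <- matching_statistics("TACCG", idx)
  expect_equal(ms2$len[1], 4L)
  # characters absent from the text
  ms3 <- matching_statistics("NNNN", idx)
  expect_equal(ms3$len, rep(0L, 4))
})

test_that("matching statistics equal the naive oracle on random pairs", {
  set.seed(601)
  for (rep in 1:100) {
    n <- sample(100:2000, 1)
    text <- random_dna(n, alphabet = c("A", "C", "G", "T", "N"))
    idx <- index_of(text)
    m <- sample(20:100, 1)
    if (runif(1) < 0.6) { # reads sampled from the text with mutations
      st <- sample(n - m, 1)
      rd <- substr(text, st, st + m - 1L)
      v <- strsplit(rd, "")[[1]]
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        at <- sample(m, nmut)
        v[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      rd <- paste(v, collapse = "")
    } else rd <- random_dna(m, alphabet = c("A", "C", "G", "T", "N"))
    ms <- matching_statistics(rd, idx)
    expect_equal(ms$len, naive_matching_stats(text, rd))
    # reported positions really carry the reported match
    rdn <- gsub("N", "n", rd)
    for (i in which(ms$len > 0)) {
      expect_identical(substr(text, ms$pos[i] + 1L, ms$pos[i] + ms$len[i]),
                       substr(rdn, i, i + ms$len[i] - 1L) |> toupper())
      expect_false(grepl("n", substr(rd, i, i + ms$len[i] - 1L)))
    }
  }
})

test_that("extracted MEMs are maximal matches", {
  set.seed(602)
  text <- random_dna(1500)
  idx <- index_of(text)
  cfg <- seeding_config(min_mem_len = 8L)
  for (rep in 1:10) {
    st <- sample(1400, 1)
    rd <- substr(text, st, st + 60)
    ms <- matching_statistics(rd, idx)
    mems <- extract_mems(ms, cfg)
    for (k in seq_len(nrow(mems))) {
      s0 <- mems$start[k]; L <- mems$len[k]
      mem <- substr(rd, s0, s0 + L - 1L)
      expect_gt(length(naive_occurrences(text, mem)), 0)
      # right-maximal: extending one base right kills all occurrences
      if (s0 + L <= nchar(rd))
        expect_length(naive_occurrences(text, substr(rd, s0, s0 + L)), 0)
      # left-maximal: extending one base left kills all occurrences
      if (s0 > 1)
        expect_length(naive_occurrences(text, substr(rd, s0 - 1L, s0 + L - 1L)), 0)
    }
  }
})

test_that("MEM start rule follows the nondecreasing-length definition", {
  mems <- extract_mems(list(len = c(4L, 3L, 2L, 1L)),
                       seeding_config(min_mem_len = 2L))
  expect_equal(nrow(mems), 1L)
  expect_equal(mems$start, 1L)
  expect_equal(mems$len, 4L)
  none <- extract_mems(list(len = c(3L, 2L, 1L)), seeding_config())
  expect_equal(nrow(none), 0L) # all below the default 25 bp minimum
})

test_that("long MEMs split into two adjacent halves", {
  cfg <- seeding_config()
  s100 <- split_long_mems(data.frame(start = 1L, len = 100L), cfg)
  expect_equal(nrow(s100), 2L)
  expect_equal(s100$len, c(50L, 50L))
  expect_equal(s100$start, c(1L, 51L))
  s50 <- split_long_mems(data.frame(start = 5L, len = 50L), cfg)
  expect_equal(nrow(s50), 1L)           # boundary: strictly-greater rule
  s51 <- split_long_mems(data.frame(start = 1L, len = 51L), cfg)
  expect_equal(s51$len, c(26L, 25L))
})

test_that("locate_seeds finds occurrences and honours the per-genome cap", {
  # two documents of one genome, a third of another
  mk_hap <- function(id, seq) structure(
    list(id = id, contigs = setNames(seq, "c"),
         liftmaps = setNames(list(identity_liftmap(nchar(seq), "c")), "c")),
    class = "pm_haplotype")
  motif <- "ACGTACGTGG"
  d1 <- paste0(strrep(motif, 3), random_dna(40))   # 3 occurrences
  set.seed(603)
  d2 <- paste0(random_dna(40), motif)              # 1 occurrence
  pt <- build_pangenome_text(list(mk_hap("g1#1", d1), mk_hap("g1#2", d2),
                                  mk_hap("g2#1", d1)),
                             include_reference = FALSE)
  idx <- build_rindex(pt)
  seeds <- locate_seeds(data.frame(start = 1L, len = nchar(motif)), motif, idx,
                        seeding_config(min_mem_len = 5L))
  occ <- seeds[[1]]$occ
  expect_equal(seeds[[1]]$occ_total_uncapped, 7)
  expect_equal(sum(occ$doc == 1L), 3L)
  expect_equal(occ$local[occ$doc == 2L], 41L)
  # cap = 2 per genome: g1 (docs 1+2, 4 occurrences) and g2 (doc 3, 3
  # occurrences) each keep 2
  capped <- locate_seeds(data.frame(start = 1L, len = nchar(motif)), motif, idx,
                         seeding_config(min_mem_len = 5L, max_occ_per_genome = 2L))
  cocc <- capped[[1]]$occ
  expect_equal(sum(cocc$doc %in% c(1L, 2L)), 2L)
  expect_equal(sum(cocc$doc == 3L), 2L)
  expect_equal(capped[[1]]$occ_total_uncapped, 7)
})

test_that("frequency filter removes dominating seeds by the stated rule", {
  mk_seed <- function(n) list(start = 1L, len = 30L,
                              occ = data.frame(doc = rep(1L, n),
                                               local = seq_len(n)),
                              occ_total_uncapped = n)
  cfg <- seeding_config()
  # counts 600/300/100: the 600 seed holds >= 50% of 1000
  out <- frequency_filter(list(mk_seed(600), mk_seed(300), mk_seed(100)), cfg)
  expect_equal(vapply(out, function(s) nrow(s$occ), integer(1)), c(300L, 100L))
  # counts 400/400/200: none reaches 50%
  out2 <- frequency_filter(list(mk_seed(400), mk_seed(400), mk_seed(200)), cfg)
  expect_length(out2, 3L)
  # single seed: guard rule keeps it
  out3 <- frequency_filter(list(mk_seed(999)), cfg)
  expect_length(out3, 1L)
  # filters never alter surviving seeds
  expect_identical(out[[1]]$occ, mk_seed(300)$occ)
})

test_that("orientation filter drops the short-MEM strand only beyond the gap", {
  mk <- function(lens) lapply(lens, function(l)
    list(start = 1L, len = l, occ = data.frame(doc = 1L, local = 1L),
         occ_total_uncapped = 1))
  cfg <- seeding_config()
  r1 <- orientation_filter(mk(c(80, 80)), mk(c(20, 20)), cfg)
  expect_length(r1$rc, 0L)     # means 80 vs 20: rc dropped
  expect_length(r1$fwd, 2L)
  r2 <- orientation_filter(mk(c(60, 60)), mk(c(20, 20)), cfg)
  expect_length(r2$rc, 2L)     # gap 40 < 50: both kept
  r3 <- orientation_filter(mk(c(80)), list(), cfg)
  expect_length(r3$fwd, 1L)    # empty strand never drops the other
})

test_that("MEM statistics CSV has one row per read and consistent totals", {
  fix <- small_sim()
  pt <- build_pangenome_text(fix$sim$haplotypes, include_reference = TRUE,
                             ref = fix$sim$ref)
  idx <- build_rindex(pt)
  hseq <- fix$sim$haplotypes[[1]]$contigs[[1]]
  reads <- data.frame(id = c("a", "b"),
                      seq = c(substr(hseq, 101, 200),
                              revcomp(substr(hseq, 501, 600))))
  path <- tempfile(fileext = ".csv")
  stats <- mem_stats_csv(reads, idx, path = path)
  expect_equal(nrow(stats), 2L)
  on_disk <- read.csv(path)
  expect_equal(nrow(on_disk), 2L)
  expect_true(all(stats$occ_after_cap <= stats$occ_uncapped))
  expect_true(all(stats$occ_after_freq <= stats$occ_after_cap))
  # header-only file for empty input
  p2 <- tempfile(fileext = ".csv")
  mem_stats_csv(data.frame(id = character(), seq = character()), idx, path = p2)
  expect_equal(nrow(read.csv(p2)), 0L)
})
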