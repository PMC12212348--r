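# Independent oracles: naive, definition-level implementations used to
# check the index and alignment machinery.  They deliberately avoid the
# package's own code paths.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# 0-based suffix array by direct suffix sorting (C-locale byte order).
naive_sa <- function(text) {
  n <- nchar(text)
  sufs <- substring(text, seq_len(n), n)
  order(sufs, method = "radix") - 1L
}

naive_bwt <- function(text) {
  sa <- naive_sa(text)
  n <- nchar(text)
  prev <- ifelse(sa == 0L, n, sa)          # 1-based index of preceding char
  paste(substring(text, prev, prev), collapse = "")
}

# all (overlapping) 0-based occurrence positions of pat in text
naive_occurrences <- function(text, pat) {
  n <- nchar(text); k <- nchar(pat)
  if (k == 0 || k > n) return(integer(0))
  starts <- seq_len(n - k + 1L)
  which(substring(text, starts, starts + k - 1L) == pat) - 1L
}

# Matching statistics by definition, honouring the N rule (read N matches
# nothing; text N matches no read character).  Right-to-left with the
# len[i] <= len[i+1] + 1 bound; occurrence tests via fixed-string grepl.
naive_matching_stats <- function(text, read) {
  text_m <- text                          # text N stays N
  read_m <- gsub("N", "n", toupper(read)) # read N can never match
  m <- nchar(read_m)
  len <- integer(m)
  prev <- 0L
  for (i in m:1) {
    L <- min(m - i + 1L, prev + 1L)
    while (L > 0 &&
           !grepl(substr(read_m, i, i + L - 1L), text_m, fixed = TRUE))
      L <- L - 1L
    len[i] <- L
    prev <- L
  }
  len
}

# exhaustive colinear chaining over <= ~12 anchors
brute_chain_score <- function(x, y, l, c1 = 0.12, c2 = 0.5, max_gap = 500L) {
  k <- length(x)
  best <- -Inf
  link_ok <- function(i, j) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    dx > 0 && dy > 0 && dx <= max_gap && dy <= max_gap
  }
  link_score <- function(i, j) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    gain <- min(dx, dy, l[j])
    d <- abs(dy - dx)
    gain - if (d == 0) 0 else c1 * d + c2 * log2(d)
  }
  dfs <- function(last, score) {
    best <<- max(best, score)
    for (j in seq_len(k)) {
      if (link_ok(last, j)) dfs(j, score + link_score(last, j))
    }
  }
  for (s in seq_len(k)) dfs(s, l[s])
  best
}

# full-matrix global affine-gap alignment score (Gotoh), score only
affine_global_oracle <- function(a, b, match = 2, mismatch = 4, gap_open = 4,
                                 gap_extend = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, la + 1, lb + 1)
  E <- matrix(NEG, la + 1, lb + 1)  # gap in b (deletion)
  F_ <- matrix(NEG, la + 1, lb + 1) # gap in a (insertion)
  M[1, 1] <- 0
  for (j in seq_len(lb)) {
    E[1, j + 1] <- -(gap_open + j * gap_extend); M[1, j + 1] <- E[1, j + 1]
  }
  for (i in seq_len(la)) {
    F_[i + 1, 1] <- -(gap_open + i * gap_extend); M[i + 1, 1] <- F_[i + 1, 1]
  }
  acgt <- c("A", "C", "G", "T")
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - gap_extend,
                             M[i + 1, j] - gap_open - gap_extend)
      F_[i + 1, j + 1] <- max(F_[i, j + 1] - gap_extend,
                              M[i, j + 1] - gap_open - gap_extend)
      hit <- av[i] == bv[j] && av[i] %in% acgt
      M[i + 1, j + 1] <- max(M[i, j] + if (hit) match else -mismatch,
                             E[i + 1, j + 1], F_[i + 1, j + 1])
    }
  }
  M[la + 1, lb + 1]
}

# two-pass mean/sd for the Welford cross-check
two_pass_sd <- function(x) {
  if (length(x) < 2) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / (length(x) - 1))
}
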