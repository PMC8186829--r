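# Independent brute-force oracles, deliberately implemented without reusing
# any package internals.

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mis <- 0L; comp <- 0L
  for (i in seq_along(av)) {
    if (av[i] == "N" || bv[i] == "N") next
    comp <- comp + 1L
    if (av[i] != bv[i]) mis <- mis + 1L
  }
  if (comp == 0) 0 else mis / comp
}

# upper-tail binomial P(X >= h) by explicit pmf summation
oracle_binom_upper <- function(h, size, prob) {
  if (h <= 0) return(1)
  k <- h:size
  sum(choose(size, k) * prob^k * (1 - prob)^(size - k))
}

# BH step-up: adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# type-7 quantile: linear interpolation between order statistics
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# small collapsed-family tibble from named UMI counts and sequences
make_family <- function(seqs, umis) {
  tibble::tibble(
    sequence_id = names(seqs),
    sequence_nt = unname(seqs),
    umi_count = unname(umis[names(seqs)]),
    productive = TRUE
  )
}

# minimal rearrangement tibble
make_records <- function(n = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    sequence_id = sprintf("s%03d", seq_len(n)),
    sequence_nt = vapply(seq_len(n), function(i) random_nt(60), character(1)),
    v_call = sample(c("IGHV1-69*01", "IGHV3-23*01"), n, replace = TRUE),
    j_call = sample(c("IGHJ4*02", "IGHJ6*02"), n, replace = TRUE),
    junction_nt = vapply(seq_len(n), function(i) random_nt(24), character(1)),
    productive = sample(c(TRUE, FALSE), n, replace = TRUE),
    umi_count = sample(1:50, n, replace = TRUE),
    read_count = sample(5:500, n, replace = TRUE),
    sample_id = "S1",
    replicate_id = sample(c("rep1", "rep2"), n, replace = TRUE)
  )
}
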