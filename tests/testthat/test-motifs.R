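# Motif site maps, mutation categories, enrichment tests, Ts:Tv

test_that("site maps encode the motif definitions on both strands", {
  hot <- builtin_motifs()$aid_hotspot
  cold <- builtin_motifs()$aid_coldspot
  # "TAC": C is WRC (W=T, R=A)
  expect_true(motif_site_map("TAC", hot)[3])
  # "GTC": C is SYC (S=G, Y=T)
  expect_true(motif_site_map("GTC", cold)[3])
  expect_false(motif_site_map("GTC", hot)[3])
  # "GCA": G is GYW on the reverse strand (rc of WRC)
  expect_true(motif_site_map("GCA", hot)[1])
  # Pol-eta: A in a WA context
  pe <- builtin_motifs()$poleta_hotspot
  expect_true(motif_site_map("TA", pe)[2])
  expect_true(motif_site_map("TT", pe)[1])  # the T of TW on the reverse strand
  expect_false(motif_site_map("GA", pe)[2])
  expect_error(motif_spec("bad", "WXC", 3, "GC"), "IUPAC")
})

test_that("hotspot masks are strand-symmetric mirror images", {
  set.seed(61)
  for (spec in builtin_motifs()[c("aid_hotspot", "aid_coldspot",
                                  "poleta_hotspot", "apobec_hotspot")]) {
    for (k in 1:20) {
      s <- random_nt(50)
      m_fwd <- motif_site_map(s, spec)
      m_rev <- motif_site_map(oracle_revcomp(s), spec)
      expect_equal(m_fwd, rev(m_rev))
    }
  }
})

test_that("category assignment is an exhaustive partition matching an oracle", {
  # independent per-position oracle written from the motif definitions
  oracle_category <- function(s, pos, from) {
    ch <- strsplit(s, "")[[1]]
    at <- function(i) if (i >= 1 && i <= length(ch)) ch[i] else ""
    W <- c("A", "T"); R <- c("A", "G"); S <- c("C", "G"); Y <- c("C", "T")
    if (from %in% c("C", "G")) {
      hot <- (from == "C" && at(pos - 2) %in% W && at(pos - 1) %in% R) ||
        (from == "G" && at(pos + 1) %in% Y && at(pos + 2) %in% W)
      if (hot) return("aid_hotspot")
      cold <- (from == "C" && at(pos - 2) %in% S && at(pos - 1) %in% Y) ||
        (from == "G" && at(pos + 1) %in% R && at(pos + 2) %in% S)
      if (cold) return("aid_coldspot")
      return("other")
    }
    pe <- (from == "A" && at(pos - 1) %in% W) ||
      (from == "T" && at(pos + 1) %in% W)
    if (pe) "poleta_hotspot" else "other"
  }
  set.seed(62)
  s <- random_nt(30)
  ch <- strsplit(s, "")[[1]]
  muts <- tibble::tibble(
    position = rep(1:30, each = 3),
    from = rep(ch, each = 3)
  )
  muts$to <- unlist(lapply(ch, function(b) setdiff(c("A", "C", "G", "T"), b)))
  got <- classify_mutations(muts, s)
  expected <- vapply(seq_len(nrow(muts)), function(i) {
    oracle_category(s, muts$position[i], muts$from[i])
  }, character(1))
  expect_equal(as.character(got$category), expected)
  # partition: every mutation in exactly one category
  expect_false(any(is.na(got$category)))
})

test_that("substitution-constrained signatures require the substitution", {
  sig1 <- builtin_motifs()$aging_sig1
  ref <- "AACGA"
  m_ct <- tibble::tibble(position = 3L, from = "C", to = "T")
  m_cg <- tibble::tibble(position = 3L, from = "C", to = "G")
  expect_true(signature_match(m_ct, ref, sig1))
  expect_false(signature_match(m_cg, ref, sig1))
  # reverse strand: G>A at the G of NCG's complement (CGN)
  m_ga <- tibble::tibble(position = 4L, from = "G", to = "A")
  expect_true(signature_match(m_ga, ref, sig1))
  sig5 <- builtin_motifs()$cancer_sig5
  m_tc <- tibble::tibble(position = 2L, from = "T", to = "C")
  expect_true(signature_match(m_tc, "ATG", sig5))
  expect_false(signature_match(tibble::tibble(position = 2L, from = "T", to = "G"),
                               "ATG", sig5))
})

test_that("binomial enrichment matches pmf-summation oracle and closed forms", {
  set.seed(63)
  ref <- random_nt(200)
  spec <- builtin_motifs()$aid_hotspot
  # closed forms via direct binomial identities
  r0 <- enrichment_test(tibble::tibble(position = integer(), from = character(),
                                       to = character()), ref, spec)
  expect_false(r0$testable)
  # h = 0: upper tail at 0 is 1
  expect_equal(oracle_binom_upper(0, 10, 0.3), 1)
  # all at motif: p = p0^(h+n)
  expect_equal(oracle_binom_upper(7, 7, 0.3), 0.3^7)
  # oracle equivalence on random (h, n, p0)
  for (k in 1:1000) {
    h <- sample(0:30, 1); n <- sample(0:30, 1)
    if (h + n == 0) next
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(stats::pbinom(h - 1, h + n, p0, lower.tail = FALSE),
                 oracle_binom_upper(h, h + n, p0), tolerance = 1e-12)
  }
  # end-to-end: enrichment_test on constructed mutations reproduces counts
  hot_sites <- which(motif_site_map(ref, spec) & base_class_sites(ref, "GC"))
  gc_sites <- which(base_class_sites(ref, "GC"))
  hot_sites <- hot_sites[hot_sites > 2 & hot_sites < 199]
  non_hot <- setdiff(gc_sites[gc_sites > 2 & gc_sites < 199], hot_sites)
  muts <- tibble::tibble(
    position = c(sample(hot_sites, 8, replace = TRUE),
                 sample(non_hot, 2, replace = TRUE))
  )
  muts$from <- strsplit(ref, "")[[1]][muts$position]
  muts$to <- "A"  # placeholder; context test ignores the to-base
  res <- enrichment_test(muts, ref, spec)
  expect_equal(res$h, 8L); expect_equal(res$n, 2L)
  expect_equal(res$p_value,
               oracle_binom_upper(8, 10, res$p0), tolerance = 1e-12)
})

test_that("enrichment p-value is monotone in the expected proportion", {
  # p_value at p0 = h/(h+n) is >= p_value at any smaller p0
  set.seed(64)
  for (k in 1:100) {
    h <- sample(1:20, 1); n <- sample(0:20, 1)
    p_hat <- h / (h + n)
    p_small <- runif(1, 0.01, max(p_hat - 1e-6, 0.011))
    pv_hat <- stats::pbinom(h - 1, h + n, min(p_hat, 0.999), lower.tail = FALSE)
    pv_small <- stats::pbinom(h - 1, h + n, p_small, lower.tail = FALSE)
    expect_gte(pv_hat, pv_small - 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.42), 0.42)
  expect_equal(bh_correct(rep(0.2, 6)), rep(0.2, 6))
  set.seed(65)
  for (k in 1:200) {
    p <- runif(sample(1:15, 1))
    expect_equal(bh_correct(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("category fractions sum to one and detect AID weighting", {
  set.seed(66)
  ref <- random_nt(300)
  all_wrc <- which(motif_site_map(ref, builtin_motifs()$aid_hotspot))
  muts <- tibble::tibble(position = all_wrc,
                         from = strsplit(ref, "")[[1]][all_wrc], to = "A")
  fr <- category_fractions(muts, ref)
  expect_equal(fr$aid_hotspot, 1)
  expect_equal(fr$aid_hotspot + fr$aid_coldspot + fr$poleta_hotspot + fr$other, 1)
  expect_equal(category_fractions(muts[0, ], ref)$n_mutations, 0L)
  # AID-weighted simulated mutations exceed the base hotspot rate
  base_rate <- mean(motif_site_map(ref, builtin_motifs()$aid_hotspot))
  pool <- list()
  for (i in 1:40) {
    pool[[i]] <- mutate_sequence(ref, "aid", 20, transition_prob = 0.6,
                                 hotspot_multiplier = 8)$mutations
  }
  mm <- dplyr::bind_rows(pool)
  fr2 <- category_fractions(mm, ref)
  expect_gt(fr2$aid_hotspot, base_rate)
})

test_that("Ts:Tv follows the transition definition", {
  m <- tibble::tibble(position = 1:3, from = c("C", "G", "A"),
                      to = c("T", "A", "C"))
  expect_equal(ts_tv_ratio(m), 2)
  expect_true(is.nan(ts_tv_ratio(m[0, ])))
  only_ts <- tibble::tibble(position = 1:2, from = c("A", "C"), to = c("G", "T"))
  expect_true(is.infinite(ts_tv_ratio(only_ts)))
  by <- list(a = m, b = m, inf = only_ts)
  expect_warning(res <- ts_tv_by_sample(by), "no transversions")
  expect_equal(res$median, 2)
})

test_that("non-productive comparators are selected by pooled family frequency", {
  rec <- tibble::tibble(
    sequence_id = c("p1", "n1", "n2", "n2b"),
    sequence_nt = c("AAAA", "CCCC", "CCCT", "CCCT"),
    clone_id = c("c1", "c2", "c2", "c2"),
    productive = c(TRUE, FALSE, FALSE, FALSE),
    umi_count = c(100L, 9990L, 6L, 4L)
  )
  out <- select_nonproductive_comparators(rec, 8e-5)
  # productive excluded; n2 pooled frequency 10/10000 = 0.1% >= 0.008%
  expect_setequal(out$sequence_id, c("n1", "n2"))
  expect_equal(out$frequency[out$sequence_id == "n2"], 0.001)
  out2 <- select_nonproductive_comparators(rec, 0.5)
  expect_equal(out2$sequence_id, "n1")
  set.seed(67)
  for (k in 1:20) {
    n <- 30
    rec <- tibble::tibble(
      sequence_id = sprintf("s%02d", 1:n),
      sequence_nt = replicate(n, random_nt(12)),
      clone_id = "f1",
      productive = FALSE,
      umi_count = sample(1:500, n, replace = TRUE)
    )
    thr <- runif(1, 0, 0.1)
    out <- select_nonproductive_comparators(rec, thr)
    truth <- rec$sequence_id[rec$umi_count / sum(rec$umi_count) >= thr]
    expect_setequal(out$sequence_id, truth)
  }
})
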