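# R/S classification, expected replacement fraction, selection strength

test_that("R/S classification matches the genetic-code oracle exhaustively", {
  expect_equal(classify_r_s(tibble::tibble(position = 1L, from = "C", to = "T"),
                            "CTA")$rs_class, "S")  # Leu -> Leu
  expect_equal(classify_r_s(tibble::tibble(position = 3L, from = "G", to = "C"),
                            "TGG")$rs_class, "R")  # Trp -> Cys
  # 64 codons x 9 substitutions against seqinr's translation
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (cod in codons) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        got <- classify_r_s(tibble::tibble(position = p,
                                           from = substr(cod, p, p), to = b),
                            cod)$rs_class
        mut <- cod; substr(mut, p, p) <- b
        aa0 <- seqinr::translate(strsplit(cod, "")[[1]])
        aa1 <- seqinr::translate(strsplit(mut, "")[[1]])
        want <- if (aa0 == "*" || aa1 == "*") "stop" else
          if (aa0 == aa1) "S" else "R"
        expect_equal(got, want)
      }
    }
  }
})

test_that("R/S classification respects the reading-frame offset", {
  # offset 2: codons start at position 3
  ref <- paste0("GG", "TGG", "CTA")
  m <- classify_r_s(tibble::tibble(position = 5L, from = "G", to = "C"),
                    ref, reading_frame_offset = 2L)
  expect_equal(m$rs_class, "R")  # TGG -> TGC, Trp -> Cys
  # positions before the frame start have no complete codon
  m2 <- classify_r_s(tibble::tibble(position = 1L, from = "G", to = "A"),
                     ref, reading_frame_offset = 2L)
  expect_true(is.na(m2$rs_class))
})

test_that("expected replacement fraction follows enumeration with stop handling", {
  regions <- tibble::tibble(start = 1L, end = 3L, type = "CDR")
  # ATG: all 9 substitutions are replacements, none silent, no stops
  expect_equal(expected_r_fraction("ATG", regions)$pi0, 1)
  # region of identical codons has the single-codon pi0
  reg2 <- tibble::tibble(start = 1L, end = 9L, type = "CDR")
  expect_equal(expected_r_fraction(strrep("CTA", 3), reg2)$pi0,
               expected_r_fraction("CTA", regions)$pi0)
  # motif-weighted model with all weight on one position
  w <- stats::setNames(c(100), "ATG")  # 3-mer centered weight, center = T
  reg3 <- tibble::tibble(start = 1L, end = 6L, type = "FR")
  ref <- "CATGCA"
  pw <- targeting_weights(ref, w)
  expect_equal(which(pw > 1), 3L)
  # enumeration oracle for the uniform model on a random region
  set.seed(71)
  ref <- random_germline(30)
  reg <- tibble::tibble(start = 1L, end = 30L, type = "CDR")
  got <- expected_r_fraction(ref, reg)
  n_r <- 0L; n_s <- 0L
  for (p in 1:30) {
    cod_start <- 3 * ((p - 1) %/% 3) + 1
    cod <- substr(ref, cod_start, cod_start + 2)
    for (b in setdiff(c("A", "C", "G", "T"), substr(ref, p, p))) {
      mut <- cod
      substr(mut, p - cod_start + 1, p - cod_start + 1) <- b
      aa0 <- seqinr::translate(strsplit(cod, "")[[1]])
      aa1 <- seqinr::translate(strsplit(mut, "")[[1]])
      if (aa0 == "*" || aa1 == "*") next
      if (aa0 == aa1) n_s <- n_s + 1L else n_r <- n_r + 1L
    }
  }
  expect_equal(got$pi0, n_r / (n_r + n_s))
})

test_that("selection strength has correct null, sign and symmetry behavior", {
  # null: observed fraction equal to pi0 at large counts -> mode near 0
  null <- selection_strength(300, 100, 0.75)
  expect_lt(abs(null$mode), 0.02)
  expect_true(null$ci[1] < 0 && null$ci[2] > 0)
  # sign: all replacements -> mass predominantly positive
  pos <- selection_strength(10, 0, 0.75)
  expect_gt(pos$mode, 0)
  z <- diff(pos$sigma[1:2])
  expect_gt(sum(pos$density[pos$sigma > 0]) * z, 0.9)
  # mirror symmetry: swapping R<->S and pi0<->1-pi0 negates the posterior
  a <- selection_strength(12, 4, 0.6)
  b <- selection_strength(4, 12, 0.4)
  expect_equal(a$mode, -b$mode, tolerance = 1e-10)
  expect_equal(a$ci, -rev(b$ci), tolerance = 1e-6)
  expect_equal(a$density, rev(b$density), tolerance = 1e-8)
  expect_error(selection_strength(0, 0, 0.5), "at least one")
  expect_error(selection_strength(5, 5, 1), "degenerate")
})

test_that("posterior summaries agree with a dense-grid integration oracle", {
  set.seed(72)
  for (k in 1:10) {
    r <- sample(1:40, 1); s <- sample(1:40, 1)
    pi0 <- runif(1, 0.2, 0.8)
    got <- selection_strength(r, s, pi0)
    fine <- seq(-10, 10, by = 0.001)
    theta <- stats::plogis(fine + stats::qlogis(pi0))
    f <- theta^(r + 1) * (1 - theta)^(s + 1)
    f <- f / sum(f * 0.001)
    cdf <- cumsum(f * 0.001)
    mode_oracle <- fine[which.max(f)]
    ci_oracle <- suppressWarnings(c(stats::approx(cdf, fine, 0.025)$y,
                                    stats::approx(cdf, fine, 0.975)$y))
    expect_lt(abs(got$mode - mode_oracle), 1e-3)
    expect_lt(max(abs(got$ci - ci_oracle)), 2e-3)
    # density integrates to 1 on its grid
    zw <- diff(got$sigma)[1]
    expect_equal(sum(got$density) * zw, 1, tolerance = 1e-6)
  }
})

test_that("group comparison is calibrated on identical posteriors", {
  a <- selection_strength(10, 10, 0.5)
  cmp <- compare_selection(a, a)
  expect_equal(cmp$p_greater, 0.5, tolerance = 1e-4)
  expect_equal(cmp$p_value, 1, tolerance = 1e-3)
  b <- selection_strength(30, 2, 0.5)
  c2 <- selection_strength(2, 30, 0.5)
  cmp2 <- compare_selection(b, c2)
  expect_gt(cmp2$p_greater, 0.99)
  expect_lt(cmp2$p_value, 0.02)
})

test_that("region-pooled selection analysis recovers planted direction", {
  set.seed(73)
  ref <- random_germline(366)
  regions <- default_region_map()
  # mutate CDR positions toward replacements, FR positions toward silents
  pi0 <- expected_r_fraction(ref, regions)
  seqs <- character(0)
  for (i in 1:30) {
    s <- ref
    cdr_pos <- unlist(mapply(seq, regions$start[regions$type == "CDR"],
                             regions$end[regions$type == "CDR"]))
    for (p in sample(cdr_pos, 4)) {
      cands <- classify_r_s(
        tibble::tibble(position = p, from = substr(ref, p, p),
                       to = setdiff(c("A", "C", "G", "T"), substr(ref, p, p))),
        ref)
      pick <- cands[!is.na(cands$rs_class) & cands$rs_class == "R", ]
      if (nrow(pick) > 0) substr(s, p, p) <- pick$to[1]
    }
    seqs <- c(seqs, s)
  }
  sel <- selection_by_region(seqs, ref, regions)
  expect_gt(sel$CDR$mode, 0)
})
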