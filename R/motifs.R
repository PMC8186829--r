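# Mechanistic attribution of post-CDC mutations by sequence context.
#
# Mutations are assumed to have occurred on the CDC background. G:C mutations
# are tested against AID hotspot (WRC/GYW) and coldspot (SYC/GRS) contexts;
# A:T mutations against the Pol-eta signature (WA/TW). Additional
# substitution-constrained contexts cover APOBEC3A/B (TC/GA), the aging
# signature (C>T at NCG) and the cancer signature (T>C at ApTpN).
# Enrichment of hotspot targeting is assessed with a one-sided exact
# binomial test against the hotspot fraction of the relevant base class on
# the CDC, with Benjamini-Hochberg correction across samples.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

#' @noRd
.revcomp_pattern <- function(pattern) {
  paste(rev(.IUPAC_COMP[nt_chars(pattern)]), collapse = "")
}

#' Define a mutational motif context
#'
#' A motif is an IUPAC pattern with a designated mutated-base offset; the
#' reverse-complement pattern (with mirrored offset) is derived automatically
#' so both strands are scanned. Substitution-specific signatures additionally
#' constrain the from- and to-base of the mutation (on the forward-strand
#' reading; the complementary substitution is matched on the reverse strand).
#'
#' @param name Motif name.
#' @param pattern Forward IUPAC pattern, e.g. `"WRC"`.
#' @param offset 1-based position of the mutated base within `pattern`.
#' @param base_class `"GC"` or `"AT"`: the base class whose sites form the
#'   expected-proportion denominator.
#' @param from,to Optional required substitution (forward-strand reading).
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(name, pattern, offset, base_class = c("GC", "AT"),
                       from = NA_character_, to = NA_character_) {
  base_class <- match.arg(base_class)
  pattern <- toupper(pattern)
  if (!all(nt_chars(pattern) %in% names(.IUPAC))) {
    stop("invalid IUPAC code in pattern: ", pattern)
  }
  stopifnot(offset >= 1, offset <= nchar(pattern))
  structure(list(
    name = name, pattern = pattern, offset = offset,
    rc_pattern = .revcomp_pattern(pattern),
    rc_offset = nchar(pattern) - offset + 1L,
    base_class = base_class, from = from, to = to
  ), class = "motif_spec")
}

#' Built-in motif contexts
#'
#' AID hotspot WRC/GYW and coldspot SYC/GRS (G:C sites), Pol-eta hotspot
#' WA/TW (A:T sites), APOBEC3A/B hotspot TC/GA (G:C sites), aging-signature
#' context C>T at NCG, and cancer-signature context T>C at ApTpN.
#'
#' @return Named list of `motif_spec` objects.
#' @export
builtin_motifs <- function() {
  list(
    aid_hotspot = motif_spec("aid_hotspot", "WRC", 3L, "GC"),
    aid_coldspot = motif_spec("aid_coldspot", "SYC", 3L, "GC"),
    poleta_hotspot = motif_spec("poleta_hotspot", "WA", 2L, "AT"),
    apobec_hotspot = motif_spec("apobec_hotspot", "TC", 2L, "GC"),
    aging_sig1 = motif_spec("aging_sig1", "NCG", 2L, "GC", from = "C", to = "T"),
    cancer_sig5 = motif_spec("cancer_sig5", "ATN", 2L, "AT", from = "T", to = "C")
  )
}

#' @noRd
.pattern_matches_at <- function(seq_chars, start, pattern) {
  len <- nchar(pattern)
  if (start < 1 || start + len - 1 > length(seq_chars)) return(FALSE)
  pc <- nt_chars(pattern)
  for (k in seq_len(len)) {
    if (!seq_chars[start + k - 1] %in% .IUPAC[[pc[k]]]) return(FALSE)
  }
  TRUE
}

#' Motif site map over a reference sequence
#'
#' Flags each position whose base belongs to the motif's base class and whose
#' neighborhood matches the forward or the reverse-complement pattern.
#' Positions whose context window runs off either sequence end are never
#' flagged.
#'
#' @param reference_nt Ungapped reference nucleotide string (the CDC).
#' @param spec A `motif_spec`.
#' @return Logical vector of length `nchar(reference_nt)`.
#' @export
motif_site_map <- function(reference_nt, spec) {
  s <- nt_chars(reference_nt)
  L <- length(s)
  mask <- logical(L)
  for (i in seq_len(L)) {
    fwd <- .pattern_matches_at(s, i - spec$offset + 1L, spec$pattern)
    rev <- .pattern_matches_at(s, i - spec$rc_offset + 1L, spec$rc_pattern)
    mask[i] <- fwd || rev
  }
  mask
}

#' Base-class site mask (G:C or A:T) on a reference
#' @param reference_nt Reference nucleotide string.
#' @param base_class `"GC"` or `"AT"`.
#' @return Logical vector over positions.
#' @export
base_class_sites <- function(reference_nt, base_class = c("GC", "AT")) {
  base_class <- match.arg(base_class)
  s <- nt_chars(reference_nt)
  if (base_class == "GC") s %in% c("G", "C") else s %in% c("A", "T")
}

#' Classify mutations into mechanistic categories
#'
#' Each mutation receives exactly one of four categories based on its context
#' on the CDC background: G:C mutations are `aid_hotspot` (WRC/GYW),
#' `aid_coldspot` (SYC/GRS) or `other`; A:T mutations are `poleta_hotspot`
#' (WA/TW) or `other`. The hotspot and coldspot patterns are disjoint by
#' construction, so the assignment is a partition.
#'
#' @param mutations Tibble from [call_mutations()] (columns `position`,
#'   `from`, `to`).
#' @param reference_nt CDC reference the positions index into.
#' @return `mutations` with an added `category` factor with levels
#'   `aid_hotspot`, `aid_coldspot`, `poleta_hotspot`, `other`.
#' @export
classify_mutations <- function(mutations, reference_nt) {
  specs <- builtin_motifs()
  hot <- motif_site_map(reference_nt, specs$aid_hotspot)
  cold <- motif_site_map(reference_nt, specs$aid_coldspot)
  pe <- motif_site_map(reference_nt, specs$poleta_hotspot)
  cat <- rep("other", nrow(mutations))
  gc <- mutations$from %in% c("G", "C")
  at <- mutations$from %in% c("A", "T")
  cat[gc & hot[mutations$position]] <- "aid_hotspot"
  cat[gc & !hot[mutations$position] & cold[mutations$position]] <- "aid_coldspot"
  cat[at & pe[mutations$position]] <- "poleta_hotspot"
  mutations$category <- factor(cat, levels = c("aid_hotspot", "aid_coldspot",
                                               "poleta_hotspot", "other"))
  mutations
}

#' Does a mutation match a substitution-constrained signature context?
#'
#' Checks both context and (when the spec declares one) the substitution,
#' matching the complementary substitution on the reverse strand.
#'
#' @param mutations Mutation tibble.
#' @param reference_nt CDC reference.
#' @param spec A `motif_spec`.
#' @return Logical vector, one per mutation.
#' @export
signature_match <- function(mutations, reference_nt, spec) {
  mask <- motif_site_map(reference_nt, spec)
  hit <- mask[mutations$position]
  if (!is.na(spec$from)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    fwd_sub <- mutations$from == spec$from & mutations$to == spec$to
    rev_sub <- mutations$from == comp[spec$from] & mutations$to == comp[spec$to]
    hit <- hit & (fwd_sub | rev_sub)
  }
  hit
}

#' One-sided binomial hotspot-enrichment test
#'
#' Pools the mutations of one sample (each distinct mutation counted once per
#' unique sequence carrying it), splits the mutations of the motif's base
#' class into hotspot (`h`) and non-hotspot (`n`) counts, and tests whether
#' the hotspot proportion exceeds the expected proportion `p0` = motif sites /
#' base-class sites on the CDC background. `p_value = P(X >= h)` for
#' `X ~ Binomial(h + n, p0)`, computed exactly. Positions whose context
#' window runs off the sequence end are excluded from both the numerator and
#' the denominator of `p0`.
#'
#' @param mutations Mutation tibble for one sample (pooled over unique
#'   sequences; repeats allowed and counted).
#' @param reference_nt CDC reference.
#' @param spec A `motif_spec`.
#' @param sample_id Optional sample label carried into the result.
#' @return One-row tibble: `sample_id`, `motif`, `h`, `n`, `p0`, `p_value`,
#'   `testable`.
#' @export
enrichment_test <- function(mutations, reference_nt, spec,
                            sample_id = NA_character_) {
  width <- nchar(spec$pattern)
  L <- nchar(reference_nt)
  # positions with a complete context window on both strands
  valid <- rep(TRUE, L)
  lo <- max(spec$offset, spec$rc_offset) - 1L
  hi <- max(width - spec$offset, width - spec$rc_offset)
  if (lo > 0) valid[seq_len(min(lo, L))] <- FALSE
  if (hi > 0) valid[seq.int(max(1L, L - hi + 1L), L)] <- FALSE
  class_mask <- base_class_sites(reference_nt, spec$base_class) & valid
  motif_mask <- motif_site_map(reference_nt, spec) & class_mask
  p0 <- sum(motif_mask) / sum(class_mask)
  in_class <- if (spec$base_class == "GC") {
    mutations$from %in% c("G", "C")
  } else {
    mutations$from %in% c("A", "T")
  }
  mm <- mutations[in_class & valid[mutations$position], , drop = FALSE]
  if (nrow(mm) == 0) {
    return(tibble(sample_id = sample_id, motif = spec$name, h = 0L, n = 0L,
                  p0 = p0, p_value = NA_real_, testable = FALSE))
  }
  hit <- if (!is.na(spec$from)) {
    signature_match(mm, reference_nt, spec)
  } else {
    motif_mask[mm$position]
  }
  h <- sum(hit); n <- sum(!hit)
  p <- pbinom(h - 1L, size = h + n, prob = p0, lower.tail = FALSE)
  tibble(sample_id = sample_id, motif = spec$name, h = h, n = n,
         p0 = p0, p_value = p, testable = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment, monotone and capped at 1,
#' order-preserving with the input.
#'
#' @param p_values Numeric vector in \[0, 1\] (NAs passed through).
#' @return Adjusted p values.
#' @export
bh_correct <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Hotspot enrichment across samples with sample-level BH correction
#'
#' Runs [enrichment_test()] per sample for each motif and adjusts p values
#' across samples within each motif family (`bh_scope = "across_samples"`,
#' the default) or across motifs within each sample
#' (`bh_scope = "within_sample"`).
#'
#' @param mutations_by_sample Named list of mutation tibbles, one per sample.
#' @param references Named character vector/list of CDC references keyed like
#'   `mutations_by_sample`, or a single reference recycled for all.
#' @param specs List of `motif_spec`s (default [builtin_motifs()]).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param bh_scope Scope of the BH correction.
#' @return Tibble of enrichment results with `p_adjusted` and `significant`.
#' @export
enrichment_table <- function(mutations_by_sample, references,
                             specs = builtin_motifs(), alpha = 0.05,
                             bh_scope = c("across_samples", "within_sample")) {
  bh_scope <- match.arg(bh_scope)
  ids <- names(mutations_by_sample)
  if (length(references) == 1 && is.null(names(references))) {
    references <- setNames(rep(list(references[[1]]), length(ids)), ids)
  }
  res <- bind_rows(lapply(ids, function(sid) {
    bind_rows(lapply(specs, function(sp) {
      enrichment_test(mutations_by_sample[[sid]], references[[sid]], sp,
                      sample_id = sid)
    }))
  }))
  grp <- if (bh_scope == "across_samples") res$motif else res$sample_id
  res$p_adjusted <- NA_real_
  for (g in unique(grp)) {
    sel <- grp == g & res$testable
    res$p_adjusted[sel] <- bh_correct(res$p_value[sel])
  }
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  attr(res, "bh_scope") <- bh_scope
  res
}

#' Category fractions of a mutation set
#'
#' Fractions of mutations in the four mechanistic categories (AID hotspot,
#' AID coldspot, Pol-eta hotspot, other/unclear) on the given reference
#' background.
#'
#' @param mutations Mutation tibble.
#' @param reference_nt Reference background.
#' @return One-row tibble of the four fractions plus `n_mutations`; all-NA
#'   fractions when there are no mutations.
#' @export
category_fractions <- function(mutations, reference_nt) {
  if (nrow(mutations) == 0) {
    return(tibble(aid_hotspot = NA_real_, aid_coldspot = NA_real_,
                  poleta_hotspot = NA_real_, other = NA_real_,
                  n_mutations = 0L))
  }
  cl <- classify_mutations(mutations, reference_nt)
  tab <- table(cl$category) / nrow(cl)
  out <- as_tibble(as.list(as.numeric(tab)), .name_repair = "minimal")
  names(out) <- names(tab)
  out$n_mutations <- nrow(cl)
  out
}

#' Compare category fractions between two groups by paired t test
#'
#' @param fractions_a,fractions_b Tibbles of per-sample category fractions
#'   (rows aligned by sample); samples with no mutations in either group are
#'   excluded from the pairing.
#' @return Tibble: `category`, `mean_difference` (a minus b), `p_value`.
#' @export
compare_category_fractions <- function(fractions_a, fractions_b) {
  cats <- c("aid_hotspot", "aid_coldspot", "poleta_hotspot", "other")
  bind_rows(lapply(cats, function(cc) {
    a <- fractions_a[[cc]]; b <- fractions_b[[cc]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2 || all(a[ok] - b[ok] == 0)) {
      return(tibble(category = cc, mean_difference = mean(a[ok] - b[ok]),
                    p_value = NA_real_))
    }
    tt <- t.test(a[ok], b[ok], paired = TRUE)
    tibble(category = cc, mean_difference = unname(tt$estimate),
           p_value = tt$p.value)
  }))
}

#' Transition:transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else is a transversion. With
#' no transversions the ratio is infinite and, in grouped summaries, excluded
#' from medians with a warning.
#'
#' @param mutations Mutation tibble.
#' @return Scalar ratio (possibly `Inf`; `NaN` with no mutations).
#' @export
ts_tv_ratio <- function(mutations) {
  if (nrow(mutations) == 0) return(NaN)
  ts <- is_transition(mutations$from, mutations$to)
  sum(ts) / sum(!ts)
}

#' @noRd
is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

#' Per-sample Ts:Tv ratios and the group median
#'
#' @param mutations_by_sample Named list of mutation tibbles.
#' @return List: `per_sample` tibble (`sample_id`, `ts`, `tv`, `ratio`) and
#'   `median` over finite per-sample ratios.
#' @export
ts_tv_by_sample <- function(mutations_by_sample) {
  per <- bind_rows(lapply(names(mutations_by_sample), function(sid) {
    m <- mutations_by_sample[[sid]]
    ts <- sum(is_transition(m$from, m$to))
    tibble(sample_id = sid, ts = ts, tv = nrow(m) - ts,
           ratio = ts / (nrow(m) - ts))
  }))
  inf <- is.infinite(per$ratio)
  if (any(inf)) {
    warning(sum(inf), " sample(s) with no transversions excluded from the median")
  }
  list(per_sample = per, median = median(per$ratio[is.finite(per$ratio)]))
}

#' Select non-productive comparator sequences
#'
#' Non-productive rearrangements with pooled frequency at or above the
#' expansion sensitivity threshold; their mutations (called against their own
#' family consensus) form a comparator record free of antigen selection.
#'
#' @param records Family-annotated rearrangement tibble (with `clone_id`).
#' @param threshold An `expansion_threshold` or bare fraction.
#' @return Tibble of qualifying unique sequences with `clone_id`,
#'   `sequence_id`, `sequence_nt`, `umi_count`, `frequency`.
#' @export
select_nonproductive_comparators <- function(records, threshold) {
  thr <- if (inherits(threshold, "expansion_threshold")) {
    threshold$threshold_fraction
  } else {
    threshold
  }
  np <- records %>% filter(!.data$productive)
  if (nrow(np) == 0) return(tibble(clone_id = character(), sequence_id = character(),
                                   sequence_nt = character(), umi_count = integer(),
                                   frequency = numeric()))
  np %>%
    group_by(.data$clone_id) %>%
    mutate(family_total = sum(.data$umi_count)) %>%
    group_by(.data$clone_id, .data$sequence_nt, .data$family_total) %>%
    summarise(sequence_id = min(.data$sequence_id),
              umi_count = sum(.data$umi_count), .groups = "drop") %>%
    mutate(frequency = .data$umi_count / .data$family_total) %>%
    filter(.data$frequency >= thr) %>%
    select("clone_id", "sequence_id", "sequence_nt", "umi_count", "frequency") %>%
    arrange(.data$clone_id, .data$sequence_id)
}
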