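# Replicate-concordance sensitivity threshold for subclonal expansion, and
# conversion of subclone frequencies into absolute blood concentrations.
#
# Samples sequenced as several fixed-cell-count aliquots (default 25,000
# cells) of one blood draw let sampling noise be separated from genuine
# B-cell expansion: a subclone recurring across most aliquots must come from
# expanded cells. The 25th percentile of the pooled frequency distribution of
# such concordant subclones is the cohort-wide expansion threshold.

#' Concordant subclones of a replicate set
#'
#' Returns the non-CDC unique sequences observed (UMI count >= 1) in at least
#' `ceil(min_replicate_fraction * n_replicates)` replicates, with their pooled
#' frequency: summed UMIs across replicates divided by the family's total
#' UMIs across replicates (CDC included in the denominator).
#'
#' @param repset Tibble with columns `sequence_id`, `replicate_id`,
#'   `umi_count` for one clonal family across replicates.
#' @param cdc_id CDC sequence id (excluded from the subclone set).
#' @param min_replicate_fraction Concordance requirement (default 0.75, i.e.
#'   at least three quarters of the replicates).
#' @param mode `"pooled"` (default): pooled frequency as above; `"mean"`:
#'   mean of per-replicate frequencies over all replicates.
#' @return Tibble `sequence_id`, `n_replicates_present`, `frequency`.
#' @export
concordant_subclones <- function(repset, cdc_id,
                                 min_replicate_fraction = 0.75,
                                 mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  reps <- unique(repset$replicate_id)
  n_rep <- length(reps)
  if (n_rep < 2) stop("replicate set must contain at least 2 replicates")
  need <- ceiling(min_replicate_fraction * n_rep)
  total <- sum(repset$umi_count)
  per_rep_tot <- repset %>%
    group_by(.data$replicate_id) %>%
    summarise(rep_total = sum(.data$umi_count), .groups = "drop")
  sub <- repset %>%
    filter(.data$sequence_id != cdc_id, .data$umi_count >= 1) %>%
    left_join(per_rep_tot, by = "replicate_id") %>%
    group_by(.data$sequence_id) %>%
    summarise(n_replicates_present = n_distinct(.data$replicate_id),
              pooled = sum(.data$umi_count) / total,
              mean_freq = sum(.data$umi_count / .data$rep_total) / n_rep,
              .groups = "drop") %>%
    filter(.data$n_replicates_present >= need)
  sub$frequency <- if (mode == "pooled") sub$pooled else sub$mean_freq
  sub %>% select("sequence_id", "n_replicates_present", "frequency") %>%
    arrange(.data$sequence_id)
}

#' Subclonal expansion sensitivity threshold
#'
#' Empirical percentile (linear interpolation between order statistics,
#' inclusive endpoints — R quantile type 7) of the pooled frequency
#' distribution of concordant subclones across all replicate-bearing samples.
#' The default 25th percentile gives a conservative cohort-wide cutoff below
#' which a subclone frequency cannot be distinguished from sampling.
#'
#' @param frequencies Numeric vector of concordant-subclone frequencies,
#'   pooled over samples.
#' @param percentile Percentile in \[0, 100\] (default 25).
#' @return Object of class `expansion_threshold`: list with
#'   `threshold_fraction`, `threshold_percent`, `percentile`, and the
#'   `frequencies` it was drawn from.
#' @export
expansion_threshold <- function(frequencies, percentile = 25) {
  if (length(frequencies) == 0) stop("empty frequency distribution")
  stopifnot(percentile >= 0, percentile <= 100)
  thr <- unname(quantile(frequencies, probs = percentile / 100, type = 7))
  structure(
    list(threshold_fraction = thr, threshold_percent = 100 * thr,
         percentile = percentile, frequencies = frequencies),
    class = "expansion_threshold"
  )
}

#' @export
print.expansion_threshold <- function(x, ...) {
  cat(sprintf("Subclonal expansion threshold: %.6g (%.4g%%), %gth percentile of %d concordant subclone frequencies\n",
              x$threshold_fraction, x$threshold_percent, x$percentile,
              length(x$frequencies)))
  invisible(x)
}

#' Absolute subclone abundance in blood
#'
#' Converts a within-family mRNA frequency into cells per microliter of
#' blood: `frequency * alc_per_ul * cll_fraction`, where `alc_per_ul` is the
#' absolute lymphocyte count and `cll_fraction` the CD5+CD19+ fraction of
#' lymphocytes by flow cytometry.
#'
#' @param frequency Subclone frequency (fraction of family UMIs); vectorized.
#' @param alc_per_ul Absolute lymphocyte count per microliter (> 0).
#' @param cll_fraction Fraction of lymphocytes that are CLL cells, in \[0, 1\].
#' @return Cells per microliter.
#' @export
absolute_abundance <- function(frequency, alc_per_ul, cll_fraction) {
  if (any(frequency < 0 | frequency > 1)) stop("frequency outside [0, 1]")
  stopifnot(alc_per_ul > 0, cll_fraction >= 0, cll_fraction <= 1)
  frequency * alc_per_ul * cll_fraction
}

#' Call expanded subclones against a sensitivity threshold
#'
#' A subclone is expanded iff its pooled frequency is greater than or equal
#' to the threshold (inclusive).
#'
#' @param frequency Numeric vector of subclone frequencies.
#' @param threshold An `expansion_threshold` object or a bare fraction.
#' @return Logical vector.
#' @export
call_expanded <- function(frequency, threshold) {
  thr <- if (inherits(threshold, "expansion_threshold")) {
    threshold$threshold_fraction
  } else {
    threshold
  }
  frequency >= thr
}
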