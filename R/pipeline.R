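# End-to-end pipeline: simulate (or load) -> UMI filter -> clonal families ->
# CDC/subclone statistics -> expansion threshold -> lineage/complexity ->
# motif enrichment and Ts:Tv -> selection strength. One deterministic pass
# over one sample, returning every stage's table.

#' Run the intraclonal analysis pipeline on a rearrangement table
#'
#' @param rearrangements AIRR-style rearrangement tibble (possibly several
#'   replicates of one sample).
#' @param regions Region map tibble (`start`, `end`, `type`); default
#'   [default_region_map()].
#' @param min_umis,min_reads_per_umi UMI-support filter thresholds.
#' @param clone_threshold Junction-distance clustering cutoff.
#' @param expansion_percentile Percentile defining the sensitivity threshold.
#' @return List of class `intraclone_result`: `filtered` (records kept),
#'   `records` (family-annotated), `family` (collapsed CLL family),
#'   `cdc_id`, `stats` (subclone statistics), `threshold`
#'   (`expansion_threshold` or NULL when replicates are insufficient),
#'   `expansion` (per concordant subclone), `tree`, `complexity`,
#'   `enrichment`, `tstv`, `selection` (per region), `nonproductive`
#'   (comparator sequences).
#' @export
run_pipeline <- function(rearrangements, regions = default_region_map(),
                         min_umis = 3L, min_reads_per_umi = 5L,
                         clone_threshold = 0.07,
                         expansion_percentile = 25) {
  filtered <- filter_by_umi_support(rearrangements, min_umis, min_reads_per_umi)
  records <- cluster_clones(filtered, threshold = clone_threshold)
  fam_records <- records %>% filter(.data$is_cll_family, .data$productive)
  family <- collapse_family(fam_records)
  cdc_id <- identify_cdc(family)
  stats <- subclone_stats(family, cdc_id)
  cdc_nt <- family$sequence_nt[family$sequence_id == cdc_id][1]

  threshold <- NULL
  expansion <- NULL
  if ("replicate_id" %in% names(fam_records) &&
      length(unique(fam_records$replicate_id)) >= 2) {
    # pooled frequencies keyed by unique sequence (representative id)
    rep_tbl <- fam_records %>%
      left_join(family %>% select("sequence_nt", rep_seq_id = "sequence_id"),
                by = "sequence_nt") %>%
      group_by(sequence_id = .data$rep_seq_id, .data$replicate_id) %>%
      summarise(umi_count = sum(.data$umi_count), .groups = "drop")
    conc <- concordant_subclones(rep_tbl, cdc_id)
    if (nrow(conc) > 0) {
      threshold <- expansion_threshold(conc$frequency, expansion_percentile)
      conc$expanded <- call_expanded(conc$frequency, threshold)
    }
    expansion <- conc
  }

  tree <- build_lineage(family, cdc_id)
  complexity <- classify_complexity(tree)

  variants <- family %>% filter(.data$sequence_id != cdc_id)
  post_cdc_mutations <- bind_rows(lapply(variants$sequence_nt, call_mutations,
                                         cdc_nt = cdc_nt))
  enrichment <- enrichment_table(
    setNames(list(post_cdc_mutations), fam_records$sample_id[1]),
    references = list(cdc_nt)[1],
    bh_scope = "within_sample"
  )
  tstv <- ts_tv_ratio(post_cdc_mutations)
  selection <- selection_by_region(variants$sequence_nt, cdc_nt, regions)

  nonproductive <- if (!is.null(threshold)) {
    select_nonproductive_comparators(records, threshold)
  } else {
    NULL
  }

  structure(list(
    filtered = filtered, records = records, family = family,
    cdc_id = cdc_id, stats = stats, threshold = threshold,
    expansion = expansion, tree = tree, complexity = complexity,
    post_cdc_mutations = post_cdc_mutations,
    enrichment = enrichment, tstv = tstv, selection = selection,
    nonproductive = nonproductive
  ), class = "intraclone_result")
}

#' @export
print.intraclone_result <- function(x, ...) {
  cat("Intraclonal diversification analysis\n")
  cat(sprintf("  CDC: %s; %d unique family sequences\n", x$cdc_id, nrow(x$family)))
  cat(sprintf("  variant fraction: %.4f; PSC fraction: %.5f\n",
              x$stats$variant_fraction, x$stats$psc_fraction_total))
  if (!is.null(x$threshold)) {
    cat(sprintf("  expansion threshold: %.4g%%\n", x$threshold$threshold_percent))
  }
  print(x$complexity)
  cat(sprintf("  post-CDC Ts:Tv: %.3f over %d mutations\n", x$tstv,
              nrow(x$post_cdc_mutations)))
  invisible(x)
}

#' Deterministic digest of a pipeline result
#'
#' Serializes the scientific content of an `intraclone_result` (tables,
#' threshold, tree topology, densities) into a canonical character vector,
#' for byte-identity comparison of repeated runs.
#'
#' @param result An `intraclone_result`.
#' @return Character vector.
#' @export
pipeline_digest <- function(result) {
  fmt_tbl <- function(tb) {
    if (is.null(tb)) return("NULL")
    paste(utils::capture.output(utils::write.csv(as.data.frame(tb), row.names = FALSE)),
          collapse = "\n")
  }
  c(
    fmt_tbl(result$family), result$cdc_id, fmt_tbl(result$stats),
    if (is.null(result$threshold)) "no-threshold" else
      sprintf("%.12g", result$threshold$threshold_fraction),
    fmt_tbl(result$expansion),
    fmt_tbl(result$tree$nodes),
    sprintf("%s|%d", result$complexity$class %||% "NA",
            result$complexity$max_downstream_count),
    fmt_tbl(result$post_cdc_mutations),
    fmt_tbl(result$enrichment %>% select(-dplyr::any_of("note"))),
    sprintf("%.12g", result$tstv),
    vapply(result$selection, function(sr) {
      sprintf("%.12g|%.12g|%.12g", sr$mode, sr$ci[1], sr$ci[2])
    }, character(1)),
    fmt_tbl(result$nonproductive)
  )
}
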