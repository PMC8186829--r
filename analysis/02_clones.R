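#!/usr/bin/env Rscript
# UMI-support filtering, clonal family inference, CDC identification, and
# subclone frequency statistics per sample (the variant-fraction and PSC
# numbers of the cohort overview).
#
# Input:  results/sim/<sample>.tsv
# Output: results/clones/<sample>_families.tsv, results/clones/stats.tsv

suppressPackageStartupMessages({
  library(intraclone)
  library(dplyr)
})

in_dir <- "results/sim"
out_dir <- "results/clones"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

samples <- sub("\\.tsv$", "", setdiff(list.files(in_dir, "^P\\d+\\.tsv$"), NA))
stats_rows <- list()

for (sid in samples) {
  rec <- read_rearrangements(file.path(in_dir, paste0(sid, ".tsv")))
  kept <- filter_by_umi_support(rec)
  cl <- cluster_clones(kept)
  readr::write_tsv(cl, file.path(out_dir, paste0(sid, "_families.tsv")))
  fam <- collapse_family(cl %>% filter(is_cll_family, productive))
  cdc <- identify_cdc(fam)
  st <- subclone_stats(fam, cdc)
  chim <- flag_chimeras(fam, cdc)
  stats_rows[[sid]] <- tibble(
    sample_id = sid,
    n_records = nrow(rec),
    n_kept = nrow(kept),
    n_families = dplyr::n_distinct(cl$clone_id),
    n_unique_family_seqs = nrow(fam),
    cdc_sequence_id = cdc,
    n_flagged_chimeras = length(chim)
  ) %>% bind_cols(st)
  message(sprintf("%s: %d/%d records kept, variant fraction %.3f, PSC %.4f of total",
                  sid, nrow(kept), nrow(rec), st$variant_fraction,
                  st$psc_fraction_total))
}

stats <- bind_rows(stats_rows)
readr::write_tsv(stats, file.path(out_dir, "stats.tsv"))
message(sprintf("cohort median variant fraction: %.1f%%",
                100 * median(stats$variant_fraction)))
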