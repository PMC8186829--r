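#!/usr/bin/env Rscript
# Mutation-mechanism attribution: hotspot enrichment tests (AID, Pol-eta,
# APOBEC, aging/cancer signature contexts) with BH correction across
# samples, category fractions for CDC vs post-CDC vs non-productive
# mutations, and Ts:Tv spectra by complexity stratum.
#
# Input:  results/clones/, results/sim/, results/lineage/complexity.tsv,
#         results/expansion/threshold.json
# Output: results/motifs/enrichment.tsv, category_fractions.tsv, tstv.tsv

suppressPackageStartupMessages({
  library(intraclone)
  library(dplyr)
})

out_dir <- "results/motifs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
complexity <- readr::read_tsv("results/lineage/complexity.tsv",
                              show_col_types = FALSE)
thr <- jsonlite::read_json("results/expansion/threshold.json")$threshold_fraction

samples <- sub("_families\\.tsv$", "",
               list.files("results/clones", "_families\\.tsv$"))
post_muts <- list(); cdc_refs <- list()
frac_rows <- list()

for (sid in samples) {
  cl <- readr::read_tsv(file.path("results/clones", paste0(sid, "_families.tsv")),
                        show_col_types = FALSE)
  fam <- collapse_family(cl %>% filter(is_cll_family, productive))
  cdc <- identify_cdc(fam)
  cdc_nt <- fam$sequence_nt[fam$sequence_id == cdc]
  variants <- fam %>% filter(sequence_id != cdc)
  pm <- bind_rows(lapply(variants$sequence_nt, call_mutations, cdc_nt = cdc_nt))
  post_muts[[sid]] <- pm
  cdc_refs[[sid]] <- cdc_nt

  # non-productive comparator mutations, called against the family consensus
  np <- select_nonproductive_comparators(cl, thr)
  np_m <- tibble(position = integer(), from = character(), to = character())
  if (nrow(np) > 0) {
    for (cid in unique(np$clone_id)) {
      np_fam <- collapse_family(cl %>% filter(clone_id == cid))
      np_cdc_nt <- np_fam$sequence_nt[np_fam$sequence_id == identify_cdc(np_fam)]
      sub <- np %>% filter(clone_id == cid, sequence_nt != np_cdc_nt)
      np_m <- bind_rows(np_m, bind_rows(
        lapply(sub$sequence_nt, call_mutations, cdc_nt = np_cdc_nt)))
    }
  }
  frac_rows[[sid]] <- bind_rows(
    category_fractions(pm, cdc_nt) %>% mutate(group = "post_cdc"),
    category_fractions(np_m, cdc_nt) %>% mutate(group = "non_productive")
  ) %>% mutate(sample_id = sid)
}

enr <- enrichment_table(post_muts, cdc_refs, bh_scope = "across_samples")
readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
sig <- enr %>% group_by(motif) %>% summarise(pct = 100 * mean(significant))
message("significant targeting by motif (% of samples):")
print(as.data.frame(sig), row.names = FALSE)

fracs <- bind_rows(frac_rows)
readr::write_tsv(fracs, file.path(out_dir, "category_fractions.tsv"))

tstv <- ts_tv_by_sample(post_muts)
per <- tstv$per_sample %>% left_join(complexity, by = "sample_id")
readr::write_tsv(per, file.path(out_dir, "tstv.tsv"))
med_by <- per %>% filter(is.finite(ratio)) %>% group_by(complexity) %>%
  summarise(median_tstv = median(ratio), .groups = "drop")
message(sprintf("post-CDC Ts:Tv median: %.2f", tstv$median))
print(as.data.frame(med_by), row.names = FALSE)
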