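#!/usr/bin/env Rscript
# Selection-strength analysis: posterior Sigma for replacement vs silent
# mutations in CDRs and FRs, for post-CDC mutations stratified by
# complexity, with pairwise group comparisons.
#
# Input:  results/clones/, results/lineage/complexity.tsv
# Output: results/selection/selection.tsv, results/selection/density.tsv

suppressPackageStartupMessages({
  library(intraclone)
  library(dplyr)
})

`%||%` <- function(x, y) if (is.null(x)) y else x

out_dir <- "results/selection"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
complexity <- readr::read_tsv("results/lineage/complexity.tsv",
                              show_col_types = FALSE)
regions <- default_region_map()

samples <- sub("_families\\.tsv$", "",
               list.files("results/clones", "_families\\.tsv$"))
groups <- list()  # pooled R/S counts per (complexity, region)

for (sid in samples) {
  cl <- readr::read_tsv(file.path("results/clones", paste0(sid, "_families.tsv")),
                        show_col_types = FALSE)
  fam <- collapse_family(cl %>% filter(is_cll_family, productive))
  cdc <- identify_cdc(fam)
  cdc_nt <- fam$sequence_nt[fam$sequence_id == cdc]
  variants <- fam %>% filter(sequence_id != cdc)
  muts <- bind_rows(lapply(variants$sequence_nt, call_mutations, cdc_nt = cdc_nt))
  if (nrow(muts) == 0) next
  muts <- classify_r_s(muts, cdc_nt)
  muts$region <- region_of_position(muts$position, regions)
  cx <- complexity$complexity[complexity$sample_id == sid]
  pi0 <- expected_r_fraction(cdc_nt, regions)
  for (ty in c("CDR", "FR")) {
    key <- paste(cx, ty, sep = "|")
    sub <- muts %>% filter(region == ty, rs_class %in% c("R", "S"))
    if (nrow(sub) == 0) next
    g <- groups[[key]] %||% list(r = 0L, s = 0L, pi0 = numeric(0))
    g$r <- g$r + sum(sub$rs_class == "R")
    g$s <- g$s + sum(sub$rs_class == "S")
    g$pi0 <- c(g$pi0, pi0$pi0[pi0$region_type == ty])
    groups[[key]] <- g
  }
}

res_rows <- list(); dens_rows <- list(); fits <- list()
for (key in names(groups)) {
  g <- groups[[key]]
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  sr <- selection_strength(g$r, g$s, mean(g$pi0))
  fits[[key]] <- sr
  res_rows[[key]] <- tibble(
    group = paste0("post_cdc_", parts[1]), region = parts[2],
    r = g$r, s = g$s, pi0 = mean(g$pi0),
    sigma_mode = sr$mode, ci_lower = sr$ci[1], ci_upper = sr$ci[2]
  )
  dens_rows[[key]] <- tibble(group = paste0("post_cdc_", parts[1]),
                             region = parts[2], sigma = sr$sigma,
                             density = sr$density)
}
res <- bind_rows(res_rows) %>% arrange(region, group)
readr::write_tsv(res, file.path(out_dir, "selection.tsv"))
readr::write_tsv(bind_rows(dens_rows), file.path(out_dir, "density.tsv"))
print(as.data.frame(res), row.names = FALSE)

for (ty in c("CDR", "FR")) {
  hi <- fits[[paste("High", ty, sep = "|")]]
  lo <- fits[[paste("Low", ty, sep = "|")]]
  if (!is.null(hi) && !is.null(lo)) {
    cmp <- compare_selection(hi, lo)
    message(sprintf("%s: High vs Low complexity, p = %.3g", ty, cmp$p_value))
  }
}
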