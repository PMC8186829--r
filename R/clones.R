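# Clonal family inference: junction-distance clustering, CDC identification,
# and subclone frequency statistics.

#' Normalized junction (HCDR3) hamming distance
#'
#' Distance between two junction nucleotide strings: number of mismatching
#' positions divided by the number of compared positions. Positions where
#' either string carries N are excluded from both numerator and denominator.
#' Junctions of unequal length are defined to have distance 1 and are never
#' clustered together.
#'
#' @param a,b Junction nucleotide strings.
#' @return Distance in \[0, 1\].
#' @export
junction_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty junction")
  if (nchar(a) != nchar(b)) return(1)
  av <- nt_chars(a); bv <- nt_chars(b)
  keep <- comparable_positions(av, bv)
  if (!any(keep)) return(0)
  sum(av[keep] != bv[keep]) / sum(keep)
}

#' Strip the allele designation from a V/J gene call
#' @noRd
gene_of_call <- function(call) {
  sub("\\*.*$", "", sub(",.*$", "", call))
}

#' Cluster rearrangements into clonal families
#'
#' Partitions records by (V gene, J gene, junction length) — alleles are
#' collapsed to the gene level — then applies single-linkage hierarchical
#' clustering on the normalized junction hamming distance, cutting at
#' `threshold`. Two sequences belong to the same family iff they are connected
#' by a chain of junctions each within `threshold` of the next. Within each
#' sample the family with the largest total UMI count is flagged as the CLL
#' clonal family (`is_cll_family`); secondary families are retained, never
#' dropped.
#'
#' @param records Rearrangement tibble (may span replicates; clustering uses
#'   unique junction strings).
#' @param threshold Single-linkage cutoff on junction distance (default 0.07).
#' @return `records` with added columns `clone_id` and `is_cll_family`.
#' @export
cluster_clones <- function(records, threshold = 0.07) {
  stopifnot(nrow(records) > 0)
  grp_key <- paste(gene_of_call(records$v_call), gene_of_call(records$j_call),
                   nchar(records$junction_nt), sep = "|")
  clone_id <- character(nrow(records))
  for (g in unique(grp_key)) {
    idx <- which(grp_key == g)
    juncs <- unique(records$junction_nt[idx])
    if (length(juncs) == 1) {
      memb <- setNames(1L, juncs)
    } else {
      n <- length(juncs)
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          d[i, j] <- d[j, i] <- junction_distance(juncs[i], juncs[j])
        }
      }
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      memb <- setNames(stats::cutree(hc, h = threshold), juncs)
    }
    clone_id[idx] <- paste0(g, "|", memb[records$junction_nt[idx]])
  }
  # relabel compactly and deterministically (by first appearance after sort)
  lv <- sort(unique(clone_id))
  records$clone_id <- paste0("clone_", match(clone_id, lv))
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample"
  # largest family per sample is the CLL family; ties broken by clone_id order
  fam_tot <- records %>%
    group_by(.data$sample_id, .data$clone_id) %>%
    summarise(total = sum(.data$umi_count), .groups = "drop") %>%
    group_by(.data$sample_id) %>%
    arrange(dplyr::desc(.data$total), .data$clone_id, .by_group = TRUE) %>%
    mutate(is_cll_family = dplyr::row_number() == 1L) %>%
    ungroup() %>%
    select("sample_id", "clone_id", "is_cll_family")
  records %>% left_join(fam_tot, by = c("sample_id", "clone_id"))
}

#' Collapse a clonal family to unique sequences with aggregated UMI counts
#'
#' Sums UMI counts over replicates for each unique nucleotide sequence in one
#' clonal family. Sequence identity is exact string identity; the
#' representative `sequence_id` of each unique sequence is the
#' lexicographically smallest id carrying it.
#'
#' @param records Rearrangement tibble restricted to one clonal family.
#' @return Tibble with `sequence_id`, `sequence_nt`, `umi_count` (aggregated),
#'   `productive`, sorted by decreasing UMI count then `sequence_nt`.
#' @export
collapse_family <- function(records) {
  stopifnot(nrow(records) > 0)
  records %>%
    group_by(.data$sequence_nt) %>%
    summarise(sequence_id = min(.data$sequence_id),
              umi_count = sum(.data$umi_count),
              productive = .data$productive[1],
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$umi_count), .data$sequence_nt) %>%
    select("sequence_id", "sequence_nt", "umi_count", "productive")
}

#' Identify the clinically dominant clone (CDC) of a family
#'
#' The CDC is the unique sequence with the maximal aggregated UMI count; ties
#' are broken deterministically by the lexicographically smallest
#' `sequence_nt`.
#'
#' @param family Collapsed family tibble (see [collapse_family()]).
#' @return The CDC `sequence_id`.
#' @export
identify_cdc <- function(family) {
  if (nrow(family) == 0) stop("empty clonal family")
  top <- family[family$umi_count == max(family$umi_count), , drop = FALSE]
  top$sequence_id[order(top$sequence_nt)][1]
}

#' Subclone frequency statistics of a clonal family
#'
#' Variants are members whose full aligned V(D)J nucleotide sequence differs
#' from the CDC at one or more positions (N treated as wildcard-equal). The
#' predominant subclone (PSC) is the most abundant variant. All fractions are
#' computed on UMI (mRNA molecule) counts.
#'
#' @param family Collapsed family tibble.
#' @param cdc_id CDC sequence id; computed with [identify_cdc()] if missing.
#' @return One-row tibble: `variant_fraction` (variant UMIs / family UMIs),
#'   `psc_sequence_id` (NA if no variants), `psc_fraction_total` (PSC UMIs /
#'   family UMIs), `psc_fraction_of_variants` (PSC UMIs / variant UMIs).
#' @export
subclone_stats <- function(family, cdc_id = identify_cdc(family)) {
  stopifnot(cdc_id %in% family$sequence_id)
  cdc_nt <- family$sequence_nt[family$sequence_id == cdc_id][1]
  is_variant <- !vapply(family$sequence_nt, seq_identical_wildcard, logical(1),
                        b = cdc_nt)
  total <- sum(family$umi_count)
  var_umis <- sum(family$umi_count[is_variant])
  if (!any(is_variant)) {
    return(tibble(variant_fraction = 0, psc_sequence_id = NA_character_,
                  psc_fraction_total = 0, psc_fraction_of_variants = NA_real_))
  }
  vars <- family[is_variant, , drop = FALSE]
  vars <- vars[order(-vars$umi_count, vars$sequence_nt), , drop = FALSE]
  psc <- vars[1, ]
  tibble(
    variant_fraction = var_umis / total,
    psc_sequence_id = psc$sequence_id,
    psc_fraction_total = psc$umi_count / total,
    psc_fraction_of_variants = psc$umi_count / var_umis
  )
}

#' Flag putative chimeric members of a clonal family
#'
#' A member is flagged as a putative PCR chimera when its mutation set
#' (relative to the CDC) is exactly the union of the mutation sets of two
#' other members, neither of which is nested in the other. Flagged sequences
#' are reported, never removed.
#'
#' @param family Collapsed family tibble.
#' @param cdc_id CDC sequence id.
#' @return Character vector of flagged `sequence_id`s (possibly empty).
#' @export
flag_chimeras <- function(family, cdc_id = identify_cdc(family)) {
  cdc_nt <- family$sequence_nt[family$sequence_id == cdc_id][1]
  sets <- lapply(family$sequence_nt, function(s) {
    m <- call_mutations(s, cdc_nt)
    mutation_keys(m)
  })
  names(sets) <- family$sequence_id
  nz <- which(vapply(sets, length, integer(1)) > 0)
  flagged <- character(0)
  for (k in nz) {
    target <- sets[[k]]
    if (length(target) < 2) next
    others <- setdiff(nz, k)
    hit <- FALSE
    for (i in others) {
      a <- sets[[i]]
      if (!all(a %in% target) || length(a) == length(target)) next
      for (j in others) {
        if (j <= i) next
        b <- sets[[j]]
        if (!all(b %in% target)) next
        if (all(a %in% b) || all(b %in% a)) next
        if (setequal(union(a, b), target)) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) flagged <- c(flagged, names(sets)[k])
  }
  flagged
}
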