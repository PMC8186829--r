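# Synthetic-repertoire generator with full ground truth.
#
# Emulates the data structure the analysis assumes: one dominant CDC
# sequence with a mutation-nested lineage of lower-frequency descendant
# subclones, mutations laid down by a mixture of machineries (AID-hotspot-
# biased and Pol-eta-biased with transition bias, plus a context-free
# process), power-law subclone abundances split multinomially across
# fixed-cell-count replicates with Poisson mRNA molecules per cell,
# non-productive comparator lineages, and exponential clinical event times
# with configurable group hazards. Everything is deterministic under the
# configured seed and every latent quantity is returned as ground truth.

#' Default V(D)J region map used by the simulator
#'
#' Codon-aligned IMGT-like region boundaries over a 366 nt V(D)J
#' rearrangement (1-based closed intervals).
#'
#' @return Tibble `region`, `start`, `end`, `type` (CDR/FR).
#' @export
default_region_map <- function() {
  tibble(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    start = c(1L, 79L, 103L, 154L, 178L, 292L, 334L),
    end = c(78L, 102L, 153L, 177L, 291L, 333L, 366L),
    type = c("FR", "CDR", "FR", "CDR", "FR", "CDR", "FR")
  )
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis is designed for:
#' replicates of 25,000 cells, a CDC carrying ~92% of family mRNA (median
#' variant fraction 8%), an AID-dominated machinery mixture with 5-fold
#' hotspot weighting and transition probability 0.6 (the ~1.5:1 Ts:Tv of
#' canonical SHM), a context-free component, and power-law subclone
#' abundances.
#'
#' @param seed Integer seed; the generator is deterministic under it.
#' @param germline Optional germline V(D)J nucleotide string (366 nt,
#'   stop-free in frame); randomly generated when `NULL`.
#' @param n_subclones Number of post-CDC subclones in the lineage.
#' @param pre_cdc_mutations Germline-to-CDC mutation count (IGHV mutation
#'   load of the clone; 0 emulates U-CLL).
#' @param cdc_share Fraction of family mRNA carried by the CDC.
#' @param abundance_exponent Power-law exponent of subclone abundances.
#' @param machinery_weights Mixture weights over
#'   `c(aid, poleta, context_free)`; must sum to 1.
#' @param transition_prob Per-machinery transition probability.
#' @param hotspot_multiplier Position-weight multiplier at machinery hotspot
#'   contexts (WRC/GYW for AID, WA/TW for Pol-eta).
#' @param mutations_per_edge_mean Mean mutations per lineage edge (>= 1;
#'   one plus a Poisson excess).
#' @param n_replicates,cells_per_replicate Replicate structure of the draw.
#' @param mrna_per_cell Poisson mean mRNA molecules (UMIs) per cell.
#' @param reads_per_umi_mean Mean reads behind each UMI consensus (>= 5).
#' @param n_nonproductive Number of non-productive comparator families.
#' @param nonproductive_subclones Subclones per non-productive family.
#' @param nonproductive_cells Cells per replicate carrying each
#'   non-productive family.
#' @param sample_id,ighv_status,alc_per_ul,cll_fraction Sample metadata.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       germline = NULL,
                       n_subclones = 30L,
                       pre_cdc_mutations = 20L,
                       cdc_share = 0.92,
                       abundance_exponent = 1.5,
                       machinery_weights = c(aid = 0.45, poleta = 0.2,
                                             context_free = 0.35),
                       transition_prob = c(aid = 0.6, poleta = 0.6,
                                           context_free = 1 / 3),
                       hotspot_multiplier = 5,
                       mutations_per_edge_mean = 1.3,
                       n_replicates = 4L,
                       cells_per_replicate = 25000L,
                       mrna_per_cell = 5,
                       reads_per_umi_mean = 8,
                       n_nonproductive = 1L,
                       nonproductive_subclones = 3L,
                       nonproductive_cells = 50L,
                       sample_id = "S1",
                       ighv_status = c("M-CLL", "U-CLL"),
                       alc_per_ul = 50000,
                       cll_fraction = 0.9) {
  ighv_status <- match.arg(ighv_status)
  stopifnot(abs(sum(machinery_weights) - 1) < 1e-8,
            mutations_per_edge_mean >= 1,
            cdc_share > 0, cdc_share <= 1,
            n_replicates >= 1, cells_per_replicate >= 1)
  if (n_subclones >= cells_per_replicate) stop("more subclones than cells")
  structure(as.list(environment()), class = "sim_config")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Random stop-free germline V(D)J sequence
#' @param length_nt Sequence length (multiple of 3).
#' @return Nucleotide string.
#' @export
random_germline <- function(length_nt = 366L) {
  stopifnot(length_nt %% 3 == 0)
  codons <- setdiff(.all_codons(), .STOP_CODONS)
  paste(sample(codons, length_nt / 3, replace = TRUE), collapse = "")
}

#' @noRd
.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
}

#' Apply machinery-specific mutations to a sequence
#'
#' Positions are drawn one at a time, without replacement, with probability
#' proportional to the machinery's context weights on the current sequence
#' (hotspot contexts weighted by `hotspot_multiplier`, all other positions
#' weight 1; context masks are recomputed after each mutation). The
#' substituted base is a transition with the machinery's transition
#' probability, otherwise one of the two transversions with equal
#' probability. Uses the session RNG.
#'
#' @param sequence_nt Starting sequence.
#' @param machinery `"aid"`, `"poleta"` or `"context_free"`.
#' @param n_mutations Number of mutations to introduce.
#' @param transition_prob Transition probability.
#' @param hotspot_multiplier Context weight multiplier.
#' @param exclude_positions Positions that must not be mutated (already used
#'   elsewhere in the lineage, to keep it homoplasy-free).
#' @return List: `sequence` (mutated string), `mutations` tibble
#'   (`position`, `from`, `to`, `machinery`).
#' @export
mutate_sequence <- function(sequence_nt, machinery = c("context_free", "aid", "poleta"),
                            n_mutations, transition_prob = 1 / 3,
                            hotspot_multiplier = 5,
                            exclude_positions = integer(0)) {
  machinery <- match.arg(machinery)
  s <- nt_chars(sequence_nt)
  L <- length(s)
  used <- exclude_positions
  recs <- vector("list", n_mutations)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (k in seq_len(n_mutations)) {
    w <- rep(1, L)
    if (machinery == "aid") {
      mask <- motif_site_map(paste(s, collapse = ""), builtin_motifs()$aid_hotspot)
      w[mask] <- hotspot_multiplier
    } else if (machinery == "poleta") {
      mask <- motif_site_map(paste(s, collapse = ""), builtin_motifs()$poleta_hotspot)
      w[mask] <- hotspot_multiplier
    }
    w[used] <- 0
    if (all(w == 0)) stop("infeasible: no mutable positions left")
    pos <- sample.int(L, 1L, prob = w)
    from <- s[pos]
    to <- if (runif(1) < transition_prob) {
      transition_of[[from]]
    } else {
      sample(setdiff(c("A", "C", "G", "T"), c(from, transition_of[[from]])), 1L)
    }
    s[pos] <- to
    used <- c(used, pos)
    recs[[k]] <- tibble(position = pos, from = from, to = to,
                        machinery = machinery)
  }
  list(sequence = paste(s, collapse = ""),
       mutations = if (n_mutations == 0) {
         tibble(position = integer(), from = character(), to = character(),
                machinery = character())
       } else {
         bind_rows(recs)
       })
}

#' @noRd
.sample_machinery <- function(weights) {
  sample(names(weights), 1L, prob = weights)
}

#' Simulate a mutation-nested lineage from a root sequence
#'
#' Node 0 is the root; each subsequent node attaches uniformly at random to
#' an existing node and adds `1 + Poisson(mean - 1)` mutations drawn from the
#' machinery mixture. Mutated positions are globally unique within the
#' lineage, so mutation sets nest strictly and the lineage is homoplasy-free.
#'
#' @param root_nt Root (CDC) sequence.
#' @param config A `sim_config` (machinery mixture, edge-mutation law).
#' @param n_subclones Number of nodes to add.
#' @param exclude_positions Positions already consumed (e.g. by
#'   germline-to-CDC mutations).
#' @return List: `sequences` (named, node 0..n), `edges` tibble (`node`,
#'   `parent`), `mutations` tibble (`node`, `position`, `from`, `to`,
#'   `machinery`).
#' @export
simulate_lineage <- function(root_nt, config, n_subclones = config$n_subclones,
                             exclude_positions = integer(0)) {
  seqs <- setNames(list(root_nt), "0")
  edges <- list()
  muts <- list()
  used <- exclude_positions
  for (k in seq_len(n_subclones)) {
    parent <- as.character(sample.int(k, 1L) - 1L)
    n_mut <- 1L + rpois(1L, config$mutations_per_edge_mean - 1)
    seq_now <- seqs[[parent]]
    node_mut <- vector("list", n_mut)
    for (m in seq_len(n_mut)) {
      mach <- .sample_machinery(config$machinery_weights)
      step <- mutate_sequence(seq_now, mach, 1L,
                              transition_prob = config$transition_prob[[mach]],
                              hotspot_multiplier = config$hotspot_multiplier,
                              exclude_positions = used)
      seq_now <- step$sequence
      used <- c(used, step$mutations$position)
      node_mut[[m]] <- step$mutations
    }
    seqs[[as.character(k)]] <- seq_now
    edges[[k]] <- tibble(node = as.character(k), parent = parent)
    muts[[k]] <- bind_rows(node_mut) %>% mutate(node = as.character(k))
  }
  list(sequences = seqs,
       edges = if (n_subclones == 0) tibble(node = character(), parent = character()) else bind_rows(edges),
       mutations = if (n_subclones == 0) {
         tibble(node = character(), position = integer(), from = character(),
                to = character(), machinery = character())
       } else {
         bind_rows(muts)
       })
}

#' @noRd
.true_complexity <- function(edges) {
  if (nrow(edges) == 0) return(list(class = NA_character_, max_count = 0L))
  kids <- function(id) edges$node[edges$parent == id]
  branches <- kids("0")
  counts <- vapply(branches, function(b) {
    n <- 0L; queue <- b
    while (length(queue) > 0) {
      n <- n + length(queue)
      queue <- unlist(lapply(queue, kids), use.names = FALSE)
    }
    n
  }, integer(1))
  list(class = if (max(counts) >= 4L) "High" else "Low",
       max_count = max(counts))
}

#' Generate a complete synthetic dataset
#'
#' Produces per-replicate AIRR-style rearrangement rows for one CLL clonal
#' family (plus optional non-productive comparator families), sample
#' metadata, the region map, and the full ground truth. UMI counts arise
#' from multinomial sampling of cells into replicates followed by Poisson
#' mRNA molecules per cell; read counts guarantee at least 5 reads per UMI.
#' Deterministic under `config$seed`.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_dataset`: `rearrangements` (tibble),
#'   `metadata` (one-row tibble), `regions`, `truth` (list: `edges`,
#'   `mutations`, `shares`, `sequences`, `complexity`, `germline`,
#'   `cdc_sequence`).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  germline <- config$germline %||% random_germline()
  # germline -> CDC mutations (the clone's IGHV mutation load)
  pre <- mutate_sequence(germline, "aid", config$pre_cdc_mutations,
                         transition_prob = config$transition_prob[["aid"]],
                         hotspot_multiplier = config$hotspot_multiplier)
  cdc <- pre$sequence
  lin <- simulate_lineage(cdc, config,
                          exclude_positions = pre$mutations$position)
  n_nodes <- config$n_subclones + 1L
  shares <- if (config$n_subclones == 0) 1 else {
    w <- seq_len(config$n_subclones)^(-config$abundance_exponent)
    c(config$cdc_share, (1 - config$cdc_share) * w / sum(w))
  }
  rows <- list()
  regions <- default_region_map()
  cdr3 <- regions[regions$region == "CDR3", ]
  for (r in seq_len(config$n_replicates)) {
    rep_id <- sprintf("rep%d", r)
    cells <- as.vector(rmultinom(1L, config$cells_per_replicate, shares))
    umis <- rpois(n_nodes, cells * config$mrna_per_cell)
    extra <- rpois(n_nodes, pmax(config$reads_per_umi_mean - 5, 0) * umis)
    reads <- 5L * umis + extra
    keep <- which(umis > 0)
    rows[[rep_id]] <- tibble(
      sequence_id = sprintf("%s_seq%s", config$sample_id, names(lin$sequences)[keep]),
      sample_id = config$sample_id,
      replicate_id = rep_id,
      sequence_nt = unlist(lin$sequences[keep], use.names = FALSE),
      v_call = "IGHV3-23*01",
      j_call = "IGHJ6*02",
      junction_nt = substr(unlist(lin$sequences[keep], use.names = FALSE),
                           cdr3$start - 3L, cdr3$end + 3L),
      productive = TRUE,
      umi_count = umis[keep],
      read_count = reads[keep],
      reading_frame_offset = 0L
    )
  }
  # non-productive comparator families (frameshifted junction, own V gene)
  np_truth <- list()
  for (f in seq_len(config$n_nonproductive)) {
    np_germ <- random_germline()
    np_lin <- simulate_lineage(np_germ, config,
                               n_subclones = config$nonproductive_subclones)
    np_n <- config$nonproductive_subclones + 1L
    np_shares <- if (np_n == 1) 1 else {
      w <- seq_len(np_n - 1L)^(-config$abundance_exponent)
      c(0.7, 0.3 * w / sum(w))
    }
    for (r in seq_len(config$n_replicates)) {
      rep_id <- sprintf("rep%d", r)
      cells <- as.vector(rmultinom(1L, config$nonproductive_cells, np_shares))
      umis <- rpois(np_n, cells * config$mrna_per_cell)
      extra <- rpois(np_n, pmax(config$reads_per_umi_mean - 5, 0) * umis)
      reads <- 5L * umis + extra
      keep <- which(umis > 0)
      if (length(keep) == 0) next
      rows[[paste0("np", f, "_", rep_id)]] <- tibble(
        sequence_id = sprintf("%s_np%d_seq%s", config$sample_id, f,
                              names(np_lin$sequences)[keep]),
        sample_id = config$sample_id,
        replicate_id = rep_id,
        sequence_nt = unlist(np_lin$sequences[keep], use.names = FALSE),
        v_call = "IGHV1-69*01",
        j_call = "IGHJ4*02",
        # 47 nt junction: frameshifted, length not a multiple of 3
        junction_nt = substr(unlist(np_lin$sequences[keep], use.names = FALSE),
                             cdr3$start - 3L, cdr3$end + 2L),
        productive = FALSE,
        umi_count = umis[keep],
        read_count = reads[keep],
        reading_frame_offset = 0L
      )
    }
    np_truth[[f]] <- list(germline = np_germ, edges = np_lin$edges,
                          mutations = np_lin$mutations)
  }
  rearr <- bind_rows(rows)
  metadata <- tibble(
    sample_id = config$sample_id,
    alc_per_ul = config$alc_per_ul,
    cll_fraction = config$cll_fraction,
    ighv_mutation_status = config$ighv_status
  )
  truth <- list(
    germline = germline,
    cdc_sequence = cdc,
    pre_cdc_mutations = pre$mutations,
    edges = lin$edges,
    mutations = lin$mutations,
    shares = setNames(shares, names(lin$sequences)),
    sequences = lin$sequences,
    complexity = .true_complexity(lin$edges),
    nonproductive = np_truth
  )
  structure(list(rearrangements = rearr, metadata = metadata,
                 regions = regions, truth = truth),
            class = "sim_dataset")
}

#' Simulate clinical outcome times by prognostic group
#'
#' Exponential event times with group-specific hazards and independent
#' exponential censoring. The four strata cross IGHV mutation status with
#' lineage complexity; hazard ratios are expressed against the M-CLL/Low
#' baseline.
#'
#' @param n_per_group Subjects per stratum.
#' @param baseline_hazard Event hazard (per month) of the M-CLL Low group.
#' @param hazard_ratios Named vector over
#'   `c("M_Low", "M_High", "U_Low", "U_High")`.
#' @param censoring_rate Hazard of the independent censoring process as a
#'   multiple of `baseline_hazard` (0 = no censoring).
#' @return Tibble `subject_id`, `mutation_status`, `complexity`,
#'   `ttft_months`, `ttft_event`.
#' @export
simulate_clinical <- function(n_per_group = 500L,
                              baseline_hazard = log(2) / 80,
                              hazard_ratios = c(M_Low = 1, M_High = 1.02,
                                                U_Low = 2, U_High = 2 * 2.59),
                              censoring_rate = 0.3) {
  groups <- tibble(
    group = c("M_Low", "M_High", "U_Low", "U_High"),
    mutation_status = c("M-CLL", "M-CLL", "U-CLL", "U-CLL"),
    complexity = c("Low", "High", "Low", "High")
  )
  out <- lapply(seq_len(nrow(groups)), function(g) {
    hz <- baseline_hazard * hazard_ratios[[groups$group[g]]]
    tev <- rexp(n_per_group, hz)
    tcn <- if (censoring_rate > 0) {
      rexp(n_per_group, baseline_hazard * censoring_rate)
    } else {
      rep(Inf, n_per_group)
    }
    tibble(
      subject_id = sprintf("%s_%04d", groups$group[g], seq_len(n_per_group)),
      mutation_status = groups$mutation_status[g],
      complexity = groups$complexity[g],
      ttft_months = pmin(tev, tcn),
      ttft_event = tev <= tcn
    )
  })
  bind_rows(out)
}
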