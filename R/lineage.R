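# Mutation calling against the CDC and mutation-set-nested lineage trees.
#
# The lineage model: every subclone's mutation set (relative to the CDC) is
# expected to contain its parent's set plus at least one extra mutation.
# Under that nesting regime the tree is exactly the Hasse diagram of
# mutation-set inclusion; unobserved branch points are recovered as inferred
# intermediates (maximal subsets shared by two or more descendants).

#' Call mutations of a sequence relative to the CDC
#'
#' @param sequence_nt Aligned subclone sequence.
#' @param cdc_nt Aligned CDC reference of equal length.
#' @return Tibble `position` (1-based), `from`, `to`. Positions carrying N in
#'   either sequence are excluded.
#' @export
call_mutations <- function(sequence_nt, cdc_nt) {
  if (nchar(sequence_nt) != nchar(cdc_nt)) {
    stop("sequence and CDC reference differ in aligned length")
  }
  s <- nt_chars(sequence_nt); r <- nt_chars(cdc_nt)
  keep <- comparable_positions(s, r) & s != r
  tibble(position = which(keep), from = r[keep], to = s[keep])
}

#' Canonical string keys for a mutation table
#' @param mutations Tibble from [call_mutations()].
#' @return Character vector like `"17:C>T"`, sorted by position.
#' @export
mutation_keys <- function(mutations) {
  if (nrow(mutations) == 0) return(character(0))
  k <- sprintf("%d:%s>%s", mutations$position, mutations$from, mutations$to)
  k[order(mutations$position, mutations$to)]
}

.set_key <- function(set) paste(sort(set), collapse = ";")

#' Build the mutation-nested lineage tree of a clonal family
#'
#' Nodes are the observed unique sequences (identified by their mutation sets
#' relative to the CDC) plus inferred intermediates; the root is the CDC
#' (empty set). Construction: close the observed sets under pairwise
#' intersection (adding unobserved branch-point sets as inferred
#' intermediates), build the Hasse diagram of strict inclusion — each node's
#' parent is the node with the largest mutation set that is a proper subset
#' of its own, ties broken lexicographically on the set key — then splice out
#' inferred intermediates with fewer than two children. Observed sequences
#' with identical mutation sets collapse onto one node.
#'
#' @param family Collapsed family tibble (see [collapse_family()]).
#' @param cdc_id CDC sequence id.
#' @return Object of class `lineage_tree`: list with `nodes` (tibble
#'   `node_id`, `parent_id`, `n_mutations`, `n_added`, `observed`), `sets`
#'   (named list of mutation-key vectors), `root` (= `cdc_id`).
#' @export
build_lineage <- function(family, cdc_id = identify_cdc(family)) {
  cdc_nt <- family$sequence_nt[family$sequence_id == cdc_id][1]
  obs <- list()
  obs[[cdc_id]] <- character(0)
  for (i in seq_len(nrow(family))) {
    sid <- family$sequence_id[i]
    if (sid == cdc_id) next
    keys <- mutation_keys(call_mutations(family$sequence_nt[i], cdc_nt))
    if (length(keys) == 0) next  # indistinguishable from CDC (N wildcards)
    obs[[sid]] <- keys
  }
  # collapse identical observed sets (keep lexicographically smallest id)
  set_keys <- vapply(obs, .set_key, character(1))
  keep_ids <- vapply(split(names(obs), set_keys), min, character(1))
  obs <- obs[sort(unname(keep_ids))]
  sets <- obs
  observed <- setNames(rep(TRUE, length(sets)), names(sets))
  # intersection closure: add unobserved branch-point sets
  repeat {
    keys_now <- vapply(sets, .set_key, character(1))
    added <- FALSE
    ids <- names(sets)
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (j <= i) next
        inter <- intersect(sets[[i]], sets[[j]])
        ik <- .set_key(inter)
        if (!ik %in% keys_now) {
          nid <- paste0("inferred_", length(sets))
          sets[[nid]] <- inter
          observed[nid] <- FALSE
          keys_now <- c(keys_now, ik)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  # Hasse diagram: parent = largest proper subset
  ids <- names(sets)
  sizes <- vapply(sets, length, integer(1))
  skeys <- vapply(sets, .set_key, character(1))
  parent <- setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    if (sizes[[id]] == 0) next  # root
    cand <- ids[sizes < sizes[[id]]]
    is_sub <- vapply(cand, function(c0) all(sets[[c0]] %in% sets[[id]]), logical(1))
    cand <- cand[is_sub]
    best_size <- max(sizes[cand])
    best <- cand[sizes[cand] == best_size]
    parent[[id]] <- best[order(skeys[best])][1]
  }
  # splice out inferred nodes with < 2 children
  repeat {
    child_count <- table(factor(parent, levels = ids))
    drop <- ids[!observed[ids] & sizes[ids] > 0 & child_count[ids] < 2]
    if (length(drop) == 0) break
    drop <- drop[1]  # splice one at a time so chained intermediates resolve
    parent[!is.na(parent) & parent == drop] <- parent[[drop]]
    ids <- setdiff(ids, drop)
    parent <- parent[ids]; sets <- sets[ids]
    sizes <- sizes[ids]; observed <- observed[ids]
  }
  n_added <- vapply(ids, function(id) {
    if (is.na(parent[[id]])) 0L else sizes[[id]] - sizes[[parent[[id]]]]
  }, integer(1))
  nodes <- tibble(
    node_id = ids,
    parent_id = unname(parent[ids]),
    n_mutations = unname(sizes[ids]),
    n_added = unname(n_added),
    observed = unname(observed[ids])
  ) %>% arrange(.data$n_mutations, .data$node_id)
  structure(list(nodes = nodes, sets = sets,
                 root = ids[sizes[ids] == 0][1]),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  n_obs <- sum(x$nodes$observed) - 1L
  cat(sprintf("Lineage tree rooted at %s: %d observed subclone(s), %d inferred intermediate(s)\n",
              x$root, n_obs, sum(!x$nodes$observed)))
  invisible(x)
}

#' @noRd
.children_of <- function(tree, id) {
  tree$nodes$node_id[!is.na(tree$nodes$parent_id) & tree$nodes$parent_id == id]
}

#' @noRd
.subtree_ids <- function(tree, id) {
  out <- id
  queue <- .children_of(tree, id)
  while (length(queue) > 0) {
    out <- c(out, queue)
    queue <- unlist(lapply(queue, .children_of, tree = tree), use.names = FALSE)
  }
  out
}

#' Classify intraclonal lineage complexity
#'
#' Counts, for each initial branch off the CDC, the number of observed
#' (non-inferred) unique sequences in that subtree. A sample is High
#' complexity when any initial branch carries four or more observed
#' sequences; Low when every branch carries one to three. Under
#' `rule = "total"` the total observed subclone count is used instead of the
#' per-branch maximum. A tree without subclones is reported as undetermined.
#'
#' @param tree A `lineage_tree`.
#' @param rule `"max_branch"` (default) or `"total"`.
#' @return List of class `complexity_call`: `class` ("Low", "High" or NA),
#'   `max_downstream_count`, `branch_counts` (named by initial-branch node).
#' @export
classify_complexity <- function(tree, rule = c("max_branch", "total")) {
  rule <- match.arg(rule)
  branches <- .children_of(tree, tree$root)
  if (length(branches) == 0) {
    return(structure(list(class = NA_character_, max_downstream_count = 0L,
                          branch_counts = integer(0)), class = "complexity_call"))
  }
  counts <- vapply(branches, function(b) {
    ids <- .subtree_ids(tree, b)
    sum(tree$nodes$observed[tree$nodes$node_id %in% ids])
  }, integer(1))
  names(counts) <- branches
  stat <- if (rule == "max_branch") max(counts) else sum(counts)
  structure(list(
    class = if (stat >= 4L) "High" else "Low",
    max_downstream_count = as.integer(stat),
    branch_counts = counts
  ), class = "complexity_call")
}

#' @export
print.complexity_call <- function(x, ...) {
  cat(sprintf("Complexity: %s (max downstream count %d over %d initial branch(es))\n",
              ifelse(is.na(x$class), "undetermined", x$class),
              x$max_downstream_count, length(x$branch_counts)))
  invisible(x)
}

#' @noRd
.newick_label <- function(id) gsub("[,;:()\\s]", "_", id, perl = TRUE)

#' Export a lineage tree as a Newick string
#'
#' Node labels are sequence ids; branch lengths are added-mutation counts.
#' Internal observed nodes and singleton chains are preserved.
#'
#' @param tree A `lineage_tree`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
lineage_newick <- function(tree, path = NULL) {
  emit <- function(id) {
    kids <- sort(.children_of(tree, id))
    nadd <- tree$nodes$n_added[tree$nodes$node_id == id]
    lab <- .newick_label(id)
    body <- if (length(kids) == 0) lab else {
      paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", lab)
    }
    paste0(body, ":", nadd)
  }
  nwk <- paste0(emit(tree$root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Export a lineage tree as Graphviz DOT
#'
#' @param tree A `lineage_tree`.
#' @param path Optional file to write to.
#' @return DOT source as a character string.
#' @export
lineage_dot <- function(tree, path = NULL) {
  nd <- tree$nodes
  lines <- c("digraph lineage {",
             sprintf("  \"%s\" [shape=%s];", nd$node_id,
                     ifelse(nd$observed, "ellipse", "point")))
  e <- nd[!is.na(nd$parent_id), , drop = FALSE]
  lines <- c(lines,
             sprintf("  \"%s\" -> \"%s\" [label=\"%d\"];",
                     e$parent_id, e$node_id, e$n_added),
             "}")
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(out, path)
  out
}
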