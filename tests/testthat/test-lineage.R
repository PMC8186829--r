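# Mutation calling and mutation-nested lineage reconstruction

test_that("mutation calling matches a positional loop oracle", {
  expect_equal(nrow(call_mutations("ACGT", "ACGT")), 0)
  m <- call_mutations("ACGTACGTACTT", "ACGTACGTACCT")
  expect_equal(m$position, 11L)
  expect_equal(m$from, "C"); expect_equal(m$to, "T")
  expect_error(call_mutations("ACG", "ACGT"), "length")
  set.seed(51)
  for (k in 1:200) {
    ref <- random_nt(80)
    mut <- ref
    pos <- sample(80, sample(0:10, 1))
    for (p in pos) {
      substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(ref, p, p)), 1)
    }
    got <- call_mutations(mut, ref)
    # loop oracle
    rv <- strsplit(ref, "")[[1]]; mv <- strsplit(mut, "")[[1]]
    exp_pos <- which(rv != mv)
    expect_equal(got$position, exp_pos)
    expect_equal(got$from, rv[exp_pos])
    expect_equal(got$to, mv[exp_pos])
  }
})

mk_seq <- function(cdc, pos) {
  s <- cdc
  for (p in pos) substr(s, p, p) <- if (substr(cdc, p, p) == "G") "T" else "G"
  s
}

test_that("strictly nested sets give a chain; shared subsets give intermediates", {
  cdc <- strrep("A", 40)
  fam <- make_family(
    c(cdc = cdc, a = mk_seq(cdc, 1), b = mk_seq(cdc, c(1, 2))),
    c(cdc = 100, a = 10, b = 5)
  )
  tree <- build_lineage(fam, "cdc")
  nd <- tree$nodes
  expect_equal(nd$parent_id[nd$node_id == "a"], "cdc")
  expect_equal(nd$parent_id[nd$node_id == "b"], "a")
  expect_equal(nd$n_added[nd$node_id == "b"], 1L)
  # edge count = node count - 1, all reachable
  expect_equal(sum(!is.na(nd$parent_id)), nrow(nd) - 1L)

  # {m1, m2} and {m1, m3} with {m1} unobserved -> inferred intermediate
  fam2 <- make_family(
    c(cdc = cdc, x = mk_seq(cdc, c(1, 2)), y = mk_seq(cdc, c(1, 3))),
    c(cdc = 100, x = 10, y = 5)
  )
  tree2 <- build_lineage(fam2, "cdc")
  nd2 <- tree2$nodes
  inf <- nd2$node_id[!nd2$observed & nd2$n_mutations == 1]
  expect_length(inf, 1)
  expect_equal(sort(nd2$parent_id[nd2$node_id %in% c("x", "y")]),
               rep(inf, 2))
  expect_equal(nd2$parent_id[nd2$node_id == inf], "cdc")
})

test_that("reconstruction recovers simulated homoplasy-free topologies", {
  set.seed(52)
  for (k in 1:10) {
    cfg <- sim_config(seed = 1000 + k, n_subclones = sample(5:25, 1),
                      mutations_per_edge_mean = 1.2)
    root <- random_germline()
    lin <- simulate_lineage(root, cfg)
    fam <- tibble::tibble(
      sequence_id = names(lin$sequences),
      sequence_nt = unlist(lin$sequences, use.names = FALSE),
      umi_count = c(1000L, rep(1L, cfg$n_subclones)),
      productive = TRUE
    )
    tree <- build_lineage(fam, "0")
    nd <- tree$nodes
    expect_true(all(nd$observed))  # no intermediates needed
    got <- nd[!is.na(nd$parent_id), c("node_id", "parent_id")]
    truth <- lin$edges[order(lin$edges$node), ]
    got <- got[order(got$node_id), ]
    expect_equal(got$node_id, truth$node)
    expect_equal(got$parent_id, truth$parent)
    # parsimony: total edge mutations equal the union of observed sets
    expect_equal(sum(nd$n_added), nrow(lin$mutations))
  }
})

test_that("complexity classification follows the per-branch max rule", {
  cdc <- strrep("A", 60)
  chain <- make_family(
    c(cdc = cdc, a = mk_seq(cdc, 1), b = mk_seq(cdc, 1:2), c = mk_seq(cdc, 1:3)),
    c(cdc = 50, a = 3, b = 2, c = 1)
  )
  cc <- classify_complexity(build_lineage(chain, "cdc"))
  expect_equal(cc$class, "Low")
  expect_equal(cc$max_downstream_count, 3L)

  five <- make_family(
    c(cdc = cdc, stats::setNames(lapply(1:5, function(i) mk_seq(cdc, 1:i)),
                                 paste0("n", 1:5)) |> unlist()),
    stats::setNames(c(50, 5:1), c("cdc", paste0("n", 1:5)))
  )
  cc5 <- classify_complexity(build_lineage(five, "cdc"))
  expect_equal(cc5$class, "High")

  # branches of sizes {2, 4}: High under max rule, and invariant to order
  mk_branchy <- function(ids) {
    seqs <- c(cdc = cdc,
              b1a = mk_seq(cdc, 1), b1b = mk_seq(cdc, 1:2),
              b2a = mk_seq(cdc, 10), b2b = mk_seq(cdc, 10:11),
              b2c = mk_seq(cdc, 10:12), b2d = mk_seq(cdc, 10:13))
    make_family(seqs[ids], stats::setNames(c(50, 6:1), ids))
  }
  ids <- c("cdc", "b1a", "b1b", "b2a", "b2b", "b2c", "b2d")
  cc_a <- classify_complexity(build_lineage(mk_branchy(ids), "cdc"))
  cc_b <- classify_complexity(build_lineage(mk_branchy(rev(ids))[c(7, 1:6), ], "cdc"))
  expect_equal(cc_a$class, "High")
  expect_equal(cc_a$max_downstream_count, 4L)
  expect_equal(cc_b$class, cc_a$class)
  expect_equal(sort(cc_b$branch_counts), sort(cc_a$branch_counts))
  # total-count rule differs: {2, 3} -> 5 subclones total
  expect_equal(classify_complexity(build_lineage(mk_branchy(ids[1:6]), "cdc"),
                                   rule = "total")$max_downstream_count, 5L)

  # no subclones -> undetermined
  solo <- make_family(c(cdc = cdc), c(cdc = 10))
  expect_true(is.na(classify_complexity(build_lineage(solo, "cdc"))$class))
})

test_that("newick and DOT exports reflect the tree", {
  cdc <- strrep("A", 40)
  fam <- make_family(
    c(cdc = cdc, a = mk_seq(cdc, 1), b = mk_seq(cdc, c(1, 2))),
    c(cdc = 100, a = 10, b = 5)
  )
  tree <- build_lineage(fam, "cdc")
  nwk <- lineage_newick(tree)
  expect_equal(nwk, "((b:1)a:1)cdc:0;")
  dot <- lineage_dot(tree)
  expect_match(dot, "\"a\" -> \"b\"", fixed = TRUE)
  expect_match(dot, "\"cdc\" -> \"a\"", fixed = TRUE)
})
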