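test_that("source assignment follows the modal-neighbor rule on hand fixtures", {
  # a single earlier cell: trivially its cluster, no tie
  e1 <- make_slice("6", rbind(c(0, 0)), "A")
  l1 <- make_slice("8", rbind(c(5, 5)), "X")
  a <- assign_source_states(e1, l1, k = 1)
  expect_equal(a$assigned_source_cluster, "A")
  expect_false(a$tie_broken)

  # 10 earlier cells in the neighborhood, 6xA vs 4xB: majority wins
  pos <- cbind(seq(0.1, 1, by = 0.1), 0)
  e2 <- make_slice("6", pos, c(rep("A", 6), rep("B", 4)))
  l2 <- make_slice("8", rbind(c(0, 0)), "X")
  a2 <- assign_source_states(e2, l2, k = 10)
  expect_equal(a2$assigned_source_cluster, "A")
  expect_false(a2$tie_broken)
  expect_length(a2$neighbor_ids[[1]], 10)

  # 5xA vs 5xB with the single nearest a B: tie broken toward the nearest
  e3 <- make_slice("6", pos, c("B", rep("A", 5), rep("B", 4)))
  a3 <- assign_source_states(e3, l2, k = 10)
  expect_equal(a3$assigned_source_cluster, "B")
  expect_true(a3$tie_broken)
})

test_that("assignment and graph match the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:5) {
    earlier <- random_slice("6", sample(20:40, 1), 3)
    later <- random_slice("8", sample(20:40, 1), 3)
    a <- assign_source_states(earlier, later, k = 10)
    o <- oracle_assignments(earlier, later, 10)
    expect_identical(a$assigned_source_cluster, o$assigned)
    expect_identical(a$tie_broken, o$tie_broken)
    expect_identical(a$neighbor_ids, o$neighbor_ids)

    g <- build_lineage_graph(a, earlier, later, threshold = 0.2)
    oe <- oracle_edges(o$assigned, earlier, later, 0.2)
    ge <- g$edges[order(g$edges$earlier_cluster, g$edges$later_cluster),
                  c("earlier_cluster", "later_cluster", "n_cells",
                    "fraction", "retained")]
    rownames(ge) <- rownames(oe) <- NULL
    expect_equal(ge, oe)
  }
})

test_that("edge retention is strictly greater-than the threshold", {
  # one later cluster of 10 cells: 3 trace to A (0.3), 2 to B (0.2), 5 to C
  e <- make_slice("6", rbind(c(0, 0), c(100, 0), c(0, 100)),
                  c("A", "B", "C"))
  lpos <- rbind(matrix(rep(c(0, 0), 3), ncol = 2, byrow = TRUE) + 0.1,
                matrix(rep(c(100, 0), 2), ncol = 2, byrow = TRUE) + 0.1,
                matrix(rep(c(0, 100), 5), ncol = 2, byrow = TRUE) + 0.1)
  l <- make_slice("8", lpos, rep("P", 10))
  g <- build_lineage_graph(assign_source_states(e, l, k = 1), e, l,
                           threshold = 0.2)
  frac <- setNames(g$edges$fraction, g$edges$earlier_cluster)
  expect_equal(unname(frac[c("A", "B", "C")]), c(0.3, 0.2, 0.5))
  expect_true(g$edges$retained[g$edges$earlier_cluster == "A"])
  expect_false(g$edges$retained[g$edges$earlier_cluster == "B"])
  expect_true(g$edges$retained[g$edges$earlier_cluster == "C"])
})

test_that("raising the threshold never adds edges", {
  set.seed(7)
  earlier <- random_slice("6", 40, 4)
  later <- random_slice("8", 40, 4)
  a <- assign_source_states(earlier, later, k = 10)
  taus <- c(0, 0.1, 0.2, 0.4, 0.6)
  sets <- lapply(taus, function(tau)
    edge_key(retained_edges(build_lineage_graph(a, earlier, later, tau))))
  for (i in seq_along(taus)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("the graph is invariant to cell order within a slice", {
  set.seed(11)
  earlier <- random_slice("6", 35, 3)
  later <- random_slice("8", 35, 3)
  g1 <- build_lineage_graph(assign_source_states(earlier, later), earlier,
                            later)
  perm_e <- sample(length(earlier$cell_ids))
  perm_l <- sample(length(later$cell_ids))
  earlier2 <- make_slice("6", earlier$embedding[perm_e, ],
                         earlier$cluster_labels[perm_e],
                         earlier$cell_ids[perm_e])
  later2 <- make_slice("8", later$embedding[perm_l, ],
                       later$cluster_labels[perm_l],
                       later$cell_ids[perm_l])
  g2 <- build_lineage_graph(assign_source_states(earlier2, later2),
                            earlier2, later2)
  expect_equal(g1$edges, g2$edges)
})

test_that("degenerate inputs are handled as documented", {
  e <- make_slice("6", rbind(c(0, 0), c(1, 0)), c("A", "B"))
  l <- make_slice("8", rbind(c(0, 0.5)), "X")
  # k larger than the earlier population: all earlier cells vote
  a <- assign_source_states(e, l, k = 50)
  expect_length(a$neighbor_ids[[1]], 2)
  # dimension mismatch and empty earlier slice are errors
  l3 <- make_slice("8", rbind(c(0, 0, 0)), "X")
  expect_error(assign_source_states(e, l3), "dimensionality")
  empty <- timepoint_slice("6", character(0),
                           matrix(numeric(0), 0, 2), character(0))
  expect_error(assign_source_states(empty, l), "no cells")
  expect_error(build_lineage_graph(a, e, l, threshold = 1.5), "threshold")
  expect_error(build_lineage_graph(a, e, l, threshold = -0.1), "threshold")
})

test_that("chaining adjacent timepoints unions the per-pair graphs", {
  # three stages with identity structure: a linear chain
  mk <- function(label) make_slice(label,
                                   rbind(c(0, 0), c(0, 0.1), c(10, 0),
                                         c(10, 0.1)),
                                   c("A", "A", "B", "B"))
  slices <- lapply(c("6", "8", "10"), mk)
  g <- chain_timepoints(slices, k = 2, threshold = 0.2)
  re <- retained_edges(g)
  expect_equal(nrow(re), 4)
  expect_true(all(re$fraction == 1))
  expect_true(all(re$earlier_cluster == re$later_cluster))
  expect_equal(nrow(g$nodes), 6)

  # reversed order gives a different (reversed-direction) graph, never a
  # silent reuse of the forward one
  mixed <- lapply(c("6", "8"), mk)
  mixed[[2]]$cluster_labels <- c("A", "A", "A", "B")
  gf <- chain_timepoints(mixed)
  gr <- chain_timepoints(rev(mixed))
  expect_false(identical(gf$edges, gr$edges))

  expect_error(chain_timepoints(slices[1]), "at least 2")
})
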