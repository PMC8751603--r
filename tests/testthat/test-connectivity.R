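test_that("interconnectivity matches hand-enumerated induced components", {
  tri <- toy_interactome(c("A", "B", "B", "C", "C", "A"))
  r <- largest_connected_fraction(tri, c("A", "B", "C"))
  expect_equal(r$n_lcc, 3L)
  expect_equal(r$fraction, 1)

  two <- toy_interactome(c("A", "B", "C", "D"))
  r2 <- largest_connected_fraction(two, c("A", "B", "C", "D"))
  expect_equal(r2$n_lcc, 2L)
  expect_equal(r2$fraction, 0.5)

  p10 <- path_interactome(10)
  r3 <- largest_connected_fraction(p10, c("V1", "V2", "V3", "V7", "V9"))
  expect_equal(r3$n_mapped, 5L)
  expect_equal(r3$n_lcc, 3L)       # induced edges: V1-V2, V2-V3
  expect_equal(r3$fraction, 0.6)
})

test_that("query handling: normalization, de-duplication, unmapped symbols", {
  tri <- toy_interactome(c("A", "B", "B", "C", "C", "A"))
  r <- largest_connected_fraction(tri, c(" a", "A", "b", "ZZZ"))
  expect_equal(r$n_input, 3L)      # unique normalized symbols
  expect_equal(r$n_mapped, 2L)     # ZZZ unmapped
  expect_equal(r$fraction, 1)      # A-B edge connects both

  expect_warning(r0 <- largest_connected_fraction(tri, "ZZZ"), "undefined")
  expect_true(is.na(r0$fraction))
  expect_equal(r0$n_mapped, 0L)

  # singleton mapped node: degenerate but defined
  r1 <- largest_connected_fraction(tri, c("A", "QQ"))
  expect_equal(r1$fraction, 1)
  expect_error(largest_connected_fraction(tri, character(0)), "empty")
})

test_that("adding a node adjacent to the current LCC never shrinks it", {
  for (s in 1:25) {
    g <- gen_er(25, 0.12, s)
    nodes <- interactome_nodes(g)
    set.seed(s)
    q <- sample(nodes, 8)
    r <- largest_connected_fraction(g, q)
    nb <- setdiff(unique(names(unlist(igraph::adjacent_vertices(
      g$graph, intersect(q, nodes))))), q)
    if (length(nb) == 0) next
    r2 <- largest_connected_fraction(g, c(q, nb[1]))
    expect_gte(r2$n_lcc, r$n_lcc)
  }
})

test_that("fraction is 1 exactly when the induced subgraph is connected", {
  for (s in 1:30) {
    g <- gen_er(20, 0.15, s)
    nodes <- interactome_nodes(g)
    set.seed(100 + s)
    q <- sample(nodes, 6)
    r <- largest_connected_fraction(g, q)
    sub <- igraph::induced_subgraph(g$graph, intersect(q, nodes))
    expect_equal(r$fraction == 1, igraph::is_connected(sub))
  }
})

test_that("joint networks link chemicals to thresholded targets over the PPI", {
  g <- toy_interactome(c("P1", "P2", "P2", "P3"))
  tab <- data.frame(chemical_id = c("X", "X", "Y", "Y"),
                    protein = c("P1", "P2", "P2", "P3"),
                    experimental = 0.9, database = 0, textmining = 0,
                    prediction = 0, combined_score = c(0.9, 0.9, 0.9, 0.4))
  jn <- build_joint_network(g, tab, c("X"), 0.4)
  expect_equal(jn$chemical_nodes, "X")
  expect_equal(jn$protein_nodes, c("P1", "P2"))
  expect_equal(nrow(jn$ppi_edges), 1)
  expect_equal(nrow(jn$chem_target_edges), 2)

  expect_warning(jn0 <- build_joint_network(g, tab, c("X", "Y"), 1.0),
                 "empty joint network")
  expect_equal(nrow(jn0$chem_target_edges), 0)

  # shared target appears once on the protein side
  jn2 <- build_joint_network(g, tab, c("X", "Y"), 0.4)
  expect_equal(jn2$protein_nodes, c("P1", "P2", "P3"))
  expect_equal(sum(jn2$protein_nodes == "P2"), 1)
  # protein-side interconnectivity delegates to the same statistic
  r <- largest_connected_fraction(g, jn2$protein_nodes)
  expect_equal(r$fraction, 1)
})
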