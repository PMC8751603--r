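test_that("cleaning applies every rule and accounts for each removed row", {
  rec <- rbind(
    edge_records("A", "B"),                      # kept
    edge_records("B", "A"),                      # duplicate (reversed)
    edge_records("C", "C"),                      # self-loop
    edge_records("A", "D", type = "genetic"),    # genetic
    edge_records("A", "E", org_b = 10090),       # off-species
    edge_records("B", "C"))                      # kept
  g <- clean_interactome(rec, 9606)
  expect_equal(igraph::ecount(g$graph), 2)
  el <- igraph::as_edgelist(g$graph)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("A B", "B C"))
  expect_equal(g$provenance,
               c(genetic = 1L, off_species = 1L, self_loop = 1L,
                 duplicate = 1L))
  expect_equal(sum(g$provenance), nrow(rec) - igraph::ecount(g$graph))
  # nodes appearing only in removed rows are dropped
  expect_setequal(interactome_nodes(g), c("A", "B", "C"))
})

test_that("cleaning degenerate inputs yields empty graphs with warnings", {
  expect_warning(g0 <- clean_interactome(edge_records(character(0), character(0)), 9606),
                 "no input")
  expect_equal(igraph::vcount(g0$graph), 0)
  rec <- edge_records(c("A", "B"), c("B", "C"), type = "genetic")
  expect_warning(g1 <- clean_interactome(rec, 9606), "empty")
  expect_equal(igraph::ecount(g1$graph), 0)
  g2 <- clean_interactome(edge_records("A", "B"), 9606)
  expect_equal(igraph::ecount(g2$graph), 1)
  expect_equal(igraph::vcount(g2$graph), 2)
})

test_that("cleaning an already-clean record set is idempotent", {
  set.seed(7)
  g <- gen_er(40, 0.15, 7)
  el <- igraph::as_edgelist(g$graph)
  rec <- edge_records(el[, 1], el[, 2])
  g2 <- clean_interactome(rec, 9606)
  expect_equal(sum(g2$provenance), 0)
  expect_equal(igraph::ecount(g2$graph), igraph::ecount(g$graph))
  expect_setequal(interactome_nodes(g2),
                  interactome_nodes(g)[igraph::degree(g$graph) > 0])
})

test_that("degree histograms count nodes per degree and sum to the node count", {
  tri <- toy_interactome(c("A", "B", "B", "C", "C", "A"))
  expect_equal(degree_histogram(tri), data.frame(k = 2L, count = 3L))

  star <- toy_interactome(c("H", "L1", "H", "L2", "H", "L3", "H", "L4"))
  expect_equal(degree_histogram(star),
               data.frame(k = c(1L, 4L), count = c(4L, 1L)))

  p5 <- path_interactome(5)
  expect_equal(degree_histogram(p5),
               data.frame(k = c(1L, 2L), count = c(2L, 3L)))
  expect_equal(sum(degree_histogram(p5)$count), 5)
})

test_that("interactomes round-trip through the two-column edge-list TSV", {
  g <- gen_scale_free(50, 2, 3)
  p <- tempfile(fileext = ".tsv")
  write_interactome(g, p)
  g2 <- read_interactome(p)
  expect_setequal(interactome_nodes(g2), interactome_nodes(g))
  expect_equal(igraph::ecount(g2$graph), igraph::ecount(g$graph))
})
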