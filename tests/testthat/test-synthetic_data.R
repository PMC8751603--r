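test_that("preferential-attachment generation is simple, connected, seeded", {
  tree <- gen_scale_free(10, 1, 3)
  expect_equal(igraph::ecount(tree$graph), 9)   # m = 1 growth is a tree
  expect_true(igraph::is_connected(tree$graph))

  g <- gen_scale_free(200, 3, 11)
  expect_true(igraph::is_simple(g$graph))
  expect_equal(sum(igraph::degree(g$graph)), 2 * igraph::ecount(g$graph))

  g2 <- gen_scale_free(200, 3, 11)
  expect_identical(igraph::as_edgelist(g$graph),
                   igraph::as_edgelist(g2$graph))
  expect_error(gen_scale_free(3, 3, 1), "exceed")
})

test_that("Erdos-Renyi generation hits its expected density", {
  expect_equal(igraph::ecount(gen_er(20, 0, 1)$graph), 0)
  expect_equal(igraph::ecount(gen_er(10, 1, 1)$graph), choose(10, 2))
  counts <- vapply(1:30, function(s)
    igraph::ecount(gen_er(1000, 0.01, s)$graph), numeric(1))
  mu <- choose(1000, 2) * 0.01
  sd_bin <- sqrt(choose(1000, 2) * 0.01 * 0.99)
  expect_lt(abs(mean(counts) - mu), 3 * sd_bin / sqrt(30))
})

test_that("planted target maps respect purity and determinism", {
  g <- gen_scale_free(500, 2, 7)
  sp <- synthetic_spec(n_nodes = 500, planted_module_size = 50,
                       purity = 1, n_chemicals = 4,
                       targets_per_chemical = 20, seed = 9)
  pm <- gen_planted_target_map(g, sp)
  expect_length(pm$module, 50)
  expect_true(all(pm$table$protein %in% pm$module))
  expect_true(all(pm$table$combined_score == 0.9))
  expect_true(all(pm$table$textmining == 0 & pm$table$prediction == 0))
  # per chemical: distinct targets, exact count
  by_chem <- split(pm$table$protein, pm$table$chemical_id)
  expect_true(all(vapply(by_chem, function(x)
    length(unique(x)) == 20, logical(1))))

  pm2 <- gen_planted_target_map(g, sp)
  expect_identical(pm$table, pm2$table)

  sp0 <- synthetic_spec(n_nodes = 500, planted_module_size = 50,
                        purity = 0, n_chemicals = 4,
                        targets_per_chemical = 20, seed = 9)
  pm0 <- gen_planted_target_map(g, sp0)
  expect_equal(sum(pm0$table$protein %in% pm0$module), 0)

  spbad <- synthetic_spec(n_nodes = 500, planted_module_size = 10,
                          purity = 1, targets_per_chemical = 20)
  expect_error(gen_planted_target_map(g, spbad), "pool")
})

test_that("the planted module is the deterministic top-degree core", {
  g <- gen_scale_free(300, 2, 13)
  sp <- synthetic_spec(n_nodes = 300, planted_module_size = 30,
                       targets_per_chemical = 10)
  pm <- gen_planted_target_map(g, sp)
  deg <- igraph::degree(g$graph)
  expect_gte(min(deg[pm$module]),
             max(deg[setdiff(interactome_nodes(g), pm$module)]) - 1)
})

test_that("overlap universes have the exact requested cardinalities", {
  o <- gen_overlap_universes(30, 10, 8, 3, seed = 5)
  expect_length(o$universe, 30)
  expect_length(o$set_a, 10)
  expect_length(o$set_b, 8)
  expect_length(intersect(o$set_a, o$set_b), 3)
  expect_true(all(c(o$set_a, o$set_b) %in% o$universe))

  same <- gen_overlap_universes(10, 5, 5, 5, seed = 1)
  expect_equal(same$set_a, same$set_b)
  disj <- gen_overlap_universes(10, 5, 5, 0, seed = 1)
  expect_length(intersect(disj$set_a, disj$set_b), 0)
  expect_error(gen_overlap_universes(10, 3, 5, 4, 1), "overlap exceeds")
  expect_error(gen_overlap_universes(8, 5, 5, 1, 1), "fit")
})
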