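test_that("Fisher overlap reproduces closed-form hypergeometric values", {
  u <- paste0("c", 1:10)
  r <- fisher_overlap(u[1:5], u[1:5], u)
  expect_equal(r$n_overlap, 5)
  expect_equal(r$p_value, 1 / choose(10, 5))   # 1/252

  # B a subset of A = universe: overlap is forced, p = 1
  r2 <- fisher_overlap(u, u[1:4], u)
  expect_equal(r2$p_value, 1)

  # members outside the universe are dropped with a message
  expect_message(r3 <- fisher_overlap(c(u[1:3], "zz"), u[2:4], u),
                 "outside the universe")
  expect_equal(r3$n_a, 3)
  expect_error(fisher_overlap("a", "b", character(0)), "empty")
})

test_that("overlap p-values are invariant under relabeling the universe", {
  uni <- gen_overlap_universes(40, 12, 9, 4, seed = 8)
  r1 <- fisher_overlap(uni$set_a, uni$set_b, uni$universe)
  relabel <- stats::setNames(paste0("R", seq_along(uni$universe)),
                             uni$universe)
  r2 <- fisher_overlap(relabel[uni$set_a], relabel[uni$set_b],
                       unname(relabel[uni$universe]))
  expect_equal(r2$p_value, r1$p_value)
  expect_equal(r2$odds_ratio, r1$odds_ratio)
})

test_that("enrichment reproduces closed forms on whole-set queries", {
  sets <- list(HIT = paste0("g", 1:10), OTHER = paste0("g", 21:30))
  col <- gene_set_collection(sets, universe = paste0("g", 1:100))
  rows <- enrich(paste0("g", 1:10), col)
  hit <- rows[rows$set_name == "HIT", ]
  expect_equal(hit$fold_enrichment, 10)
  expect_equal(hit$p_value, 1 / choose(100, 10))
  other <- rows[rows$set_name == "OTHER", ]
  expect_equal(other$k, 0)
  expect_equal(other$fold_enrichment, 0)
  expect_equal(other$p_value, 1)
})

test_that("enrichment edge cases: duplicate sets, whole-universe set, misses", {
  col <- gene_set_collection(list(A = paste0("g", 1:5),
                                  B = paste0("g", 1:5)),
                             universe = paste0("g", 1:50))
  rows <- enrich(paste0("g", 1:5), col)
  expect_equal(rows$p_value[1], rows$p_value[2])
  expect_equal(rows$adjusted_p[1], rows$adjusted_p[2])

  whole <- gene_set_collection(list(U = paste0("g", 1:50)),
                               universe = paste0("g", 1:50))
  r <- enrich(paste0("g", c(3, 9, 30)), whole)
  expect_equal(r$fold_enrichment, 1)
  expect_equal(r$p_value, 1)

  expect_warning(miss <- enrich("nope", whole), "does not intersect")
  expect_equal(nrow(miss), 0)
})

test_that("the EASE variant is strictly more conservative for single hits", {
  col <- gene_set_collection(list(S = paste0("g", 1:10)),
                             universe = paste0("g", 1:100))
  std <- enrich(c("g1", "g50", "g60"), col)
  ease <- enrich(c("g1", "g50", "g60"), col, ease = TRUE)
  expect_lt(std$p_value, ease$p_value)
  expect_equal(ease$p_value, 1)   # k = 1 scored as 0 hits
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(numeric(0)), "no p-values")
  # step-up with a non-trivial pattern, computed by hand:
  # sorted p = .001,.01,.04,.04 -> m/i * p = .004,.02,.0533,.04 ->
  # cummin from the top = .004,.02,.04,.04
  expect_equal(bh_adjust(c(0.04, 0.001, 0.04, 0.01)),
               c(0.04, 0.004, 0.04, 0.02))
})

test_that("the reporting filter applies the adjusted-p and fold rules", {
  rows <- data.frame(set_name = c("a", "b", "c"),
                     fold_enrichment = c(5, 1.5, 3),
                     adjusted_p = c(1e-5, 1e-6, 0.01))
  out <- enrich_filter(rows, max_adjusted_p = 0.001, min_fold = 2)
  expect_equal(out$set_name, "a")
})

test_that("ortholog maps filter by score and de-duplicate", {
  map <- data.frame(source_gene = c("A", "B", "C", "A"),
                    target_gene = c("X", "Y", "Z", "X"),
                    inparalog_score = c(1, 1, 0.8, 1))
  out <- filter_ortholog_map(map, 1.0)
  expect_equal(nrow(out), 2)
  expect_setequal(out$source_gene, c("A", "B"))
  expect_equal(nrow(filter_ortholog_map(map[0, ], 1.0)), 0)
})
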