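test_that("name canonicalization resolves synonyms case-insensitively", {
  cat <- sm_catalog()
  expect_equal(canonicalize("VPA", cat), "Valproic acid")
  expect_equal(canonicalize("vpa", cat), "Valproic acid")
  expect_equal(canonicalize("RepSOX", cat), "RepSox")
  expect_equal(canonicalize("TSA", cat), "Trichostatin A")
  expect_equal(canonicalize("AM580", cat), "AM 580")
  expect_equal(canonicalize(c("F", "T", "6"), cat),
               c("Forskolin", "Parnate", "RepSox"))
  expect_error(canonicalize("Vaproic acid", cat), "nearest")
})

test_that("the packaged catalog is consistent", {
  cat <- sm_catalog()
  expect_equal(nrow(cat), 22)
  expect_false(anyDuplicated(cat$canonical_name) > 0)
  expect_true(all(lengths(cat$categories) >= 1))
})

test_that("cocktail membership summaries behave as set operations", {
  defs <- cocktail_definitions()
  expect_length(defs, 10)

  one <- defs[1]
  f1 <- sm_frequency(one)
  expect_true(all(f1$n_cocktails == 1))
  expect_setequal(f1$sm, defs[[1]])

  expect_equal(cocktail_union(defs[c(3, 3)]), sort(defs[[3]]))
  expect_equal(cocktail_union(list()), character(0))

  # total frequency mass equals total (canonicalized) membership
  freq <- sm_frequency(defs)
  expect_equal(sum(freq$n_cocktails), sum(lengths(defs)))
  expect_false("Rapamycin" %in% freq$sm)   # SM in no cocktail is absent
})

test_that("category coverage counts members per activity category", {
  cat <- sm_catalog()
  cov2 <- category_coverage(c("NaB", "LiCl", "SB431542"), cat)
  expect_gte(cov2["epigenetic"], 1)
  expect_gte(cov2["metabolic"], 1)
  expect_gte(cov2["signaling"], 1)
  expect_true(covers_core_categories(c("NaB", "LiCl", "SB431542"), cat))
  expect_false(covers_core_categories("SB431542", cat))
  expect_equal(unname(category_coverage("SB431542", cat)["signaling"]), 1L)
  expect_error(category_coverage("NotAnSM", cat), "not in catalog")
})

test_that("target aggregation unions thresholded targets over members", {
  tab <- data.frame(chemical_id = c("X", "X", "Y", "Y"),
                    protein = c("P1", "P2", "P2", "P3"),
                    experimental = 0.9, database = 0, textmining = 0,
                    prediction = 0, combined_score = c(0.9, 0.9, 0.9, 0.9))
  expect_equal(aggregate_targets(c("X", "Y"), tab), c("P1", "P2", "P3"))
  expect_warning(none <- aggregate_targets(c("X", "Y"), tab, threshold = 0.95),
                 "no target")
  expect_equal(none, character(0))
})

test_that("cocktail/TF overlap delegates to the one-sided Fisher test", {
  u <- paste0("g", 1:10)
  tf_tab <- data.frame(tf = rep(c("POU5F1", "SOX2"), c(3, 2)),
                       target = u[1:5])
  r <- compare_to_tf_targets(u[1:5], tf_tab, c("POU5F1", "SOX2"), u)
  expect_equal(r$p_value, 1 / choose(10, 5))

  u20 <- paste0("g", 1:20)
  tf_tab2 <- data.frame(tf = "POU5F1", target = u20[1:5])
  r2 <- compare_to_tf_targets(u20[6:10], tf_tab2, "POU5F1", u20)
  expect_equal(r2$p_value, 1)   # disjoint sets: tail at k = 0

  expect_error(compare_to_tf_targets(u[1:3], tf_tab2, "KLF4", u),
               "no TF target")
})

test_that("the metabolite table fixture is well-formed", {
  met <- sm_metabolites()
  expect_equal(nrow(met), 28)
  expect_true(all(c("name", "role", "chemical_class") %in% names(met)))
  expect_true("Valproic acid" %in% met$name)
})
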