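#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a scale-free interactome, a
# chemical-target table concentrated in the planted hub module, a
# density-matched random-graph control, and a gene-set collection over
# the interactome nodes. Everything downstream (02-04) reads these files.

suppressPackageStartupMessages(library(reprognet))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260920L

g <- gen_scale_free(3000, 2, seed)
cat(sprintf("scale-free interactome: %d nodes, %d edges\n",
            length(interactome_nodes(g)), nrow(igraph::as_edgelist(g$graph))))
write_interactome(g, file.path(out, "interactome_edges.tsv"))

# simple_tsv dialect version, so the pipeline exercises the cleaning path
el <- igraph::as_edgelist(g$graph, names = TRUE)
write_edge_list(data.frame(symbol_a = el[, 1], symbol_b = el[, 2],
                           system_type = "physical",
                           organism_a = 9606L, organism_b = 9606L),
                file.path(out, "interactome_records.tsv"))

er <- gen_er(3000, 2 * 3000 / choose(3000, 2), seed)
write_interactome(er, file.path(out, "er_control_edges.tsv"))

spec <- synthetic_spec(seed = seed)
planted <- gen_planted_target_map(g, spec)
write_chem_targets(planted$table, file.path(out, "chem_targets.tsv"))
writeLines(planted$module, file.path(out, "planted_module.txt"))
cat(sprintf("planted map: %d chemicals x %d targets, module size %d\n",
            spec$n_chemicals, spec$targets_per_chemical,
            length(planted$module)))

# ten disjoint positional gene sets over the interactome nodes
nodes <- interactome_nodes(g)
gmt_lines <- vapply(1:10, function(i) {
  paste(c(sprintf("SET%02d", i), "synthetic",
          nodes[((i - 1) * 100 + 1):(i * 100)]), collapse = "\t")
}, character(1))
writeLines(gmt_lines, file.path(out, "sets.gmt"))

cat("synthetic inputs written to", out, "\n")
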