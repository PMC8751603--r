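#!/usr/bin/env Rscript
# Combinatorics of the ten published SM reprogramming cocktails: union,
# per-SM frequency, and activity-category coverage. These are exact
# counts over the packaged compositions, no randomness.

suppressPackageStartupMessages(library(reprognet))

out <- "results/cocktails"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

catalog <- sm_catalog()
defs <- cocktail_definitions(catalog = catalog)

union_sms <- cocktail_union(defs)
cat(sprintf("%d cocktails; %d non-redundant SMs\n",
            length(defs), length(union_sms)))
write_result_tsv(data.frame(sm = union_sms), file.path(out, "sm_union.tsv"))

freq <- sm_frequency(defs)
write_result_tsv(freq, file.path(out, "sm_frequency.tsv"))
cat("most frequent SMs:\n")
print(utils::head(freq, 8))

cov <- t(vapply(defs, category_coverage, integer(4), catalog = catalog))
cov_df <- data.frame(cocktail = names(defs),
                     label = attr(defs, "labels"),
                     n_members = lengths(defs), cov,
                     covers_all_three = vapply(defs, covers_core_categories,
                                               logical(1), catalog = catalog),
                     row.names = NULL)
write_result_tsv(cov_df, file.path(out, "category_coverage.tsv"))
cat(sprintf("cocktails covering epigenetic+signaling+metabolic: %d of %d\n",
            sum(cov_df$covers_all_three), nrow(cov_df)))

met <- sm_metabolites()
cat(sprintf("SMs also found in the human metabolome (packaged table): %d\n",
            nrow(met)))
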