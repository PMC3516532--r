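#!/usr/bin/env Rscript
# Fusion-protein domain analysis: breakpoint-relative retention, the 6x6
# domain-category co-occurrence permutation test with BH-FDR, partner-type
# dependence, Bernoulli-mixture clustering of functional profiles, and the
# fusion / interactor network edge lists.
suppressMessages(library(tpghallmarks))

cfg <- pipeline_config("results/bundle", "results/domains",
                       seed = 3, stages = "domains", n_perm_domains = 1e5)
s <- suppressWarnings(run_pipeline(cfg))

cat(sprintf("co-occurrence (BH q < 0.10, %d unique profiles): %d over- and %d under-represented category pairs\n",
            s$domains$n_unique_profiles, s$domains$n_over, s$domains$n_under))
cat(sprintf("partner-type dependence: Fisher p = %.3g; type2-type2 fusions %.1f%% of all, %.2f-fold vs permuted (p = %.3g)\n",
            s$domains$fisher_p, 100 * s$domains$t2t2_fraction,
            s$domains$t2t2_fold, s$domains$t2t2_p))
cat(sprintf("functional-profile clustering selected %d clusters; %d interactor edges exported\n",
            s$domains$n_clusters, s$domains$n_interactor_edges))
cat("tables in results/domains/\n")
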