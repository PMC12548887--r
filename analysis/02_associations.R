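#!/usr/bin/env Rscript
# Stage 2: pairwise association statistics on pairwise-complete data.
#
# For every variable pair: binned mutual information (nats), normalized MI,
# Pearson r, and permutation p-values (1000 permutations; one-tailed for MI,
# two-tailed for Pearson).

library(mlnpaths)

seed <- 1L
cohort <- read_cohort("results/cohort_data.tsv", "results/cohort_meta.tsv")

assoc <- association_table(cohort, n_perm = 1000, seed = seed)
write_association_table(assoc, "results/associations.tsv")

alpha <- 0.05
cat(sprintf("Pairs tested: %d\n", nrow(assoc)))
cat(sprintf("MI-significant at alpha=%.2f:      %d (%.1f%%)\n", alpha,
            sum(assoc$p_mi < alpha, na.rm = TRUE),
            100 * mean(assoc$p_mi < alpha, na.rm = TRUE)))
cat(sprintf("Pearson-significant at alpha=%.2f: %d (%.1f%%)\n", alpha,
            sum(assoc$p_r < alpha, na.rm = TRUE),
            100 * mean(assoc$p_r < alpha, na.rm = TRUE)))
within <- assoc$layer_a == assoc$layer_b
cat(sprintf("Within-layer significant fraction:  %.3f\n",
            mean(assoc$p_mi[within] < alpha, na.rm = TRUE)))
cat(sprintf("Between-layer significant fraction: %.3f\n",
            mean(assoc$p_mi[!within] < alpha, na.rm = TRUE)))
cat("Wrote results/associations.tsv\n")
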