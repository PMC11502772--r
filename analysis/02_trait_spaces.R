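#!/usr/bin/env Rscript
# Stage 2: the main trait-space grid on pairwise-complete correlations.
# Three base trait sets (UPFS, GSPFF, RES) x four root-size inclusion
# levels x three growth-form groups, each with Kaiser retention, loadings,
# angles, END and a 500-rep uncorrelated-trait null.
#
# Input:  results/data/synthetic_traits.csv   (stage 1)
# Output: results/main/  (space_summary, proportional_increases,
#         eigenvalues, loadings, angles, angle_comparisons, bundle.json)

library(traitdims)

x <- load_trait_table("results/data/synthetic_traits.csv",
                      transform = "log_scaled")

bundle <- run_space_suite(x, estimator = "pairwise",
                          groups = c("all", "woody", "herbaceous"),
                          reps = 500, seed = 101)
write_bundle(bundle, "results/main")

cat("== Space summary (group = all) ==\n")
smry <- bundle_summary(bundle)
print(smry[smry$group == "all", c("space_id", "n_species", "retained",
                                  "var_retained_pct", "end",
                                  "end_random_mean")])

cat("\n== Proportional END increases vs the uncorrelated-trait null ==\n")
pi_tab <- summarize_proportional_increases(bundle)
print(pi_tab[pi_tab$group == "all", ])

cat("\nReading: root-size analogues barely move (or shrink) UPFS/GSPFF",
    "dimensionality, but act as genuinely new dimensions in the RES --",
    "the redundant-versus-novel dichotomy of the empirical analysis.\n")
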