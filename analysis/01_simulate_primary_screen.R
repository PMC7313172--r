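#!/usr/bin/env Rscript
# Simulate the primary ex vivo screen: a 1160-compound library at three
# 2-fold doses from 5 uM on an imaging assay, for a slowly dividing primary
# culture (0.3 doublings per 72-h window, i.e. a 240-h doubling time), with
# 5% multiplicative measurement noise and 49 planted fully cytotoxic drugs.
# Writes the well-level screen table and the generating ground truth.

library(grscreen)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_compounds = 1160, dose_design = dose_series(5, 2, 3),
                  doublings = c(imaging_2d = 0.3, enzymatic_2d = 0.3,
                                imaging_3d = 0.3),
                  noise_cv = 0.05, rng_seed = seed, n_planted_hits = 49)
truth <- make_drug_truth(cfg)
run <- simulate_run(cfg, truth, "imaging_2d")

write_screen_table(run$table, "results/primary_screen.csv")
utils::write.csv(truth, "results/primary_ground_truth.csv", row.names = FALSE)

cat(sprintf("simulated %d wells on %d plates (%d treated, %d controls)\n",
            nrow(run$table), length(unique(run$table$plate_id)),
            sum(run$table$role == "treated"),
            sum(run$table$role != "treated")))
cat(sprintf("planted %d cytotoxic drugs (gr_inf < 0, gec50 below the lowest dose)\n",
            sum(truth$planted_hit)))
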