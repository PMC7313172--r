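#!/usr/bin/env Rscript
# Estimate the culture's division rate from plate controls, compute per-dose
# GR values, and nominate hits: compounds with GR < 0 at every tested dose,
# i.e. more growth-inhibitory than the hydroxyurea proliferation stall.
# Reads the screen table written by 01_simulate_primary_screen.R.

library(grscreen)

run <- assay_run(read_screen_table("results/primary_screen.csv"),
                 "imaging_2d", assay_window_T = 72)

growth <- estimate_growth(run)
print(growth)

hits <- call_hits(gr_table(run))
utils::write.csv(hits, "results/ranking.csv", row.names = FALSE)
utils::write.csv(hits[hits$is_hit, ], "results/hits.csv", row.names = FALSE)

truth <- utils::read.csv("results/primary_ground_truth.csv")
called <- hits$compound_id[hits$is_hit]
planted <- truth$compound_id[truth$planted_hit]
cat(sprintf("nominated %d hits of %d compounds (planted: %d; agreement: %s)\n",
            sum(hits$is_hit), nrow(hits), length(planted),
            if (setequal(called, planted)) "exact" else
              sprintf("%d shared", length(intersect(called, planted)))))
cat("most cytotoxic compound:", hits$compound_id[1],
    sprintf("(mean GR %.2f)\n", hits$mean_gr[1]))
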