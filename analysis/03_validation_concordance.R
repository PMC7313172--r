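#!/usr/bin/env Rscript
# Validation screen: the 90 most cytotoxic compounds re-screened at five
# 2-fold doses from 5 uM on three techniques (imaging 2D, enzymatic 2D,
# imaging 3D at 0.6 / 0.5 / 0.3 doublings per 72 h), GR-normalized and
# compared: per-dose Pearson concordance, top-30 overlap, and hierarchical
# clustering of the drug x (technique.dose) GR matrix.

library(grscreen)

seed <- 1L
ranking <- utils::read.csv("results/ranking.csv")
truth <- utils::read.csv("results/primary_ground_truth.csv")

val_ids <- utils::head(ranking$compound_id, 90)
vtruth <- truth[match(val_ids, truth$compound_id), ]
vcfg <- sim_config(n_compounds = 90, dose_design = dose_series(5, 2, 5),
                   noise_cv = 0.05, rng_seed = seed + 13L,
                   n_planted_hits = 0, n_replicates = 3)

runs <- lapply(stats::setNames(c("imaging_2d", "enzymatic_2d", "imaging_3d"),
                               c("imaging_2d", "enzymatic_2d", "imaging_3d")),
               function(t) simulate_run(vcfg, vtruth, t))
profs <- lapply(runs, gr_profiles, fit = TRUE)
utils::write.csv(do.call(rbind, profs), "results/validation_gr_profiles.csv",
                 row.names = FALSE)

longs <- lapply(profs, attr, "gr_long")
conc <- concordance(longs, n_top = 30)
jsonlite::write_json(list(pairs = conc$pairs,
                          triple_overlap = conc$triple_overlap),
                     "results/concordance.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
print(conc$pairs)
cat(sprintf("three-way top-30 overlap: %d drugs\n", conc$triple_overlap))

mats <- lapply(names(longs), function(t) {
  w <- stats::reshape(longs[[t]][c("compound_id", "dose_uM", "gr")],
                      idvar = "compound_id", timevar = "dose_uM",
                      direction = "wide")
  m <- as.matrix(w[-1]); rownames(m) <- w$compound_id
  colnames(m) <- paste0(t, ".", sub("^gr\\.", "", colnames(m)))
  m[order(rownames(m)), , drop = FALSE]
})
cl <- cluster_dose_matrix(do.call(cbind, mats))
utils::write.csv(data.frame(leaf = cl$leaf_order),
                 "results/cluster_leaf_order.csv", row.names = FALSE)
cat(sprintf("clustered %d drugs; first merge at height %.3f\n",
            length(cl$leaf_order), min(cl$heights)))
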