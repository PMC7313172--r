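# Shared fixture builders. Everything is generated in code at test time.

# A one-plate screen table: nc compounds at the given doses (single wells),
# with 14/14/8 control wells and exact (noise-free) signals unless a signal
# function is supplied.
toy_screen_table <- function(nc = 3, doses = c(5, 2.5, 1.25),
                             neg = 2000, hu = 1000, pos = 20,
                             treated_signal = function(comp, dose) hu) {
  wells <- well_labels_384()
  ctrl_roles <- rep(c("negative_dmso", "proliferation_hydroxyurea",
                      "positive_staurosporine"), times = c(14, 14, 8))
  ctrl <- data.frame(plate_id = "P1", well = wells[seq_along(ctrl_roles)],
                     compound_id = "", dose_uM = 0, channel = "luminescence",
                     signal = rep(c(neg, hu, pos), times = c(14, 14, 8)),
                     role = ctrl_roles, stringsAsFactors = FALSE)
  gr <- expand.grid(dose = doses, comp = sprintf("C%02d", seq_len(nc)),
                    stringsAsFactors = FALSE)
  tr <- data.frame(plate_id = "P1",
                   well = wells[36 + seq_len(nrow(gr))],
                   compound_id = gr$comp, dose_uM = gr$dose,
                   channel = "luminescence",
                   signal = mapply(treated_signal, gr$comp, gr$dose),
                   role = "treated", stringsAsFactors = FALSE)
  screen_table(rbind(ctrl, tr))
}

# Exact median-effect fraction affected.
hill_fa <- function(D, m, dm) (D / dm)^m / (1 + (D / dm)^m)

# Median-effect fit from exact (m, dm) points on a 3-fold series from 5 uM.
exact_me_fit <- function(m, dm, doses = dose_series(5, 3, 6)$doses) {
  median_effect_fit(doses, hill_fa(doses, m, dm))
}

# Ground-truth row in the generator's format.
truth_row <- function(id, gr_inf, gec50, hill) {
  data.frame(compound_id = id, gr_inf = gr_inf, gec50 = gec50, hill = hill,
             shift_enzymatic_2d = 1, shift_imaging_2d = 1,
             shift_imaging_3d = 1, planted_hit = gr_inf < 0,
             stringsAsFactors = FALSE)
}

# Small-library config for fast end-to-end runs.
small_cfg <- function(seed = 1, n = 60, hits = 5, noise = 0,
                      doses = dose_series(5, 2, 3), reps = 1,
                      doublings = c(imaging_2d = 0.6, enzymatic_2d = 0.5,
                                    imaging_3d = 0.3)) {
  sim_config(n_compounds = n, dose_design = doses, noise_cv = noise,
             rng_seed = seed, n_planted_hits = hits, n_replicates = reps,
             doublings = doublings)
}
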