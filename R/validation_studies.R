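# Simulation studies used to validate the pipeline's statistical behaviour.

#' Parameter-recovery simulation study
#'
#' Simulates a library of responder drugs (gr_inf uniform in [-0.8, 0.4],
#' gec50 log-uniform across the tested dose range, hill in [1, 3]) at five
#' 2-fold doses from 5 uM in triplicate wells on the enzymatic 2D technique,
#' runs the full simulate -> GR -> fit pipeline, and summarizes how well the
#' GR-curve fit recovers the generating parameters.
#'
#' GR normalization divides the per-well log-signal noise by the window's
#' doublings k*T, so a 5 percent signal CV becomes a ~10 percent CV on
#' GR + 1 at k*T = 0.5; recovery of the asymptote gr_inf is bounded by that
#' information limit, and is poorest for shallow curves with gec50 near the
#' top dose (plateau never observed).
#'
#' @param seed integer seed
#' @param n_drugs library size (100 by default)
#' @param noise_cv signal noise CV (0.05 by default)
#' @param n_replicates wells per dose (triplicate by default)
#' @param dose_design the validation dose series
#' @return list: \code{per_drug} data.frame (truth and estimates),
#'   \code{median_abs_err_gr_inf}, \code{median_fold_err_gec50} (censored
#'   fits count as infinite fold error)
#' @export
parameter_recovery_study <- function(seed = 1L, n_drugs = 100,
                                     noise_cv = 0.05, n_replicates = 3L,
                                     dose_design = dose_series(5, 2, 5)) {
  cfg <- sim_config(n_compounds = n_drugs, dose_design = dose_design,
                    noise_cv = noise_cv, rng_seed = seed,
                    n_planted_hits = 0, n_replicates = n_replicates)
  rng <- range(dose_design$doses)
  truth <- with_seed(seed + 500L, data.frame(
    compound_id = sprintf("D%03d", seq_len(n_drugs)),
    gr_inf = stats::runif(n_drugs, -0.8, 0.4),
    gec50 = 10^stats::runif(n_drugs, log10(rng[1]), log10(rng[2])),
    hill = stats::runif(n_drugs, 1, 3),
    shift_enzymatic_2d = 1, shift_imaging_2d = 1, shift_imaging_3d = 1,
    planted_hit = FALSE, stringsAsFactors = FALSE))
  run <- simulate_run(cfg, truth, "enzymatic_2d")
  prof <- gr_profiles(run, fit = TRUE)
  m <- merge(prof, truth, by = "compound_id",
             suffixes = c("_hat", "_true"))
  fold_err <- exp(abs(log(m$gec50_hat / m$gec50_true)))
  fold_err[!is.finite(fold_err)] <- Inf
  list(per_drug = m,
       median_abs_err_gr_inf = stats::median(abs(m$gr_inf_hat - m$gr_inf_true)),
       median_fold_err_gec50 = stats::median(fold_err))
}

#' Type-I error of the dilution-series Welch comparison
#'
#' Simulates null pairs of dose series (both vectors drawn from the same
#' normal distribution) and reports the fraction rejected at the given
#' alpha.
#'
#' @param n_sims number of simulated pairs
#' @param n per-group size (5, the typical dilution-series length)
#' @param alpha significance level
#' @param seed integer seed
#' @return rejection rate
#' @export
welch_type1_study <- function(n_sims = 10000, n = 5, alpha = 0.05,
                              seed = 1L) {
  with_seed(seed, {
    rej <- vapply(seq_len(n_sims), function(i) {
      welch_dose_series(stats::rnorm(n), stats::rnorm(n))$p < alpha
    }, logical(1))
    mean(rej)
  })
}
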