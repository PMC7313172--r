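test_that("median-effect fit recovers exact parameters", {
  # by definition fa = 0.5 at D = Dm
  f1 <- exact_me_fit(1, 1)
  expect_equal(hill_fa(1, 1, 1), 0.5)
  expect_equal(f1$m, 1, tolerance = 1e-9)
  expect_equal(f1$dm, 1, tolerance = 1e-9)

  f2 <- exact_me_fit(2, 0.5)
  expect_true(f2$valid)
  expect_equal(f2$m, 2, tolerance = 1e-9)
  expect_equal(f2$dm, 0.5, tolerance = 1e-9)
  expect_equal(f2$r2, 1, tolerance = 1e-9)
})

test_that("degenerate effect levels are discarded before fitting", {
  f <- median_effect_fit(c(1, 2, 4), c(0, 0.01, 1))
  expect_false(f$valid)                      # one usable point only
  expect_equal(f$n_points_used, 1)

  f2 <- median_effect_fit(c(1, 2, 4, 8), c(0, 0.2, 0.5, 1))
  expect_true(f2$valid)
  expect_equal(f2$n_points_used, 2)

  down <- median_effect_fit(c(1, 2, 4), c(0.8, 0.5, 0.2))  # effect falls with dose
  expect_false(down$valid)
})

test_that("CI matches the hand-evaluated fixed-ratio formula", {
  fa6 <- dose_series(5, 3, 6)$doses
  fit_a <- exact_me_fit(1, 1)
  fit_b <- exact_me_fit(1, 2.5)
  fit_mix <- exact_me_fit(1, 0.4)
  ci <- compute_ci(fit_a, fit_b, fit_mix, ratio_R = 2.5, fa_x = 0.5)
  # d1 = 0.4/3.5, d2 = 0.4*2.5/3.5; CI = d1/1 + d2/2.5 = 8/35
  expect_equal(unname(ci), 0.4 / 3.5 + (0.4 * 2.5 / 3.5) / 2.5,
               tolerance = 1e-9)
  expect_equal(unname(ci), 0.229, tolerance = 2e-3)
})

test_that("sham self-combination gives CI = 1 at every effect level", {
  f <- exact_me_fit(1.7, 0.9)
  ci <- compute_ci(f, f, f, ratio_R = 1,
                   fa_x = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95))
  expect_equal(unname(ci), rep(1, 7), tolerance = 1e-6)
  # ratio does not matter for a self-combination
  ci2 <- compute_ci(f, f, f, ratio_R = 2.5, fa_x = 0.5)
  expect_equal(unname(ci2), 1, tolerance = 1e-6)
})

test_that("compute_ci agrees with a numerical root-finding oracle", {
  # oracle: find the dose reaching fa = x on each curve by root-finding on
  # the un-linearized median-effect relation, then assemble CI directly
  oracle_ci <- function(fit_a, fit_b, fit_mix, R, fa_x) {
    dose_at <- function(fit, target) {
      f <- function(ld) hill_fa(10^ld, fit$m, fit$dm) - target
      10^stats::uniroot(f, c(-12, 12), tol = 1e-14)$root
    }
    d_mix <- dose_at(fit_mix, fa_x)
    d1 <- d_mix / (1 + R); d2 <- d_mix * R / (1 + R)
    d1 / dose_at(fit_a, fa_x) + d2 / dose_at(fit_b, fa_x)
  }
  set.seed(11)
  for (i in 1:100) {
    fa <- exact_me_fit(runif(1, 0.5, 3), 10^runif(1, -1.5, 0.7))
    fb <- exact_me_fit(runif(1, 0.5, 3), 10^runif(1, -1.5, 0.7))
    fm <- exact_me_fit(runif(1, 0.5, 3), 10^runif(1, -1.5, 0.7))
    R <- 10^runif(1, -1, 1)
    x <- runif(1, 0.1, 0.9)
    ci <- unname(compute_ci(fa, fb, fm, R, x))
    expect_equal(ci, oracle_ci(fa, fb, fm, R, x), tolerance = 1e-6)
  }
})

test_that("CI is scale-invariant and monotone in the mixture Dm", {
  f <- function(m, dm) {
    structure(list(m = m, dm = dm, r2 = 1, n_points_used = 6, valid = TRUE),
              class = "median_effect_fit")
  }
  base <- unname(compute_ci(f(1.2, 0.8), f(0.9, 2), f(1.1, 0.5), 2.5, 0.5))
  scaled <- unname(compute_ci(f(1.2, 8), f(0.9, 20), f(1.1, 5), 2.5, 0.5))
  expect_equal(base, scaled, tolerance = 1e-12)

  dms <- c(1, 0.5, 0.25, 0.1)
  cis <- vapply(dms, function(dm)
    unname(compute_ci(f(1.2, 0.8), f(0.9, 2), f(1.1, dm), 2.5, 0.5)),
    numeric(1))
  expect_true(all(diff(cis) < 0))
})

test_that("fixed-ratio extraction finds the 1:2.5 diagonal and the margins", {
  ta <- truth_row("A", -0.9, 0.2, 1.2)
  tb <- truth_row("B", -0.8, 0.9, 1.0)
  cm <- simulate_combo_matrix(ta, tb, cfg = small_cfg(noise = 0))
  ser <- extract_fixed_ratio(cm)
  expect_equal(ser$ratio_R, 2.5, tolerance = 1e-9)
  expect_equal(nrow(ser$mix), 6)
  expect_equal(ser$a$dose_uM, dose_series(2, 3, 6)$doses, tolerance = 1e-12)
  expect_equal(ser$b$dose_uM, dose_series(5, 3, 6)$doses, tolerance = 1e-12)
  # partner-dose-0 column reproduces the single-agent series: fa increases
  # with dose along the margin
  expect_true(all(diff(rev(ser$a$fa)) >= 0))
})

test_that("a ratio-breaking design is rejected", {
  ta <- truth_row("A", -0.9, 0.2, 1.2)
  tb <- truth_row("B", -0.8, 0.9, 1.0)
  cm <- simulate_combo_matrix(ta, tb, design_a = dose_series(2, 3, 6),
                              design_b = dose_series(5, 2.9, 6),
                              cfg = small_cfg(noise = 0))
  expect_error(extract_fixed_ratio(cm), "ratio not constant")
})

test_that("sham matrices run through the pipeline give CI50 near 1", {
  # at one doubling per window the generated survival is exactly a Hill
  # curve, so the median-effect model holds and the sham identity is exact
  # up to measurement noise
  ta <- truth_row("A", -1, 0.35, 0.8)
  cfg <- sim_config(noise_cv = 0.02, rng_seed = 1, pos_floor_frac = 1e-6,
                    doublings = c(imaging_2d = 1, enzymatic_2d = 1,
                                  imaging_3d = 1))
  cm <- simulate_combo_matrix(ta, ta, interaction = "sham", cfg = cfg)
  cr <- combination_result(cm)
  expect_equal(cr$ci50, 1, tolerance = 0.02)

  cfg0 <- sim_config(noise_cv = 0, rng_seed = 1, pos_floor_frac = 1e-6,
                     doublings = c(imaging_2d = 1, enzymatic_2d = 1,
                                   imaging_3d = 1))
  cr0 <- combination_result(simulate_combo_matrix(ta, ta, interaction = "sham",
                                                  cfg = cfg0))
  expect_equal(cr0$ci50, 1, tolerance = 1e-4)
})

test_that("planted synergy and antagonism move CI50 to the expected side", {
  ta <- truth_row("A", -0.6, 0.08, 1.2)
  tb <- truth_row("B", -0.5, 0.24, 1.0)
  syn <- combination_result(simulate_combo_matrix(
    ta, tb, interaction = "synergy", factor = 10, cfg = small_cfg(noise = 0)))
  expect_lt(syn$ci50, 1)
  ant <- combination_result(simulate_combo_matrix(
    ta, tb, interaction = "antagonism", factor = 10,
    cfg = small_cfg(noise = 0)))
  expect_gt(ant$ci50, 1)
})

test_that("combo matrices round-trip through the percent-viability CSV", {
  ta <- truth_row("A", -0.9, 0.2, 1.2)
  tb <- truth_row("B", -0.8, 0.9, 1.0)
  cm <- simulate_combo_matrix(ta, tb, cfg = small_cfg(noise = 0))
  pv <- percent_viability(cm$cells$signal, cm$controls[["neg_median"]],
                          cm$controls[["pos_median"]])
  df <- data.frame(dose_a_uM = cm$cells$dose_a_uM,
                   dose_b_uM = cm$cells$dose_b_uM,
                   replicate = cm$cells$replicate,
                   percent_viability = pv)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  cm2 <- read_combo_matrix(f, "A", "B")
  cr <- combination_result(cm)
  cr2 <- combination_result(cm2)
  expect_equal(cr2$ci50, cr$ci50, tolerance = 1e-6)
})
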