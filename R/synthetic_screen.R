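# Seeded generator of synthetic 384-well screens with known ground truth.
#
# The generative model inverts the GR definition: a drug whose true GR value
# at dose c is g grows from x0 seeded cells to
#   x(c) = x0 * (x_ctrl/x0)^(log2(g + 1)),   x_ctrl = x0 * 2^(k*T),
# so that the downstream GR computation recovers g exactly in the noise-free
# case regardless of the culture's division rate k*T.

#' Default doublings per 72-h assay window by technique
#' @keywords internal
DEFAULT_DOUBLINGS <- c(imaging_2d = 0.6, enzymatic_2d = 0.5, imaging_3d = 0.3)

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Study-condition defaults: a 1160-compound library at three 2-fold doses
#' from 5 uM, 384-well plates carrying 14 DMSO negative, 14 hydroxyurea
#' proliferation-stall and 8 staurosporine positive control wells (348
#' treated wells per plate), division rates of 0.6 / 0.5 / 0.3 doublings per
#' 72 h for the imaging-2D / enzymatic-2D / imaging-3D techniques, seeding of
#' 1000 cells (2D) or 2000 cells (3D), multiplicative lognormal measurement
#' noise with CV 0.05, and 49 planted fully cytotoxic drugs.
#'
#' @param n_compounds library size
#' @param dose_design a \code{\link{dose_series}}
#' @param doublings named vector, doublings per assay window by technique
#' @param seed_cells named vector: cells seeded per well, 2D and 3D
#' @param noise_cv lognormal coefficient of variation of the measurement
#'   noise; 0 yields deterministic tables
#' @param luminescence_gain photons-per-cell scale for the enzymatic channel
#' @param rng_seed integer seed; all randomness flows from it
#' @param n_planted_hits drugs planted with gr_inf < 0 and gec50 far below
#'   the lowest dose
#' @param n_replicates wells per compound x dose (single wells by default,
#'   as in a primary screen)
#' @param pos_floor_frac staurosporine positive-control floor as a fraction
#'   of seeding (kills without reaching exactly zero)
#' @param assay_window_T assay duration, hours
#' @return a \code{sim_config} list
#' @export
sim_config <- function(n_compounds = 1160,
                       dose_design = dose_series(5, 2, 3),
                       doublings = DEFAULT_DOUBLINGS,
                       seed_cells = c(`2d` = 1000, `3d` = 2000),
                       noise_cv = 0.05,
                       luminescence_gain = 10,
                       rng_seed = 1L,
                       n_planted_hits = 49,
                       n_replicates = 1L,
                       pos_floor_frac = 0.02,
                       assay_window_T = 72) {
  stopifnot(n_compounds >= 1, inherits(dose_design, "dose_series"),
            all(is.finite(doublings)), all(seed_cells > 0),
            noise_cv >= 0, luminescence_gain > 0,
            n_planted_hits >= 0, n_planted_hits <= n_compounds,
            n_replicates >= 1, pos_floor_frac > 0, assay_window_T > 0)
  structure(list(n_compounds = as.integer(n_compounds),
                 dose_design = dose_design, doublings = doublings,
                 seed_cells = seed_cells, noise_cv = noise_cv,
                 luminescence_gain = luminescence_gain,
                 rng_seed = as.integer(rng_seed),
                 n_planted_hits = as.integer(n_planted_hits),
                 n_replicates = as.integer(n_replicates),
                 pos_floor_frac = pos_floor_frac,
                 assay_window_T = assay_window_T),
            class = "sim_config")
}

#' Draw a drug ground-truth table
#'
#' Each drug carries a sigmoid GR dose-response
#' \code{GR(c) = gr_inf + (1 - gr_inf) / (1 + (c / gec50)^hill)}. The table
#' plants \code{n_planted_hits} fully cytotoxic drugs (gr_inf in
#' [-0.95, -0.5], gec50 two or more decades below the lowest dose, so GR < 0
#' at every tested dose), splits the remainder between inactive drugs
#' (gr_inf = 1) and partial responders (gr_inf in [0.3, 0.95], gec50 spanning
#' the dose range), and gives every technique a potency shift of 1 unless a
#' fraction of active drugs is assigned extra 3D potency.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param frac_active fraction of non-hit drugs that respond partially
#' @param shift_3d_frac fraction of partial responders whose gec50 is divided
#'   by \code{shift_3d_factor} in the 3D technique (emulating drug classes
#'   that act more potently on spheroid cultures)
#' @param shift_3d_factor potency gain in 3D for that subset
#' @return data.frame: compound_id, gr_inf, gec50, hill, shift_enzymatic_2d,
#'   shift_imaging_2d, shift_imaging_3d, planted_hit
#' @export
make_drug_truth <- function(cfg, frac_active = 0.4,
                            shift_3d_frac = 0, shift_3d_factor = 3) {
  n <- cfg$n_compounds
  nh <- cfg$n_planted_hits
  min_dose <- min(cfg$dose_design$doses)
  with_seed(cfg$rng_seed, {
    id <- sprintf("C%04d", seq_len(n))
    gr_inf <- rep(1, n); gec50 <- rep(1, n); hill <- rep(1, n)
    planted <- rep(FALSE, n)
    hit_idx <- seq_len(nh)
    planted[hit_idx] <- TRUE
    gr_inf[hit_idx] <- stats::runif(nh, -0.95, -0.5)
    gec50[hit_idx] <- min_dose / 10^stats::runif(nh, 2, 3)
    hill[hit_idx] <- stats::runif(nh, 1, 3)
    rest <- setdiff(seq_len(n), hit_idx)
    n_act <- round(frac_active * length(rest))
    act <- rest[seq_len(n_act)]
    gr_inf[act] <- stats::runif(n_act, 0.3, 0.95)
    gec50[act] <- 10^stats::runif(n_act, log10(min_dose / 2),
                                  log10(max(cfg$dose_design$doses) * 4))
    hill[act] <- stats::runif(n_act, 0.5, 3)
    shift3 <- rep(1, n)
    if (shift_3d_frac > 0 && n_act > 0) {
      n3 <- round(shift_3d_frac * n_act)
      shift3[act[seq_len(n3)]] <- 1 / shift_3d_factor
    }
    truth <- data.frame(compound_id = id, gr_inf = gr_inf, gec50 = gec50,
                        hill = hill, shift_enzymatic_2d = 1,
                        shift_imaging_2d = 1, shift_imaging_3d = shift3,
                        planted_hit = planted, stringsAsFactors = FALSE)
    # shuffle so hits are not a contiguous block of compound ids on plates
    truth[sample.int(n), , drop = FALSE]
  })
}

#' Sigmoid GR dose-response value
#'
#' \code{GR(c) = gr_inf + (1 - gr_inf) / (1 + (c / gec50)^hill)}: the curve
#' shape shared by the generator's ground truth and the GR-curve fit.
#'
#' @param dose dose(s), uM
#' @param gr_inf asymptotic GR at saturating dose
#' @param gec50 half-effect dose, uM
#' @param hill sigmoid steepness
#' @return GR value(s)
#' @export
gr_true_at <- function(dose, gr_inf, gec50, hill) {
  gr_inf + (1 - gr_inf) / (1 + (dose / gec50)^hill)
}

expected_count <- function(gr_true, x0, x_ctrl) {
  if (any(gr_true + 1 <= 0))
    stop("ground truth implies GR + 1 <= 0; log undefined", call. = FALSE)
  x0 * (x_ctrl / x0)^(log2(gr_true + 1))
}

lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))   # mean exactly 1
}

technique_channel <- function(technique) {
  if (technique == "enzymatic_2d") "luminescence" else "nuclei_count"
}

technique_seed_cells <- function(cfg, technique) {
  if (technique == "imaging_3d") cfg$seed_cells[["3d"]] else cfg$seed_cells[["2d"]]
}

#' Simulate one screening campaign on one technique
#'
#' Plates are filled with 14 + 14 + 8 control wells (DMSO, hydroxyurea,
#' staurosporine) in the leftmost columns and 348 treated wells. Hydroxyurea
#' wells stall at the seeding count x0, negative wells grow to
#' x0 * 2^(k*T), staurosporine wells decay to the positive-control floor,
#' and treated wells follow the inverted GR model. Enzymatic runs report
#' \code{gain * count} on the luminescence channel; imaging runs report
#' counts directly. Multiplicative lognormal noise is applied to every
#' signal.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param truth ground-truth table from \code{\link{make_drug_truth}}
#'   (must cover all compounds)
#' @param technique one of enzymatic_2d, imaging_2d, imaging_3d
#' @return an \code{\link{assay_run}} with the ground truth attached as
#'   \code{attr(, "truth")} and the noise-free expected signal per treated
#'   well retained in \code{attr(, "truth_wells")}
#' @export
simulate_run <- function(cfg, truth = make_drug_truth(cfg),
                         technique = "imaging_2d") {
  technique <- match.arg(technique, TECHNIQUES)
  stopifnot(inherits(cfg, "sim_config"), nrow(truth) >= cfg$n_compounds)
  kT <- cfg$doublings[[technique]]
  x0 <- technique_seed_cells(cfg, technique)
  x_ctrl <- x0 * 2^kT
  x_pos <- cfg$pos_floor_frac * x0
  shift <- truth[[paste0("shift_", technique)]]
  doses <- cfg$dose_design$doses
  channel <- technique_channel(technique)
  gain <- if (channel == "luminescence") cfg$luminescence_gain else 1

  # treated design: compound x dose x replicate
  tr <- expand.grid(rep = seq_len(cfg$n_replicates),
                    dose_i = seq_along(doses),
                    comp_i = seq_len(cfg$n_compounds))
  g_true <- gr_true_at(doses[tr$dose_i], truth$gr_inf[tr$comp_i],
                       truth$gec50[tr$comp_i] * shift[tr$comp_i],
                       truth$hill[tr$comp_i])
  counts <- expected_count(g_true, x0, x_ctrl)

  # plate layout: 36 control + 348 treated wells per 384-well plate
  n_ctrl <- c(neg = 14L, hu = 14L, pos = 8L)
  n_treated_per_plate <- 384L - sum(n_ctrl)
  n_treated <- nrow(tr)
  n_plates <- ceiling(n_treated / n_treated_per_plate)
  wells_cm <- as.vector(outer(PLATE_ROWS, PLATE_COLS, paste0))  # column-major
  ctrl_wells <- wells_cm[seq_len(sum(n_ctrl))]
  treat_wells <- wells_cm[-seq_len(sum(n_ctrl))]

  plate_of <- rep(seq_len(n_plates), each = n_treated_per_plate)[seq_len(n_treated)]
  well_of <- rep(treat_wells, n_plates)[seq_len(n_treated)]
  plate_ids <- sprintf("%s_P%02d", technique, seq_len(n_plates))

  treated <- data.frame(
    plate_id = plate_ids[plate_of], well = well_of,
    compound_id = truth$compound_id[tr$comp_i],
    dose_uM = doses[tr$dose_i], channel = channel,
    signal = gain * counts, role = "treated", stringsAsFactors = FALSE)

  ctrl_role <- rep(c("negative_dmso", "proliferation_hydroxyurea",
                     "positive_staurosporine"), times = n_ctrl)
  ctrl_signal <- gain * rep(c(x_ctrl, x0, x_pos), times = n_ctrl)
  controls <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    data.frame(plate_id = plate_ids[p], well = ctrl_wells, compound_id = "",
               dose_uM = 0, channel = channel, signal = ctrl_signal,
               role = ctrl_role, stringsAsFactors = FALSE)
  }))

  tab <- rbind(treated, controls)
  expected <- tab$signal
  with_seed(cfg$rng_seed + 7L * match(technique, TECHNIQUES), {
    tab$signal <- tab$signal * lognorm_noise(nrow(tab), cfg$noise_cv)
  })
  run <- assay_run(screen_table(tab), technique, cfg$assay_window_T)
  attr(run, "truth") <- truth
  attr(run, "truth_wells") <- data.frame(
    plate_id = tab$plate_id, well = tab$well, expected_signal = expected,
    stringsAsFactors = FALSE)
  run
}

#' Simulate a combination dose matrix
#'
#' A full factorial matrix of two dilution series including each drug's
#' single-agent row/column (partner dose 0), in replicate wells, with the
#' usual control wells on the same plate. Under \code{independent} the
#' combined surviving fraction is the product of the single-agent surviving
#' fractions (Bliss independence); \code{synergy}/\code{antagonism} divide or
#' multiply both gec50 values by \code{factor} wherever both drugs are
#' present; \code{sham} requires identical drugs and responds to the total
#' dose on the single-agent curve (same-drug additivity, the Chou-Talalay
#' identity case).
#'
#' @param truth_a,truth_b single-row ground-truth data.frames (compound_id,
#'   gr_inf, gec50, hill)
#' @param design_a,design_b \code{\link{dose_series}} for each drug
#'   (defaults: trametinib-like 3-fold from 2 uM; partner 3-fold from 5 uM)
#' @param interaction "independent", "synergy", "antagonism" or "sham"
#' @param factor potency-shift factor for synergy/antagonism
#' @param cfg a \code{\link{sim_config}} (noise, seeding, gain, seed)
#' @param technique assay technique (enzymatic 2D by default, as in
#'   combination validation experiments)
#' @param n_replicates wells per matrix cell (triplicate default)
#' @return a \code{combo_matrix}: list with \code{$cells} (dose_a_uM,
#'   dose_b_uM, replicate, signal), \code{$controls} (neg/hu/pos medians),
#'   drug ids and the design; ground truth attached as attributes
#' @export
simulate_combo_matrix <- function(truth_a, truth_b,
                                  design_a = dose_series(2, 3, 6),
                                  design_b = dose_series(5, 3, 6),
                                  interaction = c("independent", "synergy",
                                                  "antagonism", "sham"),
                                  factor = 1,
                                  cfg = sim_config(),
                                  technique = "enzymatic_2d",
                                  n_replicates = 3L) {
  interaction <- match.arg(interaction)
  if (interaction == "sham" && !isTRUE(all.equal(truth_a, truth_b)))
    stop("sham mode requires identical drugs", call. = FALSE)
  kT <- cfg$doublings[[technique]]
  x0 <- technique_seed_cells(cfg, technique)
  x_ctrl <- x0 * 2^kT
  x_pos <- cfg$pos_floor_frac * x0
  channel <- technique_channel(technique)
  gain <- if (channel == "luminescence") cfg$luminescence_gain else 1

  da <- c(0, rev(design_a$doses)); db <- c(0, rev(design_b$doses))
  grid <- expand.grid(dose_a_uM = da, dose_b_uM = db,
                      replicate = seq_len(n_replicates))

  surv <- function(dose, gr_inf, gec50, hill) {
    expected_count(gr_true_at(dose, gr_inf, gec50, hill), x0, x_ctrl) / x_ctrl
  }
  both <- grid$dose_a_uM > 0 & grid$dose_b_uM > 0
  pshift <- rep(1, nrow(grid))
  if (interaction == "synergy") pshift[both] <- 1 / factor
  if (interaction == "antagonism") pshift[both] <- factor

  if (interaction == "sham") {
    s <- surv(grid$dose_a_uM + grid$dose_b_uM,
              truth_a$gr_inf, truth_a$gec50, truth_a$hill)
  } else {
    s_a <- surv(grid$dose_a_uM, truth_a$gr_inf, truth_a$gec50 * pshift,
                truth_a$hill)
    s_b <- surv(grid$dose_b_uM, truth_b$gr_inf, truth_b$gec50 * pshift,
                truth_b$hill)
    s <- s_a * s_b
  }
  cells <- grid
  cells$signal <- gain * x_ctrl * s

  n_ctrl <- c(neg = 14L, hu = 14L, pos = 8L)
  ctrl <- data.frame(
    role = rep(c("negative_dmso", "proliferation_hydroxyurea",
                 "positive_staurosporine"), times = n_ctrl),
    signal = gain * rep(c(x_ctrl, x0, x_pos), times = n_ctrl),
    stringsAsFactors = FALSE)

  with_seed(cfg$rng_seed + 101L, {
    cells$signal <- cells$signal * lognorm_noise(nrow(cells), cfg$noise_cv)
    ctrl$signal <- ctrl$signal * lognorm_noise(nrow(ctrl), cfg$noise_cv)
  })
  med <- function(r) stats::median(ctrl$signal[ctrl$role == r])
  structure(list(drug_a = truth_a$compound_id, drug_b = truth_b$compound_id,
                 design_a = design_a, design_b = design_b,
                 cells = cells,
                 controls = c(neg_median = med("negative_dmso"),
                              hu_median = med("proliferation_hydroxyurea"),
                              pos_median = med("positive_staurosporine")),
                 technique = technique),
            class = "combo_matrix",
            truth_a = truth_a, truth_b = truth_b, interaction = interaction)
}
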