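# End-to-end orchestration: simulate (or read) -> GR -> triage -> dose
# response -> combination, writing a deterministic output bundle.

#' Pipeline configuration
#'
#' All randomness flows from \code{seed}. By default the pipeline emulates a
#' full screening campaign: a primary screen of the whole library at three
#' 2-fold doses from 5 uM on an imaging assay growing 0.3 doublings per
#' 72 h, a validation screen of the top compounds at five 2-fold doses from
#' 5 uM on three techniques (0.6 / 0.5 / 0.3 doublings), and one
#' fixed-ratio combination matrix. Supplying \code{primary_input} (list:
#' \code{path}, \code{plate_map}, \code{technique}) analyzes an existing
#' screen-table CSV instead of simulating one.
#'
#' @param out_dir output directory (created if missing)
#' @param seed integer master seed
#' @param n_compounds,n_planted_hits primary-library size and planted hits
#' @param noise_cv measurement noise CV
#' @param n_validation compounds carried into the validation screen
#' @param n_top top-set size for concordance overlap
#' @param primary_doublings division rate of the primary culture
#'   (doublings per assay window)
#' @param primary_input optional external input (see above)
#' @return a \code{pipeline_config} list
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            n_compounds = 1160, n_planted_hits = 49,
                            noise_cv = 0.05,
                            n_validation = 90, n_top = 30,
                            primary_doublings = 0.3,
                            primary_input = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_compounds = n_compounds, n_planted_hits = n_planted_hits,
                 noise_cv = noise_cv, n_validation = n_validation,
                 n_top = n_top, primary_doublings = primary_doublings,
                 primary_input = primary_input),
            class = "pipeline_config")
}

#' Run the full screening-analysis pipeline
#'
#' Stages: primary (simulate or read; growth estimate; per-dose GR; hit
#' nomination and ranking), validation (three techniques on the most
#' cytotoxic compounds; GR profiles with curve fits; concordance; dose
#' clustering), dose_response (4PL viability fits and IC50s), combination
#' (fixed-ratio matrix and CI). Each stage appends a row-count line to
#' \code{log.txt}; any stage error aborts with a stage-tagged message and a
#' \code{FAILED} marker next to the partial outputs. Two runs with the same
#' config are byte-identical.
#'
#' @param config a \code{\link{pipeline_config}}
#' @return (invisibly) list of the main in-memory results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  unlink(c(logf, file.path(config$out_dir, "FAILED")))
  log_line <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  jwrite <- function(x, f)
    jsonlite::write_json(x, file.path(config$out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  cwrite <- function(x, f)
    utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE)

  jwrite(unclass(config), "config.json")
  log_line("pipeline seed=", config$seed)

  # ---- primary screen -------------------------------------------------------
  res <- list()
  stage("primary", {
    if (is.null(config$primary_input)) {
      cfg <- sim_config(n_compounds = config$n_compounds,
                        dose_design = dose_series(5, 2, 3),
                        doublings = c(imaging_2d = config$primary_doublings,
                                      enzymatic_2d = config$primary_doublings,
                                      imaging_3d = config$primary_doublings),
                        noise_cv = config$noise_cv,
                        rng_seed = config$seed,
                        n_planted_hits = config$n_planted_hits)
      truth <- make_drug_truth(cfg)
      run <- simulate_run(cfg, truth, "imaging_2d")
      res$truth <- truth
      write_screen_table(run$table,
                         file.path(config$out_dir, "primary_screen.csv"))
    } else {
      run <- assay_run(read_screen_table(config$primary_input$path,
                                         config$primary_input$plate_map),
                       config$primary_input$technique)
    }
    res$primary_run <- run
    growth <- estimate_growth(run)
    jwrite(list(doublings_per_window = growth$doublings_per_window,
                doubling_time_h = growth$doubling_time,
                window_T = growth$window_T), "primary_growth.json")
    gr_long <- gr_table(run)
    hits <- call_hits(gr_long)
    res$gr_long <- gr_long; res$hits <- hits; res$growth <- growth
    cwrite(hits, "ranking.csv")
    cwrite(hits[hits$is_hit, ], "hits.csv")
    log_line("primary: wells=", nrow(run$table), " compounds=",
             nrow(hits), " hits=", sum(hits$is_hit))
  })

  # ---- validation screen: three techniques ----------------------------------
  stage("validation", {
    if (is.null(config$primary_input)) {
      n_val <- min(config$n_validation, nrow(res$truth))
      val_ids <- top_cytotoxic(res$hits, n_val)
      vtruth <- res$truth[match(val_ids, res$truth$compound_id), ]
      vcfg <- sim_config(n_compounds = n_val,
                         dose_design = dose_series(5, 2, 5),
                         noise_cv = config$noise_cv,
                         rng_seed = config$seed + 13L,
                         n_planted_hits = 0)
      runs <- lapply(stats::setNames(TECHNIQUES, TECHNIQUES),
                     function(t) simulate_run(vcfg, vtruth, t))
      res$validation_runs <- runs
      profs <- lapply(runs, gr_profiles, fit = TRUE)
      res$validation_profiles <- profs
      cwrite(do.call(rbind, profs), "validation_gr_profiles.csv")
      longs <- lapply(profs, attr, "gr_long")
      conc <- concordance(longs, n_top = config$n_top)
      res$concordance <- conc
      jwrite(list(pairs = conc$pairs, triple_overlap = conc$triple_overlap,
                  n_top = conc$n_top), "concordance.json")

      # drugs x (technique.dose) matrix for clustering
      mats <- lapply(names(longs), function(t) {
        w <- stats::reshape(longs[[t]][c("compound_id", "dose_uM", "gr")],
                            idvar = "compound_id", timevar = "dose_uM",
                            direction = "wide")
        m <- as.matrix(w[-1]); rownames(m) <- w$compound_id
        colnames(m) <- paste0(t, ".", sub("^gr\\.", "", colnames(m)))
        m[order(rownames(m)), , drop = FALSE]
      })
      cl <- cluster_dose_matrix(do.call(cbind, mats))
      res$cluster <- cl
      cwrite(data.frame(leaf = cl$leaf_order), "cluster_leaf_order.csv")
      log_line("validation: compounds=", n_val, " mean_r_range=",
               paste(sprintf("%.3f", range(conc$pairs$mean_r)),
                     collapse = ".."))
    } else {
      log_line("validation: skipped (external primary input)")
    }
  })

  # ---- dose-response fits ---------------------------------------------------
  stage("dose_response", {
    run <- if (!is.null(res$validation_runs)) res$validation_runs$enzymatic_2d
           else res$primary_run
    vc <- viability_curves(run)
    res$viability <- vc
    cwrite(vc, "viability_ic50.csv")
    log_line("dose_response: curves=", nrow(vc), " censored=",
             sum(vc$censored != "none"))
  })

  # ---- combination ----------------------------------------------------------
  stage("combination", {
    ta <- data.frame(compound_id = "MEKi", gr_inf = -0.6, gec50 = 0.08,
                     hill = 1.2)
    tb <- data.frame(compound_id = "mTORi", gr_inf = -0.5, gec50 = 0.24,
                     hill = 1.0)
    ccfg <- sim_config(noise_cv = config$noise_cv,
                       rng_seed = config$seed + 29L)
    cm <- simulate_combo_matrix(ta, tb, interaction = "synergy", factor = 10,
                                cfg = ccfg)
    cr <- combination_result(cm)
    res$combination <- cr
    jwrite(list(drug_a = cr$drug_a, drug_b = cr$drug_b, ratio_R = cr$ratio_R,
                ci50 = cr$ci50, ci_at = as.list(cr$ci_at),
                m_a = cr$fit_a$m, dm_a = cr$fit_a$dm,
                m_b = cr$fit_b$m, dm_b = cr$fit_b$dm,
                m_mix = cr$fit_mix$m, dm_mix = cr$fit_mix$dm),
           "combination.json")
    log_line("combination: cells=", nrow(cm$cells),
             sprintf(" ci50=%.4f", cr$ci50))
  })

  log_line("pipeline: OK")
  invisible(res)
}
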