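# Percent-viability dose-response: four-parameter logistic fits and
# absolute IC50 extraction.
#
#   y(c) = bottom + (top - bottom) / (1 + (c / ec50_rel)^hill_dr)
#
# ec50_rel is the inflection dose (relative EC50); the headline IC50 is the
# absolute one, the dose where the fitted curve crosses 50% normalized
# viability. Both are reported because they differ whenever the curve's
# midpoint is not at 50%.

#' Fit a four-parameter logistic viability curve
#'
#' Bounded least squares (top in [50, 150], bottom in [-10, 60], hill in
#' [0.1, 5], ec50 within [min_dose/100, max_dose*100] on a log10 scale) with
#' three log-spaced ec50 starts. Dose-0 points are excluded. A fit that does
#' not converge, or does not beat the flat mean, yields a censored curve.
#'
#' @param doses dose vector (uM); >= 4 points preferred, >= 3 accepted
#' @param percents percent-viability values (unclipped)
#' @return list of class \code{viability_fit}: top, bottom, hill_dr,
#'   ec50_rel, converged, flat_fallback, rss, rss_flat, dose_range
#' @export
fit_4pl <- function(doses, percents) {
  keep <- doses > 0
  doses <- doses[keep]; percents <- percents[keep]
  stopifnot(length(doses) == length(percents), length(doses) >= 3)
  n <- length(percents)
  ybar <- mean(percents)
  rss_flat <- sum((percents - ybar)^2)
  dose_range <- range(doses)
  flat_out <- function(converged) {
    structure(list(top = ybar, bottom = ybar, hill_dr = NA_real_,
                   ec50_rel = NA_real_, converged = converged,
                   flat_fallback = TRUE, rss = rss_flat, rss_flat = rss_flat,
                   dose_range = dose_range),
              class = "viability_fit")
  }
  if (rss_flat < 1e-16) return(flat_out(TRUE))

  # with only 3 points the hill slope is not identifiable: fix it at 1
  fix_hill <- n < 4
  if (fix_hill) {
    lower <- c(50, -10, log10(dose_range[1] / 100))
    upper <- c(150, 60, log10(dose_range[2] * 100))
    model3 <- function(p, c) p[2] + (p[1] - p[2]) / (1 + c / 10^p[3])
  }
  lower4 <- c(50, -10, 0.1, log10(dose_range[1] / 100))
  upper4 <- c(150, 60, 5, log10(dose_range[2] * 100))
  model <- function(p, c) p[2] + (p[1] - p[2]) / (1 + (c / 10^p[4])^p[3])
  best <- NULL
  for (s in seq(log10(dose_range[1]), log10(dose_range[2]), length.out = 3)) {
    p0 <- c(min(max(max(percents), 50), 150),
            min(max(min(percents), -10), 60), 1, s)
    if (fix_hill) p0 <- p0[-3]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         lower = if (fix_hill) lower else lower4,
                         upper = if (fix_hill) upper else upper4,
                         fn = if (fix_hill)
                           function(p) percents - model3(p, doses)
                         else function(p) percents - model(p, doses),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$par))) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) return(flat_out(FALSE))
  if (best$rss >= rss_flat) return(flat_out(TRUE))  # flat mean is the best model
  p <- best$par
  if (fix_hill) p <- c(p[1], p[2], 1, p[3])
  if (p[2] > p[1]) { tmp <- p[1]; p[1] <- p[2]; p[2] <- tmp; p[3] <- -p[3] }
  structure(list(top = p[1], bottom = p[2], hill_dr = p[3],
                 ec50_rel = 10^p[4], converged = TRUE, flat_fallback = FALSE,
                 rss = best$rss, rss_flat = rss_flat,
                 dose_range = dose_range),
            class = "viability_fit")
}

#' Absolute IC50 from a fitted viability curve
#'
#' Solves \code{y(c) = 50} analytically:
#' \code{c = ec50_rel * ((top - 50) / (50 - bottom))^(1 / hill_dr)}.
#' Censored to \code{">max_dose"} / \code{"<min_dose"} when the curve never
#' crosses 50 within [min_dose/100, max_dose*100], reported against the
#' fitted dose range. Invariant to the ordering of the input doses.
#'
#' @param curve a \code{viability_fit}
#' @return list: ic50 (uM or NA), censored ("none", ">max_dose", "<min_dose",
#'   "no_fit")
#' @export
ic50_absolute <- function(curve) {
  stopifnot(inherits(curve, "viability_fit"))
  lo <- curve$dose_range[1] / 100; hi <- curve$dose_range[2] * 100
  if (curve$flat_fallback || !curve$converged) {
    cens <- if (isTRUE(curve$top <= 50)) "<min_dose" else ">max_dose"
    if (!curve$converged) cens <- "no_fit"
    return(list(ic50 = NA_real_, censored = cens))
  }
  num <- curve$top - 50; den <- 50 - curve$bottom
  if (num <= 0) return(list(ic50 = NA_real_, censored = "<min_dose"))
  if (den <= 0) return(list(ic50 = NA_real_, censored = ">max_dose"))
  ic50 <- curve$ec50_rel * (num / den)^(1 / curve$hill_dr)
  if (ic50 > hi) return(list(ic50 = NA_real_, censored = ">max_dose"))
  if (ic50 < lo) return(list(ic50 = NA_real_, censored = "<min_dose"))
  list(ic50 = ic50, censored = "none")
}

#' Percent-viability curves and IC50s for every compound in a run
#'
#' Normalizes treated wells to their plate's DMSO / staurosporine medians,
#' averages replicates per dose, fits the 4PL and extracts both the relative
#' EC50 and the absolute IC50 with censoring status.
#'
#' @param run an \code{\link{assay_run}}
#' @return data.frame, one row per compound: compound_id, technique, top,
#'   bottom, hill_dr, ec50_rel, ic50_abs, censored, converged, flat_fallback
#' @export
viability_curves <- function(run) {
  stopifnot(inherits(run, "assay_run"))
  tab <- run$table; pc <- run$plate_controls
  idx <- match(paste(tab$plate_id, tab$channel),
               paste(pc$plate_id, pc$channel))
  tr <- tab$role == "treated"
  pv <- percent_viability_by_plate(tab$signal[tr], pc$neg_median[idx[tr]],
                                   pc$pos_median[idx[tr]])
  d <- data.frame(compound_id = tab$compound_id[tr],
                  dose_uM = tab$dose_uM[tr], pv = pv,
                  stringsAsFactors = FALSE)
  rows <- lapply(split(d, d$compound_id), function(a) {
    fit <- fit_4pl(a$dose_uM, a$pv)   # all replicate wells enter the fit
    ic <- ic50_absolute(fit)
    data.frame(compound_id = a$compound_id[1], technique = run$technique,
               top = fit$top, bottom = fit$bottom, hill_dr = fit$hill_dr,
               ec50_rel = fit$ec50_rel, ic50_abs = ic$ic50,
               censored = ic$censored, converged = fit$converged,
               flat_fallback = fit$flat_fallback, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

percent_viability_by_plate <- function(x, neg_median, pos_median) {
  if (any(neg_median <= pos_median))
    stop("a plate has neg_median <= pos_median", call. = FALSE)
  100 * (x - pos_median) / (neg_median - pos_median)
}
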