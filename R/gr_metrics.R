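# Normalized growth-rate inhibition (GR) metrics.
#
# No time-zero read exists in an endpoint screen; the hydroxyurea-stalled
# wells serve as the stall reference x0, so GR < 0 literally means "more
# inhibitory than the hydroxyurea proliferation stall". This is the
# load-bearing convention of the module:
#   GR(x) = 2^( log2(x / x0) / log2(x_ctrl / x0) ) - 1
# with x0 = per-plate hydroxyurea median and x_ctrl = per-plate DMSO median.

#' Estimate the culture's division rate from plate controls
#'
#' Doublings per assay window: \code{log2(neg_median / hu_median)} per plate,
#' with the pooled estimate the mean across plates. Doubling time is
#' \code{T / doublings} hours, flagged non-finite for a stalled culture.
#'
#' @param run an \code{\link{assay_run}} with control summaries
#' @return a \code{growth_estimate}: list with \code{$per_plate} (data.frame:
#'   plate_id, doublings_per_window, doubling_time), \code{$doublings_per_window},
#'   \code{$doubling_time}, \code{$window_T}, \code{$no_growth} flag
#' @examples
#' # neg = 2000, hu = 1000 over 72 h -> 1 doubling, doubling time 72 h
#' @export
estimate_growth <- function(run) {
  stopifnot(inherits(run, "assay_run"))
  pc <- run$plate_controls
  if (is.null(pc)) stop("control summaries missing", call. = FALSE)
  if (any(pc$neg_median <= 0 | pc$hu_median <= 0))
    stop("control medians must be positive", call. = FALSE)
  d <- log2(pc$neg_median / pc$hu_median)
  per_plate <- data.frame(plate_id = pc$plate_id, channel = pc$channel,
                          doublings_per_window = d,
                          doubling_time = ifelse(d > 0, run$assay_window_T / d,
                                                 Inf),
                          stringsAsFactors = FALSE)
  pooled <- mean(d)
  structure(list(per_plate = per_plate,
                 doublings_per_window = pooled,
                 doubling_time = if (pooled > 0) run$assay_window_T / pooled
                                 else Inf,
                 window_T = run$assay_window_T,
                 no_growth = pooled <= 0),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("<growth_estimate> %.3f doublings / %g h (doubling time %s h)%s\n",
              x$doublings_per_window, x$window_T,
              if (is.finite(x$doubling_time)) sprintf("%.1f", x$doubling_time)
              else "Inf",
              if (x$no_growth) " [NO GROWTH]" else ""))
  invisible(x)
}

#' Per-well normalized growth-rate inhibition
#'
#' \code{GR = 2^(log2(x/x0) / log2(x_ctrl/x0)) - 1}: 1 for uninhibited
#' growth, 0 at the stall reference, negative for net cell loss, -1 for a
#' complete kill. Signals are floored at a positivity epsilon before logs and
#' the result is clipped just above -1.
#'
#' @param x treated signal(s)
#' @param x0 stall-reference signal (hydroxyurea median)
#' @param x_ctrl negative-control signal (DMSO median); must exceed x0
#' @param eps positivity floor applied to x (per-well pipelines use
#'   \code{max(1e-6, 1e-4 * pos_median)})
#' @param floor_gr lower clip: GR is never reported below \code{-1 + floor_gr}
#' @return GR value(s) in (-1, Inf), strictly increasing in x
#' @export
compute_gr <- function(x, x0, x_ctrl, eps = 1e-6, floor_gr = 1e-12) {
  if (!(x0 > 0) || !(x_ctrl > 0))
    stop("x0 and x_ctrl must be positive", call. = FALSE)
  if (x_ctrl <= x0)
    stop("x_ctrl <= x0: no measurable growth, GR undefined", call. = FALSE)
  x <- pmax(x, eps)
  if (any(x <= 0)) stop("non-positive signal after flooring", call. = FALSE)
  gr <- 2^(log2(x / x0) / log2(x_ctrl / x0)) - 1
  pmax(gr, -1 + floor_gr)
}

signal_epsilon <- function(pos_median) max(1e-6, 1e-4 * pos_median)

#' Per-dose GR table for a run
#'
#' Computes GR for every treated well against its own plate's control
#' medians, then averages replicate wells per compound x dose.
#'
#' @param run an \code{\link{assay_run}}
#' @return data.frame: compound_id, technique, dose_uM, gr, n_wells
#' @export
gr_table <- function(run) {
  d <- gr_wells(run)
  agg <- stats::aggregate(gr ~ compound_id + dose_uM, data = d, FUN = mean)
  n <- stats::aggregate(gr ~ compound_id + dose_uM, data = d, FUN = length)
  agg$n_wells <- n$gr
  agg$technique <- d$technique[1]
  agg <- agg[order(agg$compound_id, -agg$dose_uM),
             c("compound_id", "technique", "dose_uM", "gr", "n_wells")]
  rownames(agg) <- NULL
  agg
}

#' Per-well GR values for the treated wells of a run
#'
#' Each well is normalized against its own plate's hydroxyurea and DMSO
#' medians (drift isolation).
#'
#' @param run an \code{\link{assay_run}}
#' @return data.frame: compound_id, technique, dose_uM, gr (one row per well)
#' @export
gr_wells <- function(run) {
  stopifnot(inherits(run, "assay_run"))
  growth <- estimate_growth(run)
  if (growth$no_growth)
    stop("culture shows no growth (neg <= hu); GR computation refused",
         call. = FALSE)
  tab <- run$table
  pc <- run$plate_controls
  idx <- match(paste(tab$plate_id, tab$channel),
               paste(pc$plate_id, pc$channel))
  tr <- tab$role == "treated"
  gr <- compute_gr_by_plate(tab$signal[tr], pc$hu_median[idx[tr]],
                            pc$neg_median[idx[tr]],
                            pc$pos_median[idx[tr]])
  data.frame(compound_id = tab$compound_id[tr], technique = run$technique,
             dose_uM = tab$dose_uM[tr], gr = gr, stringsAsFactors = FALSE)
}

# vectorized over wells with per-plate references
compute_gr_by_plate <- function(x, x0, x_ctrl, pos_median) {
  if (any(x_ctrl <= x0))
    stop("a plate has x_ctrl <= x0: no measurable growth", call. = FALSE)
  eps <- pmax(1e-6, 1e-4 * pos_median)
  x <- pmax(x, eps)
  pmax(2^(log2(x / x0) / log2(x_ctrl / x0)) - 1, -1 + 1e-12)
}

#' Fit the sigmoid GR dose-response curve
#'
#' \code{GR(c) = gr_inf + (1 - gr_inf) / (1 + (c / gec50)^h_gr)}, fitted by
#' bounded least squares (gr_inf in [-1, 1], h in [0.1, 5], gec50 within
#' [min_dose/100, max_dose*100], log10 internally) with three log-spaced
#' gec50 starts. An F-test against the flat-line mean at alpha = 0.05 decides
#' whether the sigmoid is warranted; otherwise the fit falls back to the
#' constant mean (flat_fallback), as does a fit that fails to converge.
#'
#' @param doses dose vector (uM), >= 3 points
#' @param gr_values GR values at those doses
#' @return list: gr_inf, gec50, h_gr, converged, flat_fallback, rss, rss_flat
#' @export
fit_gr_curve <- function(doses, gr_values) {
  stopifnot(length(doses) == length(gr_values), length(doses) >= 3,
            all(doses > 0))
  fit_sigmoid(doses, gr_values,
              model = function(p, c) p[1] + (1 - p[1]) / (1 + (c / 10^p[2])^p[3]),
              lower = c(-1, log10(min(doses) / 100), 0.1),
              upper = c(1, log10(max(doses) * 100), 5),
              start_shape = function(y) c(max(min(y), -1), NA, 1),
              n_par = 3,
              out_names = c("gr_inf", "gec50", "h_gr"))
}

# shared bounded multi-start least squares with flat-line F-test fallback.
# p[2] is always log10(ec50-like); start_shape supplies the non-dose starts.
fit_sigmoid <- function(doses, y, model, lower, upper, start_shape, n_par,
                        out_names) {
  n <- length(y)
  ybar <- mean(y)
  rss_flat <- sum((y - ybar)^2)
  flat_result <- function(converged) {
    out <- stats::setNames(as.list(c(ybar, NA, NA)), out_names)
    c(out, list(converged = converged, flat_fallback = TRUE,
                rss = rss_flat, rss_flat = rss_flat))
  }
  if (rss_flat < 1e-20) return(flat_result(TRUE))

  starts_g <- seq(log10(min(doses)), log10(max(doses)), length.out = 3)
  best <- NULL
  for (s in starts_g) {
    p0 <- start_shape(y); p0[2] <- s
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = function(p) y - model(p, doses),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$par))) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) return(flat_result(FALSE))
  if (best$rss >= rss_flat) return(flat_result(TRUE))

  # F-test: does the sigmoid beat the flat mean?
  df2 <- n - n_par
  flat <- if (df2 <= 0) {
    best$rss >= rss_flat - 1e-20   # saturated fit: only reject flat if it improves
  } else {
    f <- ((rss_flat - best$rss) / (n_par - 1)) / (best$rss / df2)
    if (best$rss < 1e-20) FALSE
    else stats::pf(f, n_par - 1, df2, lower.tail = FALSE) >= 0.05
  }
  if (flat) return(flat_result(TRUE))
  out <- stats::setNames(as.list(c(best$par[1], 10^best$par[2], best$par[3])),
                         out_names)
  c(out, list(converged = TRUE, flat_fallback = FALSE,
              rss = best$rss, rss_flat = rss_flat))
}

#' Dose where the fitted GR curve crosses 0.5
#'
#' @param fit a \code{\link{fit_gr_curve}} result
#' @return dose (uM), or NA (censored) when the curve never crosses 0.5
#' @export
gr50_from_fit <- function(fit) {
  if (fit$flat_fallback || !fit$converged) return(NA_real_)
  if (fit$gr_inf >= 0.5) return(NA_real_)
  fit$gec50 * (0.5 / (0.5 - fit$gr_inf))^(1 / fit$h_gr)
}

#' Area over the GR curve
#'
#' Trapezoidal integral of (1 - GR) over log2(dose), normalized by the
#' log2 dose range so values are comparable across dose designs; 0 for an
#' uninhibited drug, up to ~2 for a complete kill. Ranking diagnostic only.
#'
#' @param doses dose vector (uM)
#' @param gr_values GR values
#' @return scalar GR-AOC
#' @export
gr_aoc <- function(doses, gr_values) {
  o <- order(doses)
  lx <- log2(doses[o]); y <- 1 - gr_values[o]
  if (length(lx) < 2) return(mean(y))
  sum(diff(lx) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
    (max(lx) - min(lx))
}

#' Per-compound GR profiles for a run
#'
#' Per-dose GR (replicates averaged), mean GR across the dilution series,
#' and optionally the sigmoid fit with derived GR50 and GR-AOC. The curve is
#' fitted on the individual well-level GR values (all replicates enter the
#' least squares), while summaries and hit-calling use the per-dose means.
#'
#' @param run an \code{\link{assay_run}}
#' @param fit fit the GR curve per compound (skip for plain hit-calling on
#'   large libraries)
#' @return data.frame, one row per compound: compound_id, technique, mean_gr,
#'   gr_aoc, and when fitted: gr_inf, gec50, h_gr, converged, flat_fallback,
#'   gr50 (NA = censored). The per-dose table is attached as
#'   \code{attr(, "gr_long")}.
#' @export
gr_profiles <- function(run, fit = TRUE) {
  wells <- gr_wells(run)
  long <- gr_table(run)
  by_dose <- split(long, long$compound_id)
  by_well <- split(wells, wells$compound_id)
  profs <- lapply(names(by_dose), function(id) {
    d <- by_dose[[id]]; d <- d[order(-d$dose_uM), ]
    w <- by_well[[id]]
    row <- data.frame(compound_id = id,
                      technique = d$technique[1],
                      mean_gr = mean(d$gr),
                      gr_aoc = gr_aoc(d$dose_uM, d$gr),
                      stringsAsFactors = FALSE)
    if (fit && nrow(d) >= 3) {
      f <- fit_gr_curve(w$dose_uM, w$gr)
      row$gr_inf <- f$gr_inf; row$gec50 <- f$gec50; row$h_gr <- f$h_gr
      row$converged <- f$converged; row$flat_fallback <- f$flat_fallback
      row$gr50 <- gr50_from_fit(f)
    }
    row
  })
  out <- do.call(rbind, profs)
  rownames(out) <- NULL
  attr(out, "gr_long") <- long
  out
}

#' Percent viability against negative and positive controls
#'
#' \code{100 * (x - pos_median) / (neg_median - pos_median)}: 100 at the
#' DMSO median, 0 at the staurosporine median; unclipped (values above 100
#' occur for wells outgrowing the negative control).
#'
#' @param x signal(s)
#' @param neg_median DMSO control median
#' @param pos_median staurosporine control median; must be below neg_median
#' @return percent viability
#' @export
percent_viability <- function(x, neg_median, pos_median) {
  if (neg_median <= pos_median)
    stop("neg_median must exceed pos_median", call. = FALSE)
  100 * (x - pos_median) / (neg_median - pos_median)
}
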