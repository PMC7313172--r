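# Chou-Talalay median-effect modelling and combination indices for
# fixed-ratio dose designs.
#
# Median-effect relation: fa/fu = (D/Dm)^m, linearized as
#   log10(fa/fu) = m*log10(D) - m*log10(Dm).
# For two agents mixed at constant molar ratio R = d_b/d_a, the combination
# index at effect level fa_x is the mutually-exclusive (classic) form
#   CI = d1/Dx_A + d2/Dx_B,
# with d1, d2 the doses of each agent inside the mixture achieving fa_x and
# Dx each agent's single-agent dose for the same effect. CI < 1 synergy,
# CI = 1 additivity, CI > 1 antagonism.

FA_CLIP <- c(0.005, 0.995)

#' Fit the median-effect line
#'
#' Ordinary least squares on the linearized points. Only effect levels
#' strictly inside the clipping band [0.005, 0.995] are used; near-degenerate
#' wells outside it (including fa of exactly 0 or 1) are discarded so the
#' logit stays finite and undistorted.
#'
#' @param doses dose vector (uM; total dose for a mixture)
#' @param fa_values fraction-affected values (1 - viability fraction)
#' @return list of class \code{median_effect_fit}: m (slope), dm (uM),
#'   r2, n_points_used, valid (FALSE when fewer than 2 usable points or
#'   m <= 0, i.e. non-inhibitory)
#' @export
median_effect_fit <- function(doses, fa_values) {
  stopifnot(length(doses) == length(fa_values))
  keep <- doses > 0 & fa_values >= FA_CLIP[1] & fa_values <= FA_CLIP[2]
  doses <- doses[keep]
  fa <- fa_values[keep]
  out <- structure(list(m = NA_real_, dm = NA_real_, r2 = NA_real_,
                        n_points_used = length(fa), valid = FALSE),
                   class = "median_effect_fit")
  if (length(fa) < 2) return(out)
  y <- log10(fa / (1 - fa)); x <- log10(doses)
  if (stats::sd(x) == 0) return(out)
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m <= 0) {
    out$m <- m
    return(out)
  }
  out$m <- m
  out$dm <- 10^(-b / m)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  out$r2 <- if (tss == 0) 1 else 1 - rss / tss
  out$valid <- TRUE
  out
}

#' Dose achieving a given effect level on a median-effect curve
#'
#' \code{Dx = Dm * (fa / (1 - fa))^(1/m)}.
#'
#' @param fit a \code{median_effect_fit}
#' @param fa effect level in (0, 1)
#' @return dose (uM)
#' @export
median_effect_dose <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"), fa > 0, fa < 1)
  if (!fit$valid) stop("invalid median-effect fit", call. = FALSE)
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index at chosen effect levels
#'
#' @param fit_a,fit_b single-agent median-effect fits
#' @param fit_mix mixture fit on total dose at fixed molar ratio
#' @param ratio_R molar ratio d_b/d_a, constant across dilution steps
#' @param fa_x effect level(s) in (0, 1); 0.5 gives the CI50
#' @return named numeric vector of CI values, one per effect level
#' @export
compute_ci <- function(fit_a, fit_b, fit_mix, ratio_R, fa_x = 0.5) {
  stopifnot(ratio_R > 0, all(fa_x > 0 & fa_x < 1))
  if (!fit_a$valid || !fit_b$valid || !fit_mix$valid)
    stop("invalid median-effect fit", call. = FALSE)
  ci <- vapply(fa_x, function(f) {
    d_mix <- median_effect_dose(fit_mix, f)
    d1 <- d_mix / (1 + ratio_R)
    d2 <- d_mix * ratio_R / (1 + ratio_R)
    d1 / median_effect_dose(fit_a, f) + d2 / median_effect_dose(fit_b, f)
  }, numeric(1))
  stats::setNames(ci, paste0("fa", fa_x))
}

#' Extract fixed-ratio and single-agent series from a combination matrix
#'
#' The matrix diagonal - both drugs diluting in matched steps - forms the
#' fixed-ratio mixture series (ratio checked constant to 1e-6 relative);
#' the partner-dose-0 row and column give the single-agent series. Percent
#' viability is computed against the matrix plate's controls, fa = 1 -
#' viability/100 (clipped to [0, 1]), and replicate wells are averaged
#' before any fitting.
#'
#' @param cm a \code{combo_matrix} from \code{\link{simulate_combo_matrix}}
#'   or \code{\link{read_combo_matrix}}
#' @return list: \code{a}, \code{b} (data.frames dose_uM, fa),
#'   \code{mix} (dose_total_uM, fa), \code{ratio_R}
#' @export
extract_fixed_ratio <- function(cm) {
  stopifnot(inherits(cm, "combo_matrix"))
  neg <- cm$controls[["neg_median"]]; pos <- cm$controls[["pos_median"]]
  cells <- cm$cells
  pv <- percent_viability(cells$signal, neg, pos)
  cells$fa <- pmin(pmax(1 - pv / 100, 0), 1)
  avg <- stats::aggregate(fa ~ dose_a_uM + dose_b_uM, data = cells, FUN = mean)

  single <- function(dcol, ocol) {
    s <- avg[avg[[ocol]] == 0 & avg[[dcol]] > 0, c(dcol, "fa")]
    names(s)[1] <- "dose_uM"
    s[order(-s$dose_uM), ]
  }
  a <- single("dose_a_uM", "dose_b_uM")
  b <- single("dose_b_uM", "dose_a_uM")

  da <- sort(unique(avg$dose_a_uM[avg$dose_a_uM > 0]), decreasing = TRUE)
  db <- sort(unique(avg$dose_b_uM[avg$dose_b_uM > 0]), decreasing = TRUE)
  k <- min(length(da), length(db))
  da <- da[seq_len(k)]; db <- db[seq_len(k)]
  ratios <- db / da
  if (max(abs(ratios / ratios[1] - 1)) > 1e-6)
    stop("diagonal molar ratio not constant across dilution steps",
         call. = FALSE)
  diag_idx <- match(paste(da, db), paste(avg$dose_a_uM, avg$dose_b_uM))
  if (anyNA(diag_idx))
    stop("missing diagonal cells in combination matrix", call. = FALSE)
  mix <- data.frame(dose_total_uM = da + db, fa = avg$fa[diag_idx])
  list(a = a, b = b, mix = mix, ratio_R = ratios[1])
}

#' Full combination analysis of a dose matrix
#'
#' Fixed-ratio extraction, three median-effect fits (two single agents and
#' the mixture on total dose) and CI at the requested effect levels.
#'
#' @param cm a \code{combo_matrix}
#' @param fa_levels effect levels for CI reporting (0.5 first: the CI50)
#' @return list of class \code{combination_result}: drug_a, drug_b, ratio_R,
#'   fit_a, fit_b, fit_mix, ci_at (named vector), ci50
#' @export
combination_result <- function(cm, fa_levels = c(0.5, 0.75, 0.9)) {
  ser <- extract_fixed_ratio(cm)
  fit_a <- median_effect_fit(ser$a$dose_uM, ser$a$fa)
  fit_b <- median_effect_fit(ser$b$dose_uM, ser$b$fa)
  fit_mix <- median_effect_fit(ser$mix$dose_total_uM, ser$mix$fa)
  ci <- compute_ci(fit_a, fit_b, fit_mix, ser$ratio_R, fa_levels)
  structure(list(drug_a = cm$drug_a, drug_b = cm$drug_b,
                 ratio_R = ser$ratio_R, fit_a = fit_a, fit_b = fit_b,
                 fit_mix = fit_mix, ci_at = ci, ci50 = unname(ci[1]),
                 series = ser),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("<combination_result> %s + %s at ratio 1:%.3g | CI50 = %.3f\n",
              x$drug_a, x$drug_b, x$ratio_R, x$ci50))
  invisible(x)
}

#' Read a combination matrix from a percent-viability CSV
#'
#' Long format: columns \code{dose_a_uM, dose_b_uM, replicate,
#' percent_viability} (including the single-agent row/column at partner
#' dose 0). Signals are reconstructed on a unit control scale so the same
#' extraction path applies.
#'
#' @param path CSV path
#' @param drug_a,drug_b compound ids for labelling
#' @return a \code{combo_matrix}
#' @export
read_combo_matrix <- function(path, drug_a = "drug_a", drug_b = "drug_b") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("dose_a_uM", "dose_b_uM", "replicate", "percent_viability")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("combo matrix CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cells <- data.frame(dose_a_uM = df$dose_a_uM, dose_b_uM = df$dose_b_uM,
                      replicate = df$replicate,
                      signal = df$percent_viability / 100)
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 design_a = NULL, design_b = NULL, cells = cells,
                 controls = c(neg_median = 1, hu_median = NA, pos_median = 0),
                 technique = "enzymatic_2d"),
            class = "combo_matrix")
}
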