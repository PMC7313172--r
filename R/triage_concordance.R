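# Screen-level statistics: hit nomination, ranking, cross-assay
# concordance, dose-response clustering, and the dilution-series Welch
# comparison.

#' Nominate hits and rank the library
#'
#' The stringent ranking criterion: a compound is a hit when its GR value is
#' below 0 at every tested dose - i.e. more growth-inhibitory than the
#' hydroxyurea stall across the full dose range. The whole library is ranked
#' by mean GR across the dilution series, ascending (most cytotoxic first).
#' Compounds missing a GR value at any dose of the common design are
#' excluded with a warning.
#'
#' @param gr_long per-dose GR table (\code{\link{gr_table}} /
#'   \code{attr(gr_profiles(run), "gr_long")}): compound_id, dose_uM, gr
#' @return data.frame: compound_id, mean_gr, is_hit, rank (1 = most
#'   cytotoxic), n_doses; excluded compounds in \code{attr(, "excluded")}
#' @export
call_hits <- function(gr_long) {
  stopifnot(all(c("compound_id", "dose_uM", "gr") %in% names(gr_long)))
  full_design <- sort(unique(gr_long$dose_uM))
  by_comp <- split(gr_long, gr_long$compound_id)
  ok <- vapply(by_comp, function(d) {
    setequal(d$dose_uM, full_design) && !anyNA(d$gr) &&
      length(d$dose_uM) == length(full_design)
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " compound(s) excluded: missing GR at >=1 dose",
            call. = FALSE)
  rows <- lapply(by_comp[ok], function(d) {
    data.frame(compound_id = d$compound_id[1], mean_gr = mean(d$gr),
               is_hit = all(d$gr < 0), n_doses = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_gr, out$compound_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- names(by_comp)[!ok]
  out
}

#' Top-n most cytotoxic compounds of a ranking
#' @param hits a \code{\link{call_hits}} result
#' @param n set size (30 by default)
#' @return character vector of compound ids
#' @export
top_cytotoxic <- function(hits, n = 30) {
  utils::head(hits$compound_id, n)   # already ranked by mean GR, ties by id
}

#' Cross-assay concordance of GR dose responses
#'
#' For every technique pair sharing the dose design: Pearson correlation of
#' GR values across compounds at each dose, averaged over doses (doses with
#' zero variance in either vector are excluded from the mean and flagged),
#' plus the overlap of the top-n most cytotoxic sets (pairwise and, with
#' three techniques, the three-way intersection).
#'
#' @param gr_long_list named list (by technique) of per-dose GR tables
#' @param n_top top-set size (default 30)
#' @return list: \code{pairs} (data.frame: tech_a, tech_b, mean_r, n_doses_used,
#'   overlap_top_n), \code{per_dose_r} (data.frame: tech_a, tech_b, dose_uM, r),
#'   \code{top_sets}, \code{triple_overlap} (NA unless >= 3 techniques)
#' @export
concordance <- function(gr_long_list, n_top = 30) {
  stopifnot(length(gr_long_list) >= 2)
  techs <- names(gr_long_list)
  wide <- lapply(gr_long_list, function(d)
    stats::reshape(d[c("compound_id", "dose_uM", "gr")],
                   idvar = "compound_id", timevar = "dose_uM",
                   direction = "wide"))
  shared <- Reduce(intersect, lapply(wide, `[[`, "compound_id"))
  if (length(shared) < 3)
    stop("fewer than 3 shared compounds across techniques", call. = FALSE)
  doses <- sort(unique(gr_long_list[[1]]$dose_uM), decreasing = TRUE)

  gr_mat <- function(tech) {
    w <- wide[[tech]]
    w <- w[match(shared, w$compound_id), ]
    m <- as.matrix(w[paste0("gr.", doses)])
    rownames(m) <- shared
    m
  }
  mats <- lapply(stats::setNames(techs, techs), gr_mat)

  top_sets <- lapply(stats::setNames(techs, techs), function(t) {
    sub <- gr_long_list[[t]]
    top_cytotoxic(call_hits(sub[sub$compound_id %in% shared, ]), n_top)
  })

  prs <- utils::combn(techs, 2, simplify = FALSE)
  per_dose <- list(); pair_rows <- list()
  for (p in prs) {
    r <- vapply(seq_along(doses), function(i) {
      a <- mats[[p[1]]][, i]; b <- mats[[p[2]]][, i]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
    if (anyNA(r))
      warning("zero-variance dose excluded from mean r for pair ",
              paste(p, collapse = " vs "), call. = FALSE)
    per_dose[[length(per_dose) + 1L]] <-
      data.frame(tech_a = p[1], tech_b = p[2], dose_uM = doses, r = r,
                 stringsAsFactors = FALSE)
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(tech_a = p[1], tech_b = p[2],
                 mean_r = mean(r, na.rm = TRUE), n_doses_used = sum(!is.na(r)),
                 overlap_top_n = length(intersect(top_sets[[p[1]]],
                                                  top_sets[[p[2]]])),
                 stringsAsFactors = FALSE)
  }
  triple <- if (length(techs) >= 3)
    length(Reduce(intersect, top_sets[1:3])) else NA_integer_
  list(pairs = do.call(rbind, pair_rows),
       per_dose_r = do.call(rbind, per_dose),
       top_sets = top_sets, triple_overlap = triple, n_top = n_top)
}

#' Hierarchical clustering of the drug x (technique.dose) GR matrix
#'
#' Agglomerative clustering with distance 1 - Pearson correlation between
#' drug rows and average linkage. Missing cells are imputed by the row mean
#' (flagged). Rows are pre-sorted by compound id so ties break
#' deterministically; shuffling row order yields identical merge heights.
#'
#' @param mat numeric matrix, rows = drugs (rownames = compound ids),
#'   columns = technique x dose GR values
#' @return list: \code{hclust} (stats::hclust object), \code{leaf_order}
#'   (compound ids in dendrogram order), \code{heights}, \code{imputed}
#'   (count of imputed cells)
#' @export
cluster_dose_matrix <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (nrow(mat) < 3) stop("need >= 3 rows to cluster", call. = FALSE)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  n_imp <- sum(is.na(mat))
  if (n_imp > 0) {
    warning(n_imp, " missing cell(s) imputed by row mean", call. = FALSE)
    for (i in seq_len(nrow(mat))) {
      na <- is.na(mat[i, ])
      if (any(na)) mat[i, na] <- mean(mat[i, !na])
    }
  }
  cm <- suppressWarnings(stats::cor(t(mat)))
  cm[!is.finite(cm)] <- 0        # zero-variance rows: treated as uncorrelated
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, leaf_order = hc$labels[hc$order], heights = hc$height,
       imputed = n_imp)
}

#' Welch's t-test across a dilution series
#'
#' Treats the doses of two dilution series as biological replicates and
#' compares the GR (or viability) vectors with Welch's unequal-variance
#' t-test (Welch-Satterthwaite degrees of freedom, two-sided p). Degenerate
#' inputs: both vectors constant with equal means gives t = 0, p = 1; both
#' constant with unequal means is flagged degenerate (p undefined).
#'
#' @param gr_a,gr_b numeric vectors, length >= 2
#' @return list: t, df, p, degenerate flag
#' @export
welch_dose_series <- function(gr_a, gr_b) {
  stopifnot(length(gr_a) >= 2, length(gr_b) >= 2)
  va <- stats::var(gr_a); vb <- stats::var(gr_b)
  if (va == 0 && vb == 0) {
    if (mean(gr_a) == mean(gr_b))
      return(list(t = 0, df = length(gr_a) + length(gr_b) - 2, p = 1,
                  degenerate = FALSE))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(gr_a, gr_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
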