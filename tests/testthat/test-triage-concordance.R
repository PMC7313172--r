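gr_long_df <- function(ids, doses, gr_fun) {
  g <- expand.grid(compound_id = ids, dose_uM = doses,
                   stringsAsFactors = FALSE)
  g$gr <- gr_fun(g$compound_id, g$dose_uM)
  g$technique <- "imaging_2d"
  g
}

test_that("the hit rule requires GR below zero at every dose", {
  doses <- c(5, 2.5, 1.25)
  grs <- list(hit = c(-0.1, -0.2, -0.05),
              miss = c(-0.9, 0.1, -0.5),
              inert = c(1, 1, 1))
  long <- do.call(rbind, lapply(names(grs), function(id) {
    data.frame(compound_id = id, dose_uM = doses, gr = grs[[id]])
  }))
  h <- call_hits(long)
  expect_true(h$is_hit[h$compound_id == "hit"])
  expect_false(h$is_hit[h$compound_id == "miss"])
  expect_false(h$is_hit[h$compound_id == "inert"])
  # ranking ascends in mean GR; hit set within mean_gr < 0
  expect_equal(h$compound_id[h$rank == 1], "miss")  # mean -0.433 lowest
  expect_true(all(h$mean_gr[h$is_hit] < 0))
})

test_that("hit calling is invariant to dose ordering and monotone rescaling", {
  cfg <- small_cfg(n = 80, hits = 7, noise = 0.05)
  run <- simulate_run(cfg, make_drug_truth(cfg), "imaging_2d")
  long <- gr_table(run)
  h1 <- call_hits(long)
  shuffled <- long[sample(nrow(long)), ]
  h2 <- call_hits(shuffled)
  expect_equal(h1, h2, ignore_attr = TRUE)

  # doubling every raw signal (gain change) leaves GR, hence hits, unchanged
  run2 <- run
  run2$table$signal <- run2$table$signal * 2
  run2 <- summarize_controls(run2)
  h3 <- call_hits(gr_table(run2))
  expect_equal(h1$is_hit, h3$is_hit)
  expect_equal(h1$mean_gr, h3$mean_gr, tolerance = 1e-12)
})

test_that("compounds with incomplete dose coverage are excluded with warning", {
  doses <- c(5, 2.5, 1.25)
  long <- rbind(
    data.frame(compound_id = "ok", dose_uM = doses, gr = c(-0.2, -0.1, 0)),
    data.frame(compound_id = "short", dose_uM = doses[1:2], gr = c(-1, -1)))
  expect_warning(h <- call_hits(long), "excluded")
  expect_equal(h$compound_id, "ok")
  expect_equal(attr(h, "excluded"), "short")
})

test_that("identical and negated GR matrices bound the correlation", {
  doses <- c(5, 2.5, 1.25)
  ids <- sprintf("C%02d", 1:40)
  set.seed(3)
  vals <- matrix(rnorm(120), 40, 3)
  base <- gr_long_df(ids, doses, function(id, d)
    vals[cbind(match(id, ids), match(d, doses))])
  same <- concordance(list(imaging_2d = base, enzymatic_2d = base),
                      n_top = 30)
  expect_equal(same$pairs$mean_r, 1, tolerance = 1e-12)
  expect_equal(same$pairs$overlap_top_n, 30)

  neg <- base; neg$gr <- -neg$gr
  anti <- concordance(list(imaging_2d = base, enzymatic_2d = neg))
  expect_equal(anti$per_dose_r$r, rep(-1, 3), tolerance = 1e-12)
})

test_that("pipeline concordance equals the direct correlation formula", {
  cfg <- small_cfg(n = 200, hits = 15, noise = 0.1,
                   doses = dose_series(5, 2, 5))
  truth <- make_drug_truth(cfg)
  runs <- lapply(c(a = "imaging_2d", b = "enzymatic_2d"),
                 function(t) simulate_run(cfg, truth, t))
  longs <- lapply(runs, gr_table)
  conc <- concordance(list(imaging_2d = longs$a, enzymatic_2d = longs$b))

  # direct formula on the same numbers
  m <- merge(longs$a, longs$b, by = c("compound_id", "dose_uM"))
  direct <- sapply(split(m, m$dose_uM), function(d) {
    n <- nrow(d)
    sxy <- sum(d$gr.x * d$gr.y) - sum(d$gr.x) * sum(d$gr.y) / n
    sxx <- sum(d$gr.x^2) - sum(d$gr.x)^2 / n
    syy <- sum(d$gr.y^2) - sum(d$gr.y)^2 / n
    sxy / sqrt(sxx * syy)
  })
  expect_equal(conc$pairs$mean_r, mean(direct), tolerance = 1e-12)

  # zero-variance dose: r undefined there, excluded from the mean
  flat <- longs$a
  flat$gr[flat$dose_uM == max(flat$dose_uM)] <- -0.5
  suppressWarnings(conc2 <- concordance(list(imaging_2d = flat,
                                             enzymatic_2d = longs$b)))
  expect_equal(conc2$pairs$n_doses_used, 4)
})

test_that("clustering merges identical rows first and is permutation-stable", {
  m <- rbind(C1 = c(1, 0.8, 0.2, -0.4),
             C2 = c(1, 0.8, 0.2, -0.4),
             C3 = c(-1, -0.7, 0.1, 0.6))
  cl <- cluster_dose_matrix(m)
  expect_equal(length(cl$leaf_order), 3)
  expect_equal(min(cl$heights), 0, tolerance = 1e-12)
  first_pair <- sort(cl$hclust$merge[1, ])
  expect_equal(first_pair, c(-2, -1))     # the identical pair merges at 0

  # hand-computed heights for 3 rows: d(1,2) = 0; average linkage joins
  # {1,2} with 3 at mean(1 - cor(1,3), 1 - cor(2,3))
  d13 <- 1 - stats::cor(m[1, ], m[3, ])
  expect_equal(max(cl$heights), d13, tolerance = 1e-12)

  perm <- m[c(3, 1, 2), ]
  cl2 <- cluster_dose_matrix(perm)
  expect_equal(cl2$heights, cl$heights, tolerance = 1e-12)
  expect_equal(cl2$leaf_order, cl$leaf_order)

  expect_error(cluster_dose_matrix(m[1:2, ]), ">= 3 rows")
})

test_that("missing cells are imputed by row mean with a flag", {
  m <- rbind(C1 = c(1, 0.5, NA, -0.5),
             C2 = c(0.9, 0.6, 0.1, -0.4),
             C3 = c(-1, -0.5, 0, 0.5))
  expect_warning(cl <- cluster_dose_matrix(m), "imputed")
  expect_equal(cl$imputed, 1)
  expect_equal(length(cl$leaf_order), 3)
})

test_that("Welch comparison matches hand-evaluated formulas", {
  r <- welch_dose_series(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(r$t, -1, tolerance = 1e-12)
  expect_equal(r$df, 8, tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-1, 8), tolerance = 1e-12)
  expect_equal(r$p, 0.3466, tolerance = 1e-4)

  same <- welch_dose_series(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const_eq <- welch_dose_series(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const_eq$p, 1)
  const_ne <- welch_dose_series(c(2, 2, 2), c(3, 3, 3))
  expect_true(const_ne$degenerate)
})

test_that("Welch t, df, p agree with the Welch-Satterthwaite formulas", {
  set.seed(21)
  for (i in 1:100) {
    a <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    r <- welch_dose_series(a, b)
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
    df_ref <- (va + vb)^2 /
      (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p_ref <- 2 * stats::pt(-abs(t_ref), df_ref)
    expect_equal(r$t, t_ref, tolerance = 1e-10)
    expect_equal(r$df, df_ref, tolerance = 1e-10)
    expect_equal(r$p, p_ref, tolerance = 1e-10)
  }
})

test_that("the null rejection rate of the dose-series Welch test is nominal", {
  rate <- welch_type1_study(n_sims = 2000, n = 5, seed = 3)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
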