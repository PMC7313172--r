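test_that("well coordinates are validated and normalized", {
  expect_equal(validate_wells(c("A1", "p24", "B03")), c("A1", "P24", "B3"))
  expect_error(validate_wells("Q1"), "out-of-range")
  expect_error(validate_wells("A25"), "out-of-range")
  expect_error(validate_wells("11"), "out-of-range")
  expect_length(well_labels_384(), 384)
})

test_that("dose series follow the descending geometric design", {
  ds <- dose_series(5, 2, 3)
  expect_equal(ds$doses, c(5, 2.5, 1.25))
  ds6 <- dose_series(2, 3, 6)
  expect_equal(ds6$doses, 2 / 3^(0:5))
  expect_true(all(diff(ds6$doses) < 0))
  expect_error(dose_series(-1, 2, 3))
  expect_error(dose_series(5, 1, 3))
})

test_that("screen table enforces its invariants", {
  tab <- toy_screen_table()
  expect_s3_class(tab, "screen_table")
  expect_equal(sum(tab$role == "treated"), 9)

  bad <- as.data.frame(tab); bad$signal[1] <- -5
  expect_error(screen_table(bad), "non-negative")
  dup <- rbind(as.data.frame(tab), as.data.frame(tab)[1, ])
  expect_error(screen_table(dup), "duplicate")
  wrongdose <- as.data.frame(tab); wrongdose$dose_uM[1] <- 1
  expect_error(screen_table(wrongdose), "dose 0")
})

test_that("a full 384-well plate with 14/14/8 controls leaves 348 treated wells", {
  cfg <- small_cfg(n = 116, hits = 0)   # 348 treated wells exactly
  run <- simulate_run(cfg, make_drug_truth(cfg), "imaging_2d")
  tab <- run$table
  expect_equal(length(unique(tab$plate_id)), 1)
  expect_equal(nrow(tab), 384)
  expect_equal(sum(tab$role == "treated"), 348)
  expect_equal(sum(tab$role == "negative_dmso"), 14)
  expect_equal(sum(tab$role == "proliferation_hydroxyurea"), 14)
  expect_equal(sum(tab$role == "positive_staurosporine"), 8)
})

test_that("read/write round-trip is lossless, with plate-map role joining", {
  cfg <- small_cfg(n = 20, hits = 2, noise = 0.05)
  run <- simulate_run(cfg, make_drug_truth(cfg), "enzymatic_2d")
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(run$table, f)
  back <- read_screen_table(f)       # role column carried in the CSV
  expect_equal(as.data.frame(back), as.data.frame(run$table),
               tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # split into readout + map and re-join
  map <- as.data.frame(run$table)[c("plate_id", "well", "role",
                                    "compound_id", "dose_uM")]
  fm <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(map, fm, row.names = FALSE)
  readout <- as.data.frame(run$table)[c("plate_id", "well", "compound_id",
                                        "dose_uM", "channel", "signal")]
  fr <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(readout, fr, row.names = FALSE)
  joined <- read_screen_table(fr, fm)
  expect_equal(joined$role, run$table$role)
})

test_that("unmapped wells are treated only with compound and dose", {
  tab <- as.data.frame(toy_screen_table())
  readout <- tab[c("plate_id", "well", "compound_id", "dose_uM",
                   "channel", "signal")]
  map <- tab[tab$role != "treated",
             c("plate_id", "well", "role", "compound_id", "dose_uM")]
  fr <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(readout, fr, row.names = FALSE)
  utils::write.csv(map, fm, row.names = FALSE)
  ok <- read_screen_table(fr, fm)    # treated wells carry compound + dose
  expect_equal(sum(ok$role == "treated"), 9)

  readout$compound_id[which(readout$dose_uM > 0)[1]] <- ""
  utils::write.csv(readout, fr, row.names = FALSE)
  expect_error(read_screen_table(fr, fm), "without compound")
})

test_that("nM doses are converted at the boundary", {
  tab <- as.data.frame(toy_screen_table())
  tab$dose_unit <- ifelse(tab$role == "treated", "nM", "uM")
  tab$dose_uM[tab$role == "treated"] <-
    tab$dose_uM[tab$role == "treated"] * 1000
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- read_screen_table(f)
  expect_equal(sort(unique(back$dose_uM[back$role == "treated"])),
               c(1.25, 2.5, 5))
})

test_that("control summaries are per-plate medians, robust to outliers", {
  tab <- toy_screen_table(neg = 1000, hu = 500, pos = 10)
  run <- assay_run(tab, "enzymatic_2d")
  pc <- run$plate_controls
  expect_equal(pc$neg_median, 1000)
  expect_equal(pc$hu_median, 500)
  expect_equal(pc$pos_median, 10)
  expect_false(pc$growth_flag)

  # single-well outlier leaves the median unchanged (odd effective n)
  tab2 <- as.data.frame(tab)
  i <- which(tab2$role == "negative_dmso")[1]
  tab2$signal[i] <- tab2$signal[i] * 10
  tab2 <- tab2[-which(tab2$role == "negative_dmso")[2], ]  # 13 wells, odd n
  run2 <- suppressWarnings(assay_run(screen_table(tab2), "enzymatic_2d"))
  expect_equal(run2$plate_controls$neg_median, 1000)
})

test_that("degenerate and missing controls are flagged or rejected", {
  flat <- toy_screen_table(neg = 800, hu = 800, pos = 800)
  run <- assay_run(flat, "enzymatic_2d")
  pc <- run$plate_controls
  expect_equal(pc$neg_median, pc$hu_median)
  expect_false(pc$growth_flag)      # equality satisfies neg >= hu >= pos
  expect_true(estimate_growth(run)$no_growth)

  inverted <- toy_screen_table(neg = 500, hu = 800, pos = 10)
  expect_true(assay_run(inverted, "enzymatic_2d")$plate_controls$growth_flag)

  nopos <- as.data.frame(toy_screen_table())
  nopos <- nopos[nopos$role != "positive_staurosporine", ]
  expect_error(suppressWarnings(assay_run(screen_table(nopos), "enzymatic_2d")),
               "missing a control role")
})

test_that("library manifest is validated", {
  man <- data.frame(compound_id = c("a", "b"), name = c("A", "B"),
                    target_class = c("MEK inhibitor", ""),
                    library_flag = c("fda_approved", "investigational"))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(man, f, row.names = FALSE)
  expect_equal(nrow(read_library_manifest(f)), 2)
  man$library_flag[2] <- "other"
  utils::write.csv(man, f, row.names = FALSE)
  expect_error(read_library_manifest(f), "library_flag")
})
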