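test_that("ingestion validates records and reports offending rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  ok <- make_trees(x = c(1, 50, 119), y = c(1, 70, 139))
  utils::write.csv(ok, path, row.names = FALSE)
  sm <- read_stem_map(path)
  expect_s3_class(sm, "stem_map")
  expect_equal(nrow(sm), 3)

  bad <- ok
  bad$hcb[2] <- 5
  bad$th[2] <- 4
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_stem_map(path), "row 2.*hcb")

  small <- ok
  small$dbh[1] <- 0.5   # below the 1 cm marking threshold
  utils::write.csv(small, path, row.names = FALSE)
  expect_error(read_stem_map(path), "marking threshold")
  expect_equal(nrow(suppressMessages(read_stem_map(path, mode = "lenient"))),
               2)

  # column renaming through a mapping config
  renamed <- ok
  names(renamed)[names(renamed) == "dbh"] <- "DBH_cm"
  utils::write.csv(renamed, path, row.names = FALSE)
  expect_equal(nrow(read_stem_map(path, column_map = c(dbh = "DBH_cm"))), 3)
  expect_error(read_stem_map(path, column_map = c(dbh = "nope")),
               "absent column")
})

test_that("stem maps round-trip through CSV without changing plot cells", {
  sm <- random_stand(40, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stem_map(sm, path)
  back <- assign_plots(read_stem_map(path, stand_width = 40,
                                     stand_height = 50))
  expect_equal(back$plot_id, sm$plot_id)
  expect_equal(back$dbh, sm$dbh, tolerance = 1e-12)
  expect_equal(back$cw, sm$cw, tolerance = 1e-12)
})

test_that("species grouping is total with an Others fallback", {
  expect_equal(classify_species_group("Betula luminifera"), "BL")
  expect_equal(classify_species_group("Pinus massoniana"), "PM")
  expect_equal(classify_species_group("Quercus fabri"), "Others")
  mixed <- classify_species_group(c("Liquidambar formosana", "x", NA))
  expect_equal(mixed, c("LF", "Others", "Others"))
})

test_that("gridding uses half-open cells closed on the upper stand edge", {
  sm <- make_stand(make_trees(x = c(0, 119.9, 120, 20, 19.999),
                              y = c(0, 139.9, 140, 20, 19.999)))
  expect_equal(sm$grid_x, c(0L, 5L, 5L, 1L, 0L))
  expect_equal(sm$grid_y, c(0L, 6L, 6L, 1L, 0L))
  expect_equal(n_grid_cells(sm), 42L)
  # partition: each tree in exactly one cell
  expect_true(all(table(sm$tree_id, sm$plot_id) %in% c(0L, 1L)))
  expect_error(stem_map(make_trees(x = 121, y = 5)), "outside the stand")
})

test_that("stand covariates: density, heights, diversity", {
  tr <- make_trees(x = runif(40, 0, 20), y = runif(40, 0, 20),
                   species = rep(c("Betula luminifera", "Pinus massoniana"),
                                 20))
  tr$species_group <- classify_species_group(tr$species_name)
  cov <- stand_covariates(tr)
  expect_equal(cov$den, 1000)        # 40 stems / 0.04 ha
  expect_equal(cov$shn, log(2))      # two equally abundant groups
  expect_equal(cov$n_trees, 40)

  tr3 <- make_trees(x = 1:3, y = 1:3, th = c(5, 10, 15))
  tr3$species_group <- "Others"
  expect_equal(stand_covariates(tr3, dominant_rule = function(t) rep(TRUE, 3))$mdh,
               10)
  expect_error(stand_covariates(tr3[0, ]), "empty plot")

  # Shannon diversity is label-permutation invariant and maximal at ln k
  set.seed(2)
  for (k in 2:4) {
    tr <- make_trees(x = runif(6 * k, 0, 20), y = runif(6 * k, 0, 20))
    tr$species_group <- rep(paste0("g", 1:k), each = 6)
    shn <- stand_covariates(tr)$shn
    expect_equal(shn, log(k))
    tr$species_group <- sample(tr$species_group)
    expect_lte(stand_covariates(tr)$shn, log(k) + 1e-12)
  }
})

test_that("dominant rule takes the largest stems with id tie-break", {
  tr <- make_trees(x = 1:6, y = 1:6, dbh = c(10, 20, 30, 20, 5, 1))
  dom <- dominant_top_n(4)(tr)
  expect_equal(sum(dom), 4)
  expect_true(all(which(dom) %in% 1:4))   # the 30, two 20s, and the 10
  expect_equal(sum(dominant_top_n(4)(tr[1:2, ])), 2)  # fewer than n: all
})

test_that("plot-level split conserves trees and is seed-deterministic", {
  # one tree in each of 39 distinct cells: the study's occupied-plot count
  cells <- expand.grid(gx = 0:5, gy = 0:6)[1:39, ]
  sm <- make_stand(make_trees(x = cells$gx * 20 + 10, y = cells$gy * 20 + 10))
  parts <- split_plots(sm, fraction = 0.8, seed = 42)
  expect_length(parts$calibration_plots, 31)
  expect_length(parts$validation_plots, 8)
  expect_identical(parts$calibration_plots,
                   split_plots(sm, fraction = 0.8, seed = 42)$calibration_plots)

  sm2 <- random_stand(60, seed = 9)
  for (seed in 1:5) {
    p <- split_plots(sm2, fraction = 0.8, seed = seed)
    expect_equal(nrow(p$calibration) + nrow(p$validation), nrow(sm2))
    expect_setequal(c(p$calibration$tree_id, p$validation$tree_id),
                    sm2$tree_id)
  }

  two <- make_stand(make_trees(x = c(5, 25), y = c(5, 5)))
  p2 <- split_plots(two, fraction = 0.5, seed = 1)
  expect_equal(nrow(p2$calibration), 1)
  expect_equal(nrow(p2$validation), 1)
  expect_error(split_plots(sm, fraction = 1.2), "between 0 and 1")
})
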