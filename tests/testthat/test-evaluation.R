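test_that("fit statistics reproduce their closed forms", {
  perfect <- fit_stats(1:10, 1:10, p = 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$r2_adj, 1)

  one <- suppressWarnings(fit_stats(2, 1, p = 0))
  expect_equal(one$mae, 1)
  expect_equal(one$mape, 0.5)
  expect_true(is.na(one$r2_adj))

  # predicting the mean makes RSS = TSS: adjusted R^2 = 1 - 9/8
  flat <- fit_stats(1:10, rep(5.5, 10), p = 1)
  expect_equal(flat$r2_adj, -0.125)

  expect_warning(fit_stats(c(0, 1), c(1, 1), p = 0), "MAPE")
})

test_that("fit statistics transform predictably under shifts and scalings", {
  set.seed(7)
  obs <- runif(50, 1, 9)
  pred <- obs + rnorm(50, 0, 0.5)
  base <- fit_stats(obs, pred, p = 2)
  expect_lte(base$mae, base$rmse)  # power-mean inequality
  shifted <- fit_stats(obs + 3, pred + 3, p = 2)
  expect_equal(shifted$rmse, base$rmse)
  expect_equal(shifted$mae, base$mae)
  scaled <- fit_stats(2 * obs, 2 * pred, p = 2)
  expect_equal(scaled$rmse, 2 * base$rmse)
  expect_equal(scaled$mae, 2 * base$mae)
  expect_equal(scaled$r2_adj, base$r2_adj)  # affine-invariant
  for (i in 1:10) {
    o <- runif(20, 1, 5)
    s <- fit_stats(o, o + rnorm(20), p = 1)
    expect_lte(s$mae, s$rmse)
  }
})

test_that("standardization divides by the modelled standard deviation", {
  fit <- fake_g_fit(c(0.9, 0.5, 0, 0, 0))
  dat <- data.frame(dbh = c(1, 4, 9), th = 0, hcb = 0, ci = 0,
                    cw = c(1, 2, 3))
  sr <- standardized_residuals(fit, dat)
  expect_equal(sr$std_residual, sr$residual / sqrt(fit$sigma2))

  m <- fake_mixed(c(0.9, 0.5, 0, 0, 0),
                  varfn = list(kind = "power", delta = -2, const = 0))
  dat$species_group <- "BL"
  dat$shgn <- 0
  srm <- standardized_residuals(m, dat)
  # at dbh = 1 the power weight is 1: divisor is sigma alone
  expect_equal(srm$std_residual[1], srm$residual[1] / sqrt(m$sigma2))
  # elsewhere the divisor is sigma * dbh^(delta/2)
  expect_equal(srm$std_residual[2],
               srm$residual[2] / (sqrt(m$sigma2) * 4^(-1)))
})

test_that("whitening: a correctly specified variance model flattens the
           residual-diameter trend", {
  g <- generate_stand(stand_config(n_trees = 700), seed = 29)
  mf <- model_frame(g$stand, g$ci_table)
  m <- fit_cw_mixed(mf, ci_kind = "SHGN", random = c("phi2", "phi5"),
                    varfn = "power")
  sr <- standardized_residuals(m, mf)
  trend <- summary(stats::lm(abs(std_residual) ~ dbh, data = sr))
  expect_gt(stats::coef(trend)[2, 4], 0.01)  # no significant |r|-D slope
})

test_that("curve simulation sweeps one covariate and is spot-identical to
           direct evaluation", {
  phi <- c(0.901, 0.441, -0.001, 0.066, -0.042)
  fit <- fake_g_fit(phi)
  curves <- simulate_cw_curves(fit, vary = "CI")
  expect_equal(nrow(curves), 600)
  expect_setequal(unique(curves$level), c(10, 50, 90, 130, 170, 210))
  # phi3 < 0: more competition, narrower crown at fixed diameter
  at_d <- curves[abs(curves$dbh - curves$dbh[50]) < 1e-9, ]
  expect_true(all(diff(at_d$cw[order(at_d$level)]) < 0))
  expect_true(all(tapply(curves$cw, curves$level,
                         function(z) all(diff(z) > 0))))  # monotone in d

  th_curves <- simulate_cw_curves(fit, vary = "TH")
  at_d_th <- th_curves[abs(th_curves$dbh - th_curves$dbh[50]) < 1e-9, ]
  expect_true(all(diff(at_d_th$cw[order(at_d_th$level)]) > 0))  # phi4 > 0

  row <- curves[123, ]
  expect_equal(row$cw,
               evaluate_form("G", phi, d = row$dbh, th = 25, hcb = 4,
                             ci = row$level))
})

test_that("cross-index regression returns exact OLS and rejects degenerate
           input", {
  tab <- data.frame(SRD = c(1, 2, 3, 4, 5), SHGN = 2 * c(1, 2, 3, 4, 5))
  xr <- cross_index_regression(tab)
  expect_equal(xr$slope, 2)
  expect_equal(xr$intercept, 0)
  expect_equal(xr$r2, 1)
  expect_equal(xr$n_plots, 5)
  expect_error(cross_index_regression(data.frame(SRD = rep(1, 5),
                                                 SHGN = 1:5)),
               "degenerate")
  expect_error(cross_index_regression(tab[1:2, ]), "at least 3")
})
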