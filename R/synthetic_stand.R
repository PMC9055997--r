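#' Configuration of the synthetic stand generator
#'
#' Defaults emulate the study system: a 120 x 140 m stand gridded into
#' 20 x 20 m plots holding about 2,800 stems of six species groups, DBH on
#' [1, 46.3] cm, total height on [1.5, 21.3] m, crown base below the tip,
#' and crown width generated from the fitted spatially explicit mixed model
#' (generalized power form with SHGN as competition index, species random
#' effects on \code{phi2} and \code{phi5}, and power-variance residual
#' noise).
#'
#' Distribution parameters were frozen by moment matching against the
#' study's calibration summaries: a truncated lognormal DBH
#' (\code{meanlog = 1.714}, \code{sdlog = 0.531}) reproduces mean 6.4 cm /
#' SD 3.7 cm on [1, 46.3]; height follows the allometry
#' \code{th = 2.747 * dbh^0.55} plus Gaussian noise (SD 1.2 m) clipped to
#' [1.5, 21.3] m; crown-base height is a Beta(3.14, 3.55) fraction of total
#' height (mean 0.47), which keeps \code{0 < hcb < th} by construction.
#'
#' The generative covariance \code{psi} of \code{(u2, u5)} is exactly
#' singular (correlation -1) at the default values; any slightly indefinite
#' input (a printed-precision artifact) is projected to the nearest
#' positive semi-definite matrix before drawing.
#'
#' @param n_trees target stem count.
#' @param stand_width,stand_height stand dimensions, m.
#' @param plot_size grid cell side, m.
#' @param pattern spatial pattern: uniform (binomial/homogeneous-Poisson
#'   conditioned on the count) or a parent-offspring cluster process.
#' @param n_parents,cluster_sd cluster process settings: parent count and
#'   Gaussian offspring spread (m).
#' @param mixture named probabilities over the six species groups.
#' @param dbh_meanlog,dbh_sdlog,dbh_range truncated-lognormal DBH law, cm.
#' @param th_a,th_b,th_sd,th_range height allometry \code{a*dbh^b} + noise.
#' @param hcb_shape1,hcb_shape2 Beta law of the crown-base fraction.
#' @param beta generative fixed effects \code{phi1..phi5} of the
#'   generalized form.
#' @param ci_kind competition index entering the generative form.
#' @param random parameters carrying species random effects.
#' @param psi covariance of the species random effects (over \code{random}).
#' @param sigma2,delta residual power-variance law
#'   \code{var(eps) = sigma2 * dbh^delta}.
#' @param cw_floor smallest emitted crown width, m.
#' @param radius,n_competitors,edge competition settings used when
#'   computing the generative plot indices.
#' @param seed default seed used by \code{\link{generate_stand}}.
#' @return A \code{stand_config} list.
#' @export
stand_config <- function(n_trees = 2800,
                         stand_width = 120, stand_height = 140,
                         plot_size = 20,
                         pattern = c("uniform", "cluster"),
                         n_parents = 60, cluster_sd = 8,
                         mixture = c(BL = 0.22, PS = 0.18, PM = 0.12,
                                     LF = 0.10, PD = 0.08, Others = 0.30),
                         dbh_meanlog = 1.714, dbh_sdlog = 0.531,
                         dbh_range = c(1, 46.3),
                         th_a = 2.747, th_b = 0.55, th_sd = 1.2,
                         th_range = c(1.5, 21.3),
                         hcb_shape1 = 3.14, hcb_shape2 = 3.55,
                         beta = c(phi1 = 1.057, phi2 = 0.410,
                                  phi3 = -0.003, phi4 = 0.057,
                                  phi5 = -0.022),
                         ci_kind = c("SHGN", "SRD"),
                         random = c("phi2", "phi5"),
                         psi = matrix(c(0.002, -0.001, -0.001, 0.0005), 2, 2,
                                      dimnames = list(c("phi2", "phi5"),
                                                      c("phi2", "phi5"))),
                         sigma2 = 0.713, delta = -2.722,
                         cw_floor = 0.1,
                         radius = 5, n_competitors = 4, edge = "torus",
                         seed = 1) {
  pattern <- match.arg(pattern)
  ci_kind <- match.arg(ci_kind)
  if (abs(sum(mixture) - 1) > 1e-8) stop("species mixture must sum to 1")
  if (length(random) && !isTRUE(all.equal(dim(psi),
                                          rep(length(random), 2)))) {
    stop("psi dimensions must match the random-effect subset")
  }
  mean_dbh <- exp(dbh_meanlog + dbh_sdlog^2 / 2)
  if (mean_dbh < dbh_range[1] || mean_dbh > dbh_range[2]) {
    stop("dbh law mean lies outside the truncation range: infeasible config")
  }
  cfg <- as.list(environment())
  class(cfg) <- "stand_config"
  cfg
}

# truncated lognormal draw by inverse-CDF restriction
.rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  lo <- stats::plnorm(range[1], meanlog, sdlog)
  hi <- stats::plnorm(range[2], meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

#' Generate a synthetic stem-mapped stand with known truth
#'
#' Places trees, draws sizes and species, computes the plot-level
#' competition indices through the competition module, draws species
#' random effects from \code{psi}, and sets crown width to the generalized
#' power form's mean plus heteroscedastic Gaussian noise with standard
#' deviation \code{sqrt(sigma2) * dbh^(delta/2)}, floored at
#' \code{cw_floor}. Fully reproducible from the seed.
#'
#' @param config a \code{\link{stand_config}}.
#' @param seed integer seed; defaults to the config's.
#' @return List with \code{stand} (a \code{stem_map} with plots assigned),
#'   \code{ci_table} (all six indices per plot), \code{summaries}
#'   (\code{\link{plot_summaries}}), and \code{truth} (beta, psi, sigma2,
#'   delta, the realized per-species random-effect draws \code{u}, ci_kind
#'   and the seed).
#' @export
generate_stand <- function(config = stand_config(), seed = config$seed) {
  stopifnot(inherits(config, "stand_config"))
  set.seed(seed)
  n <- config$n_trees
  w <- config$stand_width
  h <- config$stand_height

  if (config$pattern == "uniform") {
    x <- stats::runif(n, 0, w)
    y <- stats::runif(n, 0, h)
  } else {
    px <- stats::runif(config$n_parents, 0, w)
    py <- stats::runif(config$n_parents, 0, h)
    parent <- sample.int(config$n_parents, n, replace = TRUE)
    # offspring wrapped onto the stand torus so intensity stays uniform
    x <- (px[parent] + stats::rnorm(n, 0, config$cluster_sd)) %% w
    y <- (py[parent] + stats::rnorm(n, 0, config$cluster_sd)) %% h
  }

  groups <- sample(names(config$mixture), n, replace = TRUE,
                   prob = config$mixture)
  group_names <- c(BL = "Betula luminifera", PS = "Platycarya strobilacea",
                   PM = "Pinus massoniana", LF = "Liquidambar formosana",
                   PD = "Populus davidiana", Others = "Miscellaneous species")
  dbh <- .rlnorm_trunc(n, config$dbh_meanlog, config$dbh_sdlog,
                       config$dbh_range)
  th <- config$th_a * dbh^config$th_b + stats::rnorm(n, 0, config$th_sd)
  th <- pmin(pmax(th, config$th_range[1]), config$th_range[2])
  hcb <- th * stats::rbeta(n, config$hcb_shape1, config$hcb_shape2)

  trees <- data.frame(
    tree_id = sprintf("t%04d", seq_len(n)),
    species_name = unname(group_names[groups]),
    species_group = groups,
    x = x, y = y, dbh = dbh, th = th, hcb = hcb,
    cw = 1)  # placeholder until the generative law is applied
  stand <- stem_map(trees, stand_width = w, stand_height = h,
                    plot_size = config$plot_size)
  stand <- assign_plots(stand)

  ci_table <- competition_indices(stand, radius = config$radius,
                                  n_competitors = config$n_competitors,
                                  edge = config$edge)
  ci <- ci_table[[config$ci_kind]][match(stand$plot_id, ci_table$plot_id)]

  # species random effects: u is species x 5, zero outside `random`
  levels <- names(config$mixture)
  u <- matrix(0, length(levels), 5,
              dimnames = list(levels, paste0("phi", 1:5)))
  if (length(config$random)) {
    psi <- .psd_project(config$psi)
    draws <- MASS::mvrnorm(length(levels), mu = rep(0, ncol(psi)),
                           Sigma = psi)
    u[, config$random] <- draws
  }
  b <- config$beta
  usp <- u[stand$species_group, , drop = FALSE]
  mean_cw <- (b["phi1"] + usp[, "phi1"] +
                (b["phi3"] + usp[, "phi3"]) * ci +
                (b["phi4"] + usp[, "phi4"]) * stand$th +
                (b["phi5"] + usp[, "phi5"]) * stand$hcb) *
    stand$dbh^(b["phi2"] + usp[, "phi2"])
  noise_sd <- sqrt(config$sigma2) * stand$dbh^(config$delta / 2)
  stand$cw <- unname(pmax(mean_cw + stats::rnorm(n, 0, noise_sd),
                          config$cw_floor))

  list(stand = stand,
       ci_table = ci_table,
       summaries = plot_summaries(stand),
       truth = list(beta = b, psi = config$psi, sigma2 = config$sigma2,
                    delta = config$delta, u = u, ci_kind = config$ci_kind,
                    random = config$random, seed = seed))
}
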