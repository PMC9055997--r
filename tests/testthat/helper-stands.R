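# In-code fixtures: small stands built directly, plus an independent
# brute-force Hegyi oracle used to cross-check the neighbour-search path.

make_trees <- function(x, y, dbh = 10, th = 8, hcb = 3, cw = 2,
                       species = "Miscellaneous species", id = NULL) {
  n <- length(x)
  data.frame(
    tree_id = if (is.null(id)) sprintf("t%03d", seq_len(n)) else id,
    species_name = rep_len(species, n),
    x = x, y = y,
    dbh = rep_len(dbh, n), th = rep_len(th, n),
    hcb = rep_len(hcb, n), cw = rep_len(cw, n))
}

make_stand <- function(trees, w = 120, h = 140, s = 20) {
  assign_plots(stem_map(trees, stand_width = w, stand_height = h,
                        plot_size = s))
}

random_stand <- function(n, seed, w = 40, h = 50, s = 20) {
  set.seed(seed)
  make_stand(make_trees(x = runif(n, 0, w), y = runif(n, 0, h),
                        dbh = exp(rnorm(n, 1.7, 0.5)) + 1,
                        th = runif(n, 2, 15), hcb = runif(n, 0.5, 1.9),
                        cw = runif(n, 0.5, 6)),
             w = w, h = h, s = s)
}

# Brute-force fixed-radius Hegyi index of one subject: explicit double loop
# over all trees and all nine translation copies, entirely independent of
# the package's neighbour search.
hegyi_radius_brute <- function(i, stand, radius = 5) {
  w <- attr(stand, "stand_width")
  h <- attr(stand, "stand_height")
  total <- 0
  for (j in seq_len(nrow(stand))) {
    if (j == i) next
    best <- Inf
    for (ox in c(-w, 0, w)) {
      for (oy in c(-h, 0, h)) {
        d <- sqrt((stand$x[j] + ox - stand$x[i])^2 +
                    (stand$y[j] + oy - stand$y[i])^2)
        if (d < best) best <- d
      }
    }
    if (best <= radius) {
      total <- total + stand$dbh[j] / (stand$dbh[i] * (best + 1))
    }
  }
  total
}

shgr_plot_brute <- function(stand, plot_id, radius = 5) {
  idx <- which(stand$plot_id == plot_id)
  sum(vapply(idx, hegyi_radius_brute, numeric(1), stand = stand,
             radius = radius))
}

# minimal generalized-form fixed-effects fit object for prediction tests
fake_g_fit <- function(phi, ci_kind = "SRD") {
  structure(list(form_id = "G", phi = phi, converged = TRUE,
                 sigma2 = 0.5, ci_kind = ci_kind, n = 100),
            class = "cw_fit")
}

fake_mixed <- function(fixed, random = c("phi2", "phi5"),
                       blups = NULL, groups = c("BL", "PS"),
                       sigma2 = 0.5,
                       varfn = list(kind = "power", delta = -2, const = 0),
                       ci_kind = "SHGN") {
  if (is.null(blups)) {
    blups <- matrix(0, length(groups), length(random),
                    dimnames = list(groups, random))
  }
  structure(list(fixed = stats::setNames(fixed, paste0("phi", 1:5)),
                 psi = diag(length(random)), sigma2 = sigma2,
                 varfn = varfn, blups = blups, converged = TRUE,
                 random = random, ci_kind = ci_kind,
                 groups = rownames(blups)),
            class = "cw_mixed")
}
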