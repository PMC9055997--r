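#' Enumerate candidate random-effects structures
#'
#' All non-empty subsets of the generalized form's parameters
#' \code{phi1..phi_npar} that may carry a species-level random effect:
#' \code{2^npar - 1} structures (31 for the five-parameter form), ordered
#' by subset size then lexicographically, so the search is deterministic.
#'
#' @param npar number of parameters of the form (5 for form \code{"G"}).
#' @return List of character vectors, e.g. \code{c("phi2", "phi5")}.
#' @export
enumerate_random_structures <- function(npar = 5) {
  stopifnot(npar >= 1)
  pars <- paste0("phi", seq_len(npar))
  out <- list()
  for (size in seq_len(npar)) {
    idx <- utils::combn(npar, size, simplify = FALSE)
    out <- c(out, lapply(idx, function(i) pars[i]))
  }
  out
}

# project a covariance matrix to the nearest PSD matrix (eigenvalue clip);
# printed-precision psi inputs can be slightly indefinite
.psd_project <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% diag(v, nrow = length(v)) %*% t(e$vectors)
  dimnames(out) <- dimnames(m)
  out
}

# residual standard deviation at dbh d for a fitted variance function;
# var(eps) = sigma2 * g(d)^2
.varfn_sd <- function(sigma2, varfn, d) {
  g <- switch(varfn$kind,
    constant = rep(1, length(d)),
    power = abs(d)^(varfn$delta / 2),
    exponential = exp(varfn$delta * d / 2),
    constant_plus_power = abs(varfn$const + abs(d)^(varfn$delta / 2))
  )
  sqrt(sigma2) * g
}

#' Fit the species-level nonlinear mixed-effects crown-width model
#'
#' Estimates the generalized power form
#' \deqn{CW = (\phi_1 + \phi_3 CI + \phi_4 TH + \phi_5 HCB) D^{\phi_2} + \epsilon}
#' with species-group random effects on the parameters named in
#' \code{random} (unstructured covariance \code{psi}) and a residual
#' variance function, by maximum likelihood with the Lindstrom-Bates
#' alternating algorithm (\pkg{nlme} backend). ML rather than REML is used
#' so AIC is comparable across random structures and with the
#' fixed-effects-only fits.
#'
#' Variance functions, with \code{d} the tree's DBH:
#' \code{"constant"} var = sigma2; \code{"power"} var = sigma2 * d^delta;
#' \code{"exponential"} var = sigma2 * exp(delta * d);
#' \code{"constant_plus_power"} var = sigma2 * (c + d^(delta/2))^2.
#' \code{delta} is reported on this variance scale (twice the \pkg{nlme}
#' per-sd coefficient).
#'
#' @param data model frame with \code{cw}, \code{dbh}, \code{th},
#'   \code{hcb}, \code{species_group} and the competition-index column
#'   selected by \code{ci_kind} (see \code{\link{model_frame}}).
#' @param ci_kind \code{"SRD"} or \code{"SHGN"}.
#' @param random character vector of parameters carrying random effects,
#'   e.g. \code{c("phi2", "phi5")}.
#' @param varfn variance-function kind.
#' @param start optional named fixed-effect start; defaults to the
#'   fixed-effects NLS fit of the same form.
#' @param max_iter outer iteration cap passed to the optimizer.
#' @return Object of class \code{cw_mixed}: list with \code{fixed} (named
#'   phi1..phi5), \code{psi}, \code{sigma2}, \code{varfn} (kind, delta,
#'   const), \code{blups} (matrix, species x random parameters),
#'   \code{logLik}, \code{aic}, \code{n_params}, \code{converged},
#'   \code{random}, \code{ci_kind}, \code{n}, \code{groups} and the
#'   underlying \code{nlme} object (\code{fit}).
#' @export
fit_cw_mixed <- function(data, ci_kind = c("SRD", "SHGN"),
                         random = c("phi2", "phi5"),
                         varfn = c("power", "exponential",
                                   "constant_plus_power", "constant"),
                         start = NULL, max_iter = 100) {
  ci_kind <- match.arg(ci_kind)
  varfn <- match.arg(varfn)
  stopifnot(length(random) >= 1,
            all(random %in% paste0("phi", 1:5)))
  data <- as.data.frame(data)
  data$ci <- data[[tolower(ci_kind)]]
  if (is.null(data$ci)) stop("data lacks competition-index column ",
                             tolower(ci_kind))
  data$species_group <- factor(data$species_group)
  if (nlevels(data$species_group) < 2) {
    stop("need at least 2 species groups to estimate a random effect")
  }
  if (any(table(data$species_group) < 2)) {
    stop("every species group needs at least 2 observations")
  }
  if (is.null(start)) {
    base <- fit_cw("G", data, ci_kind = ci_kind)
    if (!base$converged) stop("fixed-effects start fit did not converge")
    start <- base$phi
  }
  random <- paste0("phi", sort(as.integer(sub("phi", "", random))))
  ran_formula <- stats::as.formula(
    paste(paste(random, collapse = " + "), "~ 1 | species_group"))
  weights <- switch(varfn,
    constant = NULL,
    power = nlme::varPower(form = ~dbh),
    exponential = nlme::varExp(form = ~dbh),
    constant_plus_power = nlme::varConstPower(form = ~dbh))
  args <- list(
    model = cw ~ (phi1 + phi3 * ci + phi4 * th + phi5 * hcb) * dbh^phi2,
    data = data,
    fixed = phi1 + phi2 + phi3 + phi4 + phi5 ~ 1,
    random = ran_formula,
    groups = ~species_group,
    start = unname(start[paste0("phi", 1:5)]),
    method = "ML",
    control = nlme::nlmeControl(maxIter = max_iter, pnlsMaxIter = 15,
                                msMaxIter = 200, returnObject = FALSE))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(nlme::nlme, args), error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(converged = FALSE, random = random, varfn = list(kind = varfn),
                ci_kind = ci_kind, n = nrow(data),
                message = conditionMessage(fit), fit = NULL)
    class(out) <- "cw_mixed"
    return(out)
  }
  fixed <- nlme::fixef(fit)
  names(fixed) <- paste0("phi", 1:5)
  # psi = sigma^2 * relative covariance of the random effects
  psi <- fit$sigma^2 * as.matrix(fit$modelStruct$reStruct[[1]])
  dimnames(psi) <- list(random, random)
  sigma2 <- fit$sigma^2
  vf <- list(kind = varfn, delta = 0, const = 0)
  if (varfn %in% c("power", "exponential")) {
    vf$delta <- 2 * as.numeric(stats::coef(fit$modelStruct$varStruct))
  } else if (varfn == "constant_plus_power") {
    vc <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE)
    vf$const <- as.numeric(vc["const"])
    vf$delta <- 2 * as.numeric(vc["power"])
  }
  blups <- as.matrix(nlme::ranef(fit))
  colnames(blups) <- random
  ll <- as.numeric(stats::logLik(fit))
  # p: 5 fixed + distinct psi entries + sigma2 + variance-function params
  q <- length(random)
  n_params <- 5 + q * (q + 1) / 2 + 1 +
    switch(varfn, constant = 0, power = 1, exponential = 1,
           constant_plus_power = 2)
  out <- list(fixed = fixed, psi = psi, sigma2 = sigma2, varfn = vf,
              blups = blups, logLik = ll, aic = -2 * ll + 2 * n_params,
              n_params = n_params, converged = TRUE, random = random,
              ci_kind = ci_kind, n = nrow(data),
              groups = rownames(blups), message = NULL, fit = fit)
  class(out) <- "cw_mixed"
  out
}

#' @export
print.cw_mixed <- function(x, ...) {
  cat(sprintf("Species-level mixed crown-width model (CI = %s)\n", x$ci_kind))
  if (!x$converged) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat("  fixed effects:\n")
  print(round(x$fixed, 4))
  cat(sprintf("  random effects on {%s}, psi diagonal: %s\n",
              paste(x$random, collapse = ", "),
              paste(sprintf("%.3g", diag(x$psi)), collapse = ", ")))
  cat(sprintf("  sigma2 = %.4g, variance function = %s (delta = %.3f)\n",
              x$sigma2, x$varfn$kind, x$varfn$delta))
  cat(sprintf("  logLik = %.2f, AIC = %.1f (p = %d), n = %d, %d groups\n",
              x$logLik, x$aic, x$n_params, x$n, length(x$groups)))
  invisible(x)
}

#' Predict crown width from a fitted mixed model
#'
#' Population-mode prediction sets every random effect to zero; group mode
#' adds the fitted species BLUPs. Species unseen at fitting time fall back
#' to the population prediction (with a note).
#'
#' @param object a converged \code{cw_mixed}.
#' @param newdata data frame with \code{dbh}, \code{th}, \code{hcb}, the
#'   competition-index column matching the model's \code{ci_kind} (or a
#'   \code{ci} column), and \code{species_group} for group mode.
#' @param level \code{"population"} or \code{"group"}.
#' @return Numeric vector of predicted crown widths, m.
#' @export
predict_cw_mixed <- function(object, newdata,
                             level = c("population", "group")) {
  level <- match.arg(level)
  if (!object$converged) stop("cannot predict from a non-converged fit")
  newdata <- as.data.frame(newdata)
  ci <- if (!is.null(newdata$ci)) newdata$ci else {
    newdata[[tolower(object$ci_kind)]]
  }
  if (is.null(ci)) stop("newdata lacks competition-index column ",
                        tolower(object$ci_kind))
  n <- nrow(newdata)
  phi <- matrix(rep(object$fixed, each = n), nrow = n,
                dimnames = list(NULL, names(object$fixed)))
  if (level == "group") {
    if (is.null(newdata$species_group)) {
      stop("group-level prediction requires species_group")
    }
    sp <- as.character(newdata$species_group)
    known <- sp %in% rownames(object$blups)
    if (any(!known)) {
      message(sprintf(
        "species group(s) %s unseen at fitting time; using population-level prediction",
        paste(unique(sp[!known]), collapse = ", ")))
    }
    for (par in object$random) {
      add <- ifelse(known, object$blups[match(sp, rownames(object$blups)),
                                        par], 0)
      phi[, par] <- phi[, par] + add
    }
  }
  unname((phi[, "phi1"] + phi[, "phi3"] * ci + phi[, "phi4"] * newdata$th +
            phi[, "phi5"] * newdata$hcb) * newdata$dbh^phi[, "phi2"])
}

#' Exhaustive random-effects structure search
#'
#' Fits every candidate random-effects structure (all 31 non-empty
#' parameter subsets for the five-parameter form, or a supplied subset of
#' them) crossed with the requested variance-function kinds, by maximum
#' likelihood, and returns the converged fit with the smallest AIC together
#' with a full report. Non-converged combinations are retained in the
#' report with \code{NA} AIC.
#'
#' @inheritParams fit_cw_mixed
#' @param varfn_kinds character vector of variance-function kinds to cross
#'   with the structures.
#' @param structures list of random-effects subsets; default all 31.
#' @param verbose print one line per fit.
#' @return List with \code{best} (a \code{cw_mixed}, or \code{NULL} when
#'   nothing converged) and \code{report} (data frame with
#'   \code{structure}, \code{varfn}, \code{converged}, \code{aic},
#'   \code{logLik}, \code{n_params}).
#' @export
select_random_structure <- function(data, ci_kind = c("SRD", "SHGN"),
                                    varfn_kinds = "power",
                                    structures = enumerate_random_structures(5),
                                    start = NULL, max_iter = 50,
                                    verbose = FALSE) {
  ci_kind <- match.arg(ci_kind)
  if (is.null(start)) {
    base <- fit_cw("G", data, ci_kind = ci_kind)
    if (!base$converged) stop("fixed-effects start fit did not converge")
    start <- base$phi
  }
  best <- NULL
  rows <- list()
  for (vf in varfn_kinds) {
    for (rs in structures) {
      # screening context: optimizer chatter from hopeless structures is
      # expected, only the converged/AIC outcome matters here
      m <- suppressWarnings(
        fit_cw_mixed(data, ci_kind = ci_kind, random = rs, varfn = vf,
                     start = start, max_iter = max_iter))
      label <- paste(rs, collapse = "+")
      if (verbose) {
        cat(sprintf("  %-28s %-20s %s\n", label, vf,
                    if (m$converged) sprintf("AIC %.1f", m$aic)
                    else "not converged"))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        structure = label, varfn = vf, converged = m$converged,
        aic = if (m$converged) m$aic else NA_real_,
        logLik = if (m$converged) m$logLik else NA_real_,
        n_params = if (m$converged) m$n_params else NA_integer_)
      if (m$converged && (is.null(best) || m$aic < best$aic)) best <- m
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (is.null(best)) {
    warning("no random-effects structure converged")
  }
  list(best = best, report = report)
}
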