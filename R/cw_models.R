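#' Candidate crown-width-diameter model forms
#'
#' The twelve classical CW-D shapes used for basic-model screening, plus
#' the covariate-generalized power form \code{"G"}:
#' \describe{
#'   \item{F1}{linear, \code{phi1 + phi2*D}}
#'   \item{F2}{power, \code{phi1*D^phi2}}
#'   \item{F3}{monomolecular, \code{phi1*(1 - exp(-phi2*D))}}
#'   \item{F4}{Hossfeld, \code{(D/(phi1 + phi2*D))^2}}
#'   \item{F5}{compound, \code{phi1*phi2^D}}
#'   \item{F6}{growth, \code{exp(phi1 + phi2*D)}}
#'   \item{F7}{exponential, \code{phi1*exp(phi2*D)}}
#'   \item{F8}{quadratic, \code{phi1 + phi2*D + phi3*D^2}}
#'   \item{F9}{Richards, \code{phi1*(1 - exp(-phi2*D))^phi3}}
#'   \item{F10}{logistic, \code{phi1/(1 + phi2*exp(-phi3*D))}}
#'   \item{F11}{log-logistic, \code{phi1/(1 + exp(phi2 + phi3*log(D + 1)))}}
#'   \item{F12}{Weibull, \code{phi1*(1 - exp(-phi2*D^phi3))}}
#'   \item{G}{\code{(phi1 + phi3*CI + phi4*TH + phi5*HCB)*D^phi2}, the
#'     power form generalized with a plot-level competition index CI
#'     (SRD or SHGN), tree height and height to crown base}
#' }
#' F5, F6 and F7 are reparameterizations of one exponential curve and fit
#' identically; they are screened separately because their parameters carry
#' different interpretations in the literature.
#'
#' @return Character vector of form ids.
#' @export
cw_form_ids <- function() c(paste0("F", 1:12), "G")

#' Number of parameters of a model form
#' @param form_id a form id, see \code{\link{cw_form_ids}}.
#' @return Integer parameter count.
#' @export
cw_form_arity <- function(form_id) {
  arity <- c(F1 = 2L, F2 = 2L, F3 = 2L, F4 = 2L, F5 = 2L, F6 = 2L, F7 = 2L,
             F8 = 3L, F9 = 3L, F10 = 3L, F11 = 3L, F12 = 3L, G = 5L)
  out <- arity[[match.arg(form_id, names(arity))]]
  out
}

#' Evaluate a crown-width model form
#'
#' Closed-form prediction of crown width (m) from DBH (cm) and, for the
#' generalized form, tree height (m), height to crown base (m) and a
#' plot-level competition index. Vector inputs recycle elementwise.
#'
#' @param form_id form id, see \code{\link{cw_form_ids}}.
#' @param phi numeric parameter vector of length \code{cw_form_arity(form_id)}.
#' @param d DBH, cm.
#' @param th,hcb,ci covariates, required for form \code{"G"} only.
#' @return Predicted crown width, m.
#' @examples
#' evaluate_form("F2", c(0.861, 0.620), d = 10)
#' @export
evaluate_form <- function(form_id, phi, d, th = NULL, hcb = NULL, ci = NULL) {
  form_id <- match.arg(form_id, cw_form_ids())
  if (length(phi) != cw_form_arity(form_id)) {
    stop(sprintf("form %s needs %d parameters, got %d", form_id,
                 cw_form_arity(form_id), length(phi)))
  }
  if (form_id == "G" && (is.null(th) || is.null(hcb) || is.null(ci))) {
    stop("form G requires th, hcb and ci")
  }
  p <- phi
  switch(form_id,
    F1  = p[1] + p[2] * d,
    F2  = p[1] * d^p[2],
    F3  = p[1] * (1 - exp(-p[2] * d)),
    F4  = (d / (p[1] + p[2] * d))^2,
    F5  = p[1] * p[2]^d,
    F6  = exp(p[1] + p[2] * d),
    F7  = p[1] * exp(p[2] * d),
    F8  = p[1] + p[2] * d + p[3] * d^2,
    F9  = p[1] * (1 - exp(-p[2] * d))^p[3],
    F10 = p[1] / (1 + p[2] * exp(-p[3] * d)),
    F11 = p[1] / (1 + exp(p[2] + p[3] * log(d + 1))),
    F12 = p[1] * (1 - exp(-p[2] * d^p[3])),
    G   = (p[1] + p[3] * ci + p[4] * th + p[5] * hcb) * d^p[2]
  )
}

# nls model formulas per form, over columns cw, dbh (and ci/th/hcb for G)
.cw_form_formula <- function(form_id) {
  switch(form_id,
    F1  = cw ~ phi1 + phi2 * dbh,
    F2  = cw ~ phi1 * dbh^phi2,
    F3  = cw ~ phi1 * (1 - exp(-phi2 * dbh)),
    F4  = cw ~ (dbh / (phi1 + phi2 * dbh))^2,
    F5  = cw ~ phi1 * phi2^dbh,
    F6  = cw ~ exp(phi1 + phi2 * dbh),
    F7  = cw ~ phi1 * exp(phi2 * dbh),
    F8  = cw ~ phi1 + phi2 * dbh + phi3 * dbh^2,
    F9  = cw ~ phi1 * (1 - exp(-phi2 * dbh))^phi3,
    F10 = cw ~ phi1 / (1 + phi2 * exp(-phi3 * dbh)),
    F11 = cw ~ phi1 / (1 + exp(phi2 + phi3 * log(dbh + 1))),
    F12 = cw ~ phi1 * (1 - exp(-phi2 * dbh^phi3)),
    G   = cw ~ (phi1 + phi3 * ci + phi4 * th + phi5 * hcb) * dbh^phi2
  )
}

# Initial values per form. Linearizable forms start from the exact linear
# (or log/logit-linear) solution; sigmoids pin the asymptote slightly above
# the observed maximum first.
.cw_form_start <- function(form_id, data) {
  d <- data$dbh
  cw <- data$cw
  loglog <- stats::coef(stats::lm(log(cw) ~ log(d)))
  amax <- 1.2 * max(cw)
  safe_frac <- pmin(pmax(cw / amax, 1e-6), 1 - 1e-6)
  switch(form_id,
    F1 = {
      b <- stats::coef(stats::lm(cw ~ d))
      list(phi1 = unname(b[1]), phi2 = unname(b[2]))
    },
    F2 = list(phi1 = unname(exp(loglog[1])), phi2 = unname(loglog[2])),
    F3 = list(phi1 = amax, phi2 = unname(mean(cw) / (amax * mean(d)))),
    F4 = {
      b <- stats::coef(stats::lm(I(1 / sqrt(cw)) ~ I(1 / d)))
      list(phi1 = unname(b[2]), phi2 = unname(b[1]))
    },
    F5 = {
      b <- stats::coef(stats::lm(log(cw) ~ d))
      list(phi1 = unname(exp(b[1])), phi2 = unname(exp(b[2])))
    },
    F6 = {
      b <- stats::coef(stats::lm(log(cw) ~ d))
      list(phi1 = unname(b[1]), phi2 = unname(b[2]))
    },
    F7 = {
      b <- stats::coef(stats::lm(log(cw) ~ d))
      list(phi1 = unname(exp(b[1])), phi2 = unname(b[2]))
    },
    F8 = {
      b <- stats::coef(stats::lm(cw ~ d + I(d^2)))
      list(phi1 = unname(b[1]), phi2 = unname(b[2]), phi3 = unname(b[3]))
    },
    F9 = list(phi1 = amax, phi2 = unname(mean(cw) / (amax * mean(d))),
              phi3 = 1),
    F10 = {
      b <- stats::coef(stats::lm(log(1 / safe_frac - 1) ~ d))
      list(phi1 = amax, phi2 = unname(exp(b[1])), phi3 = unname(-b[2]))
    },
    F11 = {
      b <- stats::coef(stats::lm(log(1 / safe_frac - 1) ~ log(d + 1)))
      list(phi1 = amax, phi2 = unname(b[1]), phi3 = unname(b[2]))
    },
    F12 = {
      b <- stats::coef(stats::lm(log(-log(1 - safe_frac)) ~ log(d)))
      list(phi1 = amax, phi2 = unname(exp(b[1])), phi3 = unname(b[2]))
    },
    G = list(phi1 = unname(exp(loglog[1])), phi2 = unname(loglog[2]),
             phi3 = 0, phi4 = 0, phi5 = 0)
  )
}

#' Attach per-tree competition-index covariates to a model frame
#'
#' Joins a stem map to a plot-level competition-index table (see
#' \code{\link{competition_indices}}) so that every tree carries its plot's
#' \code{srd} and \code{shgn} values, the covariates of the generalized
#' form.
#'
#' @param stand a \code{stem_map} with plots assigned.
#' @param ci_table output of \code{\link{competition_indices}} for the full
#'   stand (or a compatible data frame keyed by \code{plot_id}).
#' @return Data frame with columns \code{cw}, \code{dbh}, \code{th},
#'   \code{hcb}, \code{species_group}, \code{plot_id}, \code{srd},
#'   \code{shgn}.
#' @export
model_frame <- function(stand, ci_table) {
  if (is.null(stand$plot_id)) stand <- assign_plots(stand)
  m <- match(stand$plot_id, ci_table$plot_id)
  if (anyNA(m)) stop("ci_table lacks rows for plot(s): ",
                     paste(unique(stand$plot_id[is.na(m)]), collapse = ", "))
  data.frame(tree_id = stand$tree_id, plot_id = stand$plot_id,
             species_group = stand$species_group,
             cw = stand$cw, dbh = stand$dbh, th = stand$th, hcb = stand$hcb,
             srd = ci_table$SRD[m], shgn = ci_table$SHGN[m])
}

#' Fit one crown-width form by nonlinear least squares
#'
#' Levenberg-Marquardt least squares (via \code{minpack.lm}) with
#' form-specific automatic starting values (exact linearizations where the
#' form permits). Non-convergence is reported as a state
#' (\code{converged = FALSE}), not an error, mirroring how screening tables
#' report failed candidates.
#'
#' @param form_id form id, see \code{\link{cw_form_ids}}.
#' @param data model frame with columns \code{cw}, \code{dbh} and, for form
#'   \code{"G"}, \code{th}, \code{hcb} and the competition index selected by
#'   \code{ci_kind}.
#' @param ci_kind which plot index feeds the \code{ci} covariate of form
#'   \code{"G"}: \code{"SRD"} (spatially non-explicit) or \code{"SHGN"}
#'   (spatially explicit).
#' @param start optional named list of starting values; default automatic.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return Object of class \code{cw_fit}: list with \code{form_id},
#'   \code{phi}, \code{converged}, \code{sigma2}, \code{logLik}, \code{aic},
#'   \code{n}, \code{ci_kind} and the underlying \code{nls} object
#'   (\code{fit}) when converged.
#' @export
fit_cw <- function(form_id, data, ci_kind = c("none", "SRD", "SHGN"),
                   start = NULL, max_iter = 500) {
  form_id <- match.arg(form_id, cw_form_ids())
  ci_kind <- match.arg(ci_kind)
  arity <- cw_form_arity(form_id)
  if (nrow(data) <= arity) {
    stop(sprintf("need more than %d observations to fit form %s",
                 arity, form_id))
  }
  data <- as.data.frame(data)
  if (form_id == "G") {
    if (ci_kind == "none") stop("form G requires ci_kind 'SRD' or 'SHGN'")
    col <- tolower(ci_kind)
    if (is.null(data[[col]])) stop("data lacks column ", col)
    data$ci <- data[[col]]
  }
  if (is.null(start)) start <- .cw_form_start(form_id, data)
  fit <- tryCatch(
    minpack.lm::nlsLM(.cw_form_formula(form_id), data = data, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(form_id = form_id, phi = unlist(start), converged = FALSE,
                sigma2 = NA_real_, logLik = NA_real_, aic = NA_real_,
                n = nrow(data), ci_kind = ci_kind, fit = NULL,
                message = conditionMessage(fit))
    class(out) <- "cw_fit"
    return(out)
  }
  rss <- sum(stats::residuals(fit)^2)
  ll <- as.numeric(stats::logLik(fit))
  out <- list(form_id = form_id, phi = stats::coef(fit), converged = TRUE,
              sigma2 = rss / nrow(data), logLik = ll,
              aic = -2 * ll + 2 * (arity + 1),  # +1 for sigma^2
              n = nrow(data), ci_kind = ci_kind, fit = fit, message = NULL)
  class(out) <- "cw_fit"
  out
}

#' @export
print.cw_fit <- function(x, ...) {
  cat(sprintf("Crown-width NLS fit, form %s (%s)\n", x$form_id,
              if (x$converged) "converged" else "did not converge"))
  if (x$converged) {
    cat("  phi: ", paste(sprintf("%.4g", x$phi), collapse = ", "), "\n")
    cat(sprintf("  n = %d, sigma2 = %.4g, AIC = %.1f\n",
                x$n, x$sigma2, x$aic))
  }
  invisible(x)
}

#' @export
predict.cw_fit <- function(object, newdata, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  ci <- NULL
  if (object$form_id == "G") {
    col <- tolower(object$ci_kind)
    ci <- if (!is.null(newdata$ci)) newdata$ci else newdata[[col]]
    if (is.null(ci)) stop("newdata lacks competition-index column ", col)
  }
  evaluate_form(object$form_id, unname(object$phi), d = newdata$dbh,
                th = newdata$th, hcb = newdata$hcb, ci = ci)
}

#' Fit and rank the twelve candidate CW-D forms
#'
#' Fits every candidate on the calibration set, evaluates each converged
#' fit on calibration (AIC, adjusted R^2, RMSE, MAE, MAPE) and validation
#' (adjusted R^2, RMSE, MAE, MAPE), and orders the table by calibration
#' AIC with non-converged forms last (their statistics are NA, rendered as
#' dashes in screening tables).
#'
#' @param calibration,validation model frames with \code{cw} and \code{dbh}.
#' @return Data frame with 12 rows and a \code{fits} attribute holding the
#'   \code{cw_fit} objects.
#' @export
rank_cw_candidates <- function(calibration, validation) {
  forms <- paste0("F", 1:12)
  fits <- lapply(forms, fit_cw, data = calibration)
  names(fits) <- forms
  rows <- lapply(fits, function(f) {
    if (!f$converged) {
      return(data.frame(form_id = f$form_id, converged = FALSE,
                        cal_aic = NA_real_, cal_r2_adj = NA_real_,
                        cal_rmse = NA_real_, cal_mae = NA_real_,
                        cal_mape = NA_real_, val_r2_adj = NA_real_,
                        val_rmse = NA_real_, val_mae = NA_real_,
                        val_mape = NA_real_))
    }
    p <- cw_form_arity(f$form_id)
    cal <- fit_stats(calibration$cw, predict(f, calibration), p = p,
                     loglik = f$logLik)
    val <- fit_stats(validation$cw, predict(f, validation), p = p)
    data.frame(form_id = f$form_id, converged = TRUE,
               cal_aic = f$aic, cal_r2_adj = cal$r2_adj,
               cal_rmse = cal$rmse, cal_mae = cal$mae, cal_mape = cal$mape,
               val_r2_adj = val$r2_adj, val_rmse = val$rmse,
               val_mae = val$mae, val_mape = val$mape)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$converged, out$cal_aic), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
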