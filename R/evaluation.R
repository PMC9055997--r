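#' Goodness-of-fit statistics
#'
#' The five screening statistics used throughout: AIC (from a supplied
#' log-likelihood, \code{-2 logLik + 2 p}), adjusted R^2
#' \deqn{R^2_a = 1 - \frac{n-1}{n-p-1} \frac{\sum (y_i - \hat y_i)^2}{\sum (y_i - \bar y)^2},}
#' RMSE, MAE and MAPE (reported as a fraction, not a percentage).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param p number of estimated parameters.
#' @param loglik optional log-likelihood; AIC is \code{NA} when absent.
#' @return One-row data frame with \code{aic}, \code{r2_adj}, \code{rmse},
#'   \code{mae}, \code{mape}, \code{n}, \code{p}. \code{mape} is \code{NA}
#'   (with a warning) when any observed value is zero; \code{r2_adj} is
#'   \code{NA} (with a warning) when \code{n <= p + 1} or the observed
#'   values are constant, since the adjusted formula is then undefined.
#' @export
fit_stats <- function(observed, predicted, p, loglik = NULL) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  res <- observed - predicted
  rss <- sum(res^2)
  tss <- sum((observed - mean(observed))^2)
  r2_adj <- if (n <= p + 1 || tss == 0) {
    warning("adjusted R^2 undefined for n <= p + 1 or constant observations")
    NA_real_
  } else {
    1 - (n - 1) / (n - p - 1) * rss / tss
  }
  mape <- if (any(observed == 0)) {
    warning("observed values of 0: MAPE undefined")
    NA_real_
  } else {
    mean(abs(res) / abs(observed))
  }
  data.frame(
    aic = if (is.null(loglik)) NA_real_ else -2 * loglik + 2 * p,
    r2_adj = r2_adj,
    rmse = sqrt(rss / n),
    mae = mean(abs(res)),
    mape = mape,
    n = n, p = p)
}

#' Standardized residuals of a fitted crown-width model
#'
#' Residuals divided by their modelled standard deviation: a single
#' \code{sigma} for homoscedastic NLS fits, and the fitted variance
#' function \code{sigma * g(dbh)} for mixed models (so, e.g., a power
#' variance fit divides by \code{sigma * dbh^(delta/2)}). Mixed-model
#' residuals are taken about the group-level (BLUP-adjusted) prediction.
#'
#' @param object a converged \code{cw_fit} or \code{cw_mixed}.
#' @param data model frame to evaluate on (for \code{cw_fit}, defaults to
#'   the fitting data is not retained, so it must be supplied).
#' @return Data frame with \code{fitted}, \code{residual},
#'   \code{std_residual}, \code{dbh}.
#' @export
standardized_residuals <- function(object, data) {
  data <- as.data.frame(data)
  if (inherits(object, "cw_fit")) {
    fitted <- predict(object, data)
    sd <- sqrt(object$sigma2)
    sds <- rep(sd, nrow(data))
  } else if (inherits(object, "cw_mixed")) {
    fitted <- predict_cw_mixed(object, data, level = "group")
    sds <- .varfn_sd(object$sigma2, object$varfn, data$dbh)
  } else {
    stop("object must be a cw_fit or cw_mixed")
  }
  res <- data$cw - fitted
  data.frame(fitted = fitted, residual = res, std_residual = res / sds,
             dbh = data$dbh)
}

#' Simulate crown-width-diameter curves across covariate levels
#'
#' Evaluates a fitted model over a DBH grid at several levels of one
#' covariate, the others held fixed -- the standard way of displaying how
#' competition, tree height or crown-base height bend the CW-D curve. The
#' default levels and held values follow the study convention: CI levels
#' 10, 50, 90, 130, 170, 210; TH levels 1, 6, 11, 16, 21, 26; HCB levels
#' 0, 5, 10, 15, 20, 25; held values TH = 25, CI = 45, HCB = 4.
#'
#' @param object a converged \code{cw_fit} (form \code{"G"}) or
#'   \code{cw_mixed} (population-level prediction).
#' @param vary which covariate the curves sweep: \code{"CI"}, \code{"TH"}
#'   or \code{"HCB"}.
#' @param levels numeric vector of levels for the varied covariate.
#' @param held named list of fixed values for the other covariates.
#' @param d DBH grid, cm.
#' @return Long data frame with \code{level}, \code{dbh}, \code{cw}; one
#'   row per level x grid point.
#' @export
simulate_cw_curves <- function(object, vary = c("CI", "TH", "HCB"),
                               levels = NULL,
                               held = list(th = 25, ci = 45, hcb = 4),
                               d = seq(1, 46.3, length.out = 100)) {
  vary <- match.arg(vary)
  if (is.null(levels)) {
    levels <- switch(vary,
                     CI = c(10, 50, 90, 130, 170, 210),
                     TH = c(1, 6, 11, 16, 21, 26),
                     HCB = c(0, 5, 10, 15, 20, 25))
  }
  predict_one <- function(ci, th, hcb) {
    nd <- data.frame(dbh = d, th = th, hcb = hcb, ci = ci)
    if (inherits(object, "cw_mixed")) {
      predict_cw_mixed(object, nd, level = "population")
    } else {
      predict(object, nd)
    }
  }
  rows <- lapply(levels, function(lv) {
    ci <- if (vary == "CI") lv else held$ci
    th <- if (vary == "TH") lv else held$th
    hcb <- if (vary == "HCB") lv else held$hcb
    data.frame(level = lv, dbh = d, cw = predict_one(ci, th, hcb))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear regression between the two selected competition indices
#'
#' Ordinary least squares of the distance-dependent index SHGN on the
#' distance-independent index SRD across plots, quantifying how well the
#' spatially explicit index is approximated by the spatially non-explicit
#' one.
#'
#' @param ci_table plot-level table with \code{SRD} and \code{SHGN}
#'   columns, see \code{\link{competition_indices}}.
#' @return List with \code{slope}, \code{intercept}, \code{r2},
#'   \code{p_value}, \code{n_plots}.
#' @export
cross_index_regression <- function(ci_table) {
  ci_table <- as.data.frame(ci_table)
  if (nrow(ci_table) < 3) stop("need at least 3 plots")
  if (stats::var(ci_table$SRD) == 0) {
    stop("SRD is constant across plots: regression degenerate")
  }
  fit <- stats::lm(SHGN ~ SRD, data = ci_table)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n_plots = nrow(ci_table))
}
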