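#' Run the full crown-width modelling pipeline
#'
#' Orchestrates the analysis end to end on one stem map: plot assignment,
#' calibration/validation split, competition indices, candidate CW-D
#' screening, the two generalized fits (SRD and SHGN), the mixed-effects
#' structure search for each, and evaluation tables. Every produced file
#' records the seed and a config hash; reruns with identical inputs and
#' config reproduce the same artifacts.
#'
#' The structure search is staged: the 31 random-effects subsets are
#' screened under the power variance function, then the winning subset is
#' refitted under each requested variance-function kind and the final model
#' taken by AIC.
#'
#' @param stand a \code{stem_map}, or a path readable by
#'   \code{\link{read_stem_map}}.
#' @param out_dir output directory (created if needed).
#' @param seed seed for the plot split.
#' @param fraction calibration fraction of plots.
#' @param radius,n_competitors,edge competition settings.
#' @param ci_kinds which generalized/mixed model families to fit.
#' @param varfn_kinds variance-function kinds tried for the final model.
#' @param search_structures random-effects subsets to screen; default all
#'   31.
#' @param verbose print stage progress.
#' @return The run manifest (named list), invisibly written to
#'   \code{manifest.json} in \code{out_dir} along with the artifact files.
#' @export
run_pipeline <- function(stand, out_dir, seed = 1, fraction = 0.8,
                         radius = 5, n_competitors = 4, edge = "torus",
                         ci_kinds = c("SRD", "SHGN"),
                         varfn_kinds = c("power", "exponential",
                                         "constant_plus_power"),
                         search_structures = enumerate_random_structures(5),
                         verbose = TRUE) {
  t0 <- Sys.time()
  if (is.character(stand)) stand <- read_stem_map(stand)
  stopifnot(inherits(stand, "stem_map"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- character(0)
  stages <- list()
  config <- list(seed = seed, fraction = fraction, radius = radius,
                 n_competitors = n_competitors, edge = edge,
                 ci_kinds = ci_kinds, varfn_kinds = varfn_kinds)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(cfg_path))
  emit <- function(name) artifacts <<- c(artifacts, name)
  emit("config.json")
  stamp <- function(df) {
    df$seed <- seed
    df$config_hash <- config_hash
    df
  }

  failed <- NULL
  result <- tryCatch({
    stand <- assign_plots(stand)
    write_stem_map(stand, file.path(out_dir, "stems.csv"))
    emit("stems.csv")
    stages$ingest <- list(n_trees = nrow(stand))
    say("ingest: %d trees", nrow(stand))

    ci_table <- competition_indices(stand, radius = radius,
                                    n_competitors = n_competitors,
                                    edge = edge)
    summaries <- plot_summaries(stand)
    plot_table <- merge(summaries, ci_table[, setdiff(names(ci_table),
                                                      c("grid_x", "grid_y"))],
                        by = "plot_id")
    utils::write.csv(stamp(plot_table),
                     file.path(out_dir, "plot_indices.csv"),
                     row.names = FALSE)
    emit("plot_indices.csv")
    stages$competition <- list(n_plots = nrow(ci_table))
    say("competition: %d occupied plots", nrow(ci_table))

    parts <- split_plots(stand, fraction = fraction, seed = seed)
    cal <- model_frame(parts$calibration, ci_table)
    val <- model_frame(parts$validation, ci_table)
    stages$split <- list(n_calibration_plots = length(parts$calibration_plots),
                         n_validation_plots = length(parts$validation_plots),
                         n_calibration_trees = nrow(cal),
                         n_validation_trees = nrow(val))
    say("split: %d/%d plots, %d/%d trees",
        length(parts$calibration_plots), length(parts$validation_plots),
        nrow(cal), nrow(val))

    candidates <- rank_cw_candidates(cal, val)
    utils::write.csv(stamp(candidates),
                     file.path(out_dir, "candidates.csv"), row.names = FALSE)
    emit("candidates.csv")
    basic <- attr(candidates, "fits")[[candidates$form_id[1]]]
    stages$candidates <- list(best_form = basic$form_id)
    say("candidates: best basic form %s", basic$form_id)

    model_json <- function(m, path) {
      obj <- list(kind = class(m)[1], seed = seed, config_hash = config_hash)
      if (inherits(m, "cw_fit")) {
        obj <- c(obj, list(form_id = m$form_id, ci_kind = m$ci_kind,
                           phi = as.list(m$phi), converged = m$converged,
                           sigma2 = m$sigma2, logLik = m$logLik,
                           aic = m$aic, n = m$n))
      } else {
        obj <- c(obj, list(ci_kind = m$ci_kind, random = m$random,
                           fixed = as.list(m$fixed),
                           psi = unclass(m$psi), sigma2 = m$sigma2,
                           varfn = m$varfn,
                           blups = as.data.frame(m$blups),
                           logLik = m$logLik, aic = m$aic,
                           n_params = m$n_params, n = m$n))
      }
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
    model_json(basic, file.path(out_dir, "model_basic.json"))
    emit("model_basic.json")

    stats_rows <- list()
    add_stats <- function(label, obs_cal, pred_cal, p, loglik,
                          obs_val, pred_val) {
      cal_s <- fit_stats(obs_cal, pred_cal, p, loglik)
      val_s <- fit_stats(obs_val, pred_val, p)
      stats_rows[[length(stats_rows) + 1L]] <<- cbind(
        data.frame(model = label),
        stats::setNames(cal_s[, 1:5], paste0("cal_", names(cal_s)[1:5])),
        stats::setNames(val_s[, 2:5], paste0("val_", names(val_s)[2:5])))
    }
    add_stats(paste0("basic_", basic$form_id), cal$cw, predict(basic, cal),
              cw_form_arity(basic$form_id), basic$logLik,
              val$cw, predict(basic, val))

    for (ck in ci_kinds) {
      gen <- fit_cw("G", cal, ci_kind = ck)
      model_json(gen, file.path(out_dir,
                                sprintf("model_generalized_%s.json", ck)))
      emit(sprintf("model_generalized_%s.json", ck))
      if (gen$converged) {
        add_stats(paste0("generalized_", ck), cal$cw, predict(gen, cal), 5,
                  gen$logLik, val$cw, predict(gen, val))
      }
      say("generalized (%s): %s", ck,
          if (gen$converged) sprintf("AIC %.1f", gen$aic) else "no convergence")

      search <- select_random_structure(cal, ci_kind = ck,
                                        varfn_kinds = "power",
                                        structures = search_structures,
                                        verbose = FALSE)
      utils::write.csv(stamp(search$report),
                       file.path(out_dir,
                                 sprintf("structure_search_%s.csv", ck)),
                       row.names = FALSE)
      emit(sprintf("structure_search_%s.csv", ck))
      if (!is.null(search$best)) {
        refits <- lapply(varfn_kinds, function(vf) {
          fit_cw_mixed(cal, ci_kind = ck, random = search$best$random,
                       varfn = vf)
        })
        ok <- Filter(function(m) m$converged, refits)
        mixed <- if (length(ok)) {
          ok[[which.min(vapply(ok, `[[`, numeric(1), "aic"))]]
        } else {
          search$best
        }
        model_json(mixed, file.path(out_dir,
                                    sprintf("model_mixed_%s.json", ck)))
        emit(sprintf("model_mixed_%s.json", ck))
        add_stats(paste0("mixed_", ck), cal$cw,
                  predict_cw_mixed(mixed, cal, level = "group"),
                  mixed$n_params, mixed$logLik, val$cw,
                  predict_cw_mixed(mixed, val, level = "population"))
        stages[[paste0("mixed_", ck)]] <- list(
          random = paste(mixed$random, collapse = "+"),
          varfn = mixed$varfn$kind, aic = mixed$aic)
        say("mixed (%s): random {%s}, varfn %s, AIC %.1f", ck,
            paste(mixed$random, collapse = ", "), mixed$varfn$kind,
            mixed$aic)
      } else {
        stages[[paste0("mixed_", ck)]] <- list(random = NA, varfn = NA,
                                               aic = NA)
      }
    }

    stats <- do.call(rbind, stats_rows)
    utils::write.csv(stamp(stats), file.path(out_dir, "fit_stats.csv"),
                     row.names = FALSE)
    emit("fit_stats.csv")

    xreg <- cross_index_regression(ci_table)
    stages$cross_index <- xreg
    say("cross-index: SHGN ~ SRD, R^2 = %.3f over %d plots",
        xreg$r2, xreg$n_plots)
    TRUE
  }, error = function(e) {
    failed <<- conditionMessage(e)
    FALSE
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("crownforge")),
    seed = seed, config_hash = config_hash, config = config,
    completed = isTRUE(result), failed_stage_message = failed,
    stages = stages, artifacts = artifacts,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
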