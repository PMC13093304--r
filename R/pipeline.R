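#' Pipeline configuration
#'
#' Collects every stage's options for an end-to-end run over a directory
#' of per-site daily CSVs. Defaults follow the detector and resistance
#' conventions documented in [detector_config()] and
#' [event_resistance()]; the boosted-tree stage fits both resistance
#' targets with the tuned hyperparameters.
#'
#' @param input_dir Directory of per-site FLUXNET-dialect daily CSVs
#'   (file name = site id).
#' @param site_table_path Site metadata CSV ([read_site_table()]).
#' @param output_dir Directory for result tables and the manifest.
#' @param detector A [detector_config()].
#' @param epsilon_ts Minimum soil-temperature contrast (degC).
#' @param rank_daily Percentile variant flag ([event_phase_profile()]).
#' @param trend_min_n Minimum annual series length for trend testing.
#' @param targets Resistance targets to model.
#' @param cv_k,seed Cross-validation folds and fold seed for the model.
#' @param variable_map Column-name overrides for [read_fluxnet_daily()].
#' @param min_model_rows Fewest valid events needed to fit the driver
#'   model (defaults to `2 * cv_k`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, site_table_path, output_dir,
                            detector = detector_config(), epsilon_ts = 0.5,
                            rank_daily = FALSE, trend_min_n = 4L,
                            targets = c("rt_nee", "rt_re"), cv_k = 5L,
                            seed = 1L,
                            variable_map = default_variable_map(),
                            min_model_rows = NULL) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  if (!file.exists(site_table_path)) {
    stop("site table does not exist: ", site_table_path)
  }
  structure(list(input_dir = input_dir,
                 site_table_path = site_table_path,
                 output_dir = output_dir, detector = detector,
                 epsilon_ts = epsilon_ts, rank_daily = rank_daily,
                 trend_min_n = as.integer(trend_min_n), targets = targets,
                 cv_k = as.integer(cv_k), seed = as.integer(seed),
                 variable_map = variable_map,
                 min_model_rows = min_model_rows %||% (2L * as.integer(cv_k))),
            class = "pipeline_config")
}

pipeline_log <- function(tag, ...) {
  message(sprintf("[ftcflux:%s] %s", tag, sprintf(...)))
}

#' Run the full freeze-thaw analysis pipeline
#'
#' For every readable site file: detect freeze-thaw events, profile the
#' nine variables around each event, compute event resistance, and build
#' annual series; then aggregate phase percentiles, summarise resistance
#' by plant functional type, test per-site trends (annual FTC days and
#' annual mean resistance), fit the boosted-tree driver model per target
#' and attribute it with exact Shapley values. All tables are written as
#' CSV plus a JSON manifest; identical inputs and config give identical
#' tables. Unreadable site files are skipped with a logged reason; zero
#' usable sites is an error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory tables (`events`,
#'   `profiles`, `profile_summary`, `resistance`, `pft_summary`,
#'   `trends`, `shap`, `models`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sites <- read_site_table(config$site_table_path)
  files <- list.files(config$input_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  files <- files[basename(files) != basename(config$site_table_path) &
                   !startsWith(basename(files), "truth_")]
  if (!length(files)) stop("no site files in ", config$input_dir)

  events <- list(); profiles <- list(); resistance <- list()
  annual <- list(); site_status <- list()
  for (f in files) {
    sid <- sub("\\.csv$", "", basename(f))
    series <- tryCatch(
      read_fluxnet_daily(f, site = sid, variable_map = config$variable_map),
      error = function(e) e)
    if (inherits(series, "error")) {
      pipeline_log("skip", "site %s unreadable: %s", sid,
                   conditionMessage(series))
      site_status[[sid]] <- list(status = "skipped",
                                 reason = conditionMessage(series))
      next
    }
    ev <- detect_events(series, config$detector)
    pipeline_log("detect", "site %s: %d events over %d days", sid,
                 nrow(ev), nrow(series))
    events[[sid]] <- ev
    if (nrow(ev)) {
      profiles[[sid]] <- site_phase_profiles(ev, series, config$detector,
                                             config$rank_daily)
      resistance[[sid]] <- site_resistance(ev, series, config$detector,
                                           config$epsilon_ts)
    }
    ann <- annual_ftc_days(ev, series$date)
    annual[[sid]] <- list(ftc_days = ann$per_year$ftc_days)
    site_status[[sid]] <- list(status = "ok", n_events = nrow(ev),
                               n_days = nrow(series))
  }
  if (!length(events)) stop("zero usable sites")

  all_events <- do.call(rbind, events)
  all_profiles <- if (length(profiles)) do.call(rbind, profiles) else NULL
  all_res <- if (length(resistance)) do.call(rbind, resistance) else NULL

  prof_summary <- if (!is.null(all_profiles) && nrow(all_profiles)) {
    aggregate_profiles(all_profiles)
  } else NULL
  pft <- if (!is.null(all_res)) pft_resistance(all_res, sites) else NULL

  # annual resistance series for trend testing
  if (!is.null(all_res)) {
    sm <- site_mean_resistance(all_res, all_events)
    for (sid in names(annual)) {
      sy <- sm$per_site_year[sm$per_site_year$site_id == sid, ]
      if (nrow(sy)) {
        sy <- sy[order(sy$year), ]
        annual[[sid]]$rt_nee <- sy$mean_rt_nee
        annual[[sid]]$rt_re <- sy$mean_rt_re
      }
    }
  }
  trend_tab <- site_trend_table(annual, min_n = config$trend_min_n)

  models <- list(); shap_tabs <- list()
  if (!is.null(all_res)) {
    for (target in config$targets) {
      ft <- build_feature_table(all_res, all_events, sites, target)
      if (nrow(ft) < config$min_model_rows) {
        pipeline_log("drivers", "target %s: only %d valid events (< %d); %s",
                     target, nrow(ft), config$min_model_rows,
                     "model stage skipped")
        next
      }
      fit <- fit_gbt(ft, cv_k = config$cv_k, seed = config$seed)
      sh <- model_shapley(fit, ft)
      sh$table$target <- target
      models[[target]] <- fit
      shap_tabs[[target]] <- sh
      pipeline_log("drivers", "target %s: R2(oof) = %.3f over %d events",
                   target, fit$metrics$r2, fit$n)
    }
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  fmt_dates <- function(df) {
    for (col in names(df)) if (inherits(df[[col]], "Date")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    df
  }
  write_table(fmt_dates(all_events), out("events.csv"))
  if (!is.null(all_profiles)) {
    write_table(all_profiles, out("profiles.csv"))
  }
  if (!is.null(prof_summary)) {
    write_table(prof_summary$overall, out("profile_summary.csv"))
  }
  if (!is.null(all_res)) write_table(all_res, out("resistance.csv"))
  if (!is.null(pft)) write_table(pft, out("pft_summary.csv"))
  write_table(trend_tab, out("trends.csv"))
  if (length(shap_tabs)) {
    write_table(do.call(rbind, lapply(shap_tabs, `[[`, "table")),
                out("shap.csv"))
  }
  model_meta <- lapply(models, function(m) {
    list(target = m$target_name, hyperparams = m$hyperparams,
         fixed_params = m$fixed_params, cv_k = m$cv_k, seed = m$seed,
         n = m$n, metrics = m$metrics, metrics_train = m$metrics_train)
  })
  if (length(model_meta)) {
    jsonlite::write_json(model_meta, out("model_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest <- list(
    config = list(input_dir = config$input_dir,
                  site_table = config$site_table_path,
                  detector = unclass(config$detector),
                  epsilon_ts = config$epsilon_ts,
                  rank_daily = config$rank_daily,
                  trend_min_n = config$trend_min_n,
                  targets = config$targets, cv_k = config$cv_k,
                  seed = config$seed),
    sites = site_status,
    rows = list(events = nrow(all_events),
                profiles = if (is.null(all_profiles)) 0L else nrow(all_profiles),
                resistance = if (is.null(all_res)) 0L else nrow(all_res),
                trends = nrow(trend_tab)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(events = all_events, profiles = all_profiles,
                 profile_summary = prof_summary, resistance = all_res,
                 pft_summary = pft, trends = trend_tab,
                 models = models, shap = shap_tabs, manifest = manifest))
}

#' Minimal phase-percentile summary plot
#'
#' Grouped barplot of mean percentile per variable and phase, a quick
#' visual check of how the meteorology and fluxes shift around events.
#'
#' @param profile_summary The `overall` table from [aggregate_profiles()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix plotted.
#' @export
plot_phase_profiles <- function(profile_summary, ...) {
  m <- with(profile_summary,
            tapply(mean_percentile, list(phase, variable), mean))
  m <- m[PHASES, , drop = FALSE]
  graphics::barplot(m, beside = TRUE, ylim = c(0, 100),
                    legend.text = rownames(m), ylab = "mean percentile",
                    ...)
  graphics::abline(h = 50, lty = 2)
  invisible(m)
}
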