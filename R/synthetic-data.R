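#' Configuration of the synthetic daily-series generator
#'
#' Describes one synthetic site: a seasonal shallow soil-temperature cycle
#' (cosine with winter minimum in mid-January) with stationary AR(1)
#' noise, a Q10 respiration response with multiplicative suppression while
#' the soil is frozen, a half-sine growing-season GPP gated by Ts > 0 (so
#' winter NEE is essentially RE), and ancillary meteorology as seasonally
#' modulated positive noise. Defaults sketch a boreal evergreen site with
#' a single long winter freeze per year.
#'
#' @param seed Integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @param n_years Number of simulated calendar years (>= 1).
#' @param ts_mean Annual mean soil temperature (degC).
#' @param ts_amplitude Seasonal half-range of the soil-temperature cosine
#'   (degC); 0 gives a flat series.
#' @param ar1_rho Lag-1 autocorrelation of the temperature noise, in
#'   \[0, 1).
#' @param noise_sd Stationary standard deviation of that noise in the
#'   warm season (degC). As the seasonal state approaches and falls below
#'   freezing the innovation scale is damped to
#'   `freeze_noise_damp * noise_sd` (linear ramp over the 0-4 degC band of
#'   the seasonal curve), emulating the zero-curtain effect: latent heat
#'   and snow insulation pin shallow soil temperature near 0 degC through
#'   the transitions and suppress its variability while frozen.
#' @param freeze_noise_damp Fraction of `noise_sd` retained at and below
#'   the freezing point, in (0, 1\].
#' @param q10 Respiration temperature sensitivity (> 0): RE multiplies by
#'   `q10` per 10 degC.
#' @param r_ref Reference respiration at 10 degC (umol CO2 m-2 s-1).
#' @param freeze_re_factor Multiplicative RE suppression while the
#'   seasonal soil state is frozen (deterministic curve below 0 degC), in
#'   \[0, 1\].
#' @param gpp_summer_max Midsummer GPP peak (umol CO2 m-2 s-1).
#' @param missing_frac Fraction of cells masked as missing, in \[0, 1);
#'   soil temperature and fluxes inside event-defining windows are never
#'   masked so the prescribed truth stays computable.
#' @param site_id Site identifier written into outputs.
#' @param start_year First simulated calendar year.
#' @param igbp,latitude,longitude,elevation,mat,map Site metadata carried
#'   into bundle site tables.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_years = 12L, ts_mean = 3,
                             ts_amplitude = 12, ar1_rho = 0.7,
                             noise_sd = 1.2, freeze_noise_damp = 0.15,
                             q10 = 2.5, r_ref = 2.5,
                             freeze_re_factor = 0.3, gpp_summer_max = 8,
                             missing_frac = 0.05, site_id = "SYN-001",
                             start_year = 2001L, igbp = "ENF",
                             latitude = 62, longitude = 25,
                             elevation = 200, mat = 3, map = 700) {
  cfg <- list(seed = as.integer(seed), n_years = as.integer(n_years),
              ts_mean = ts_mean, ts_amplitude = ts_amplitude,
              ar1_rho = ar1_rho, noise_sd = noise_sd,
              freeze_noise_damp = freeze_noise_damp, q10 = q10,
              r_ref = r_ref, freeze_re_factor = freeze_re_factor,
              gpp_summer_max = gpp_summer_max,
              missing_frac = missing_frac, site_id = site_id,
              start_year = as.integer(start_year), igbp = igbp,
              latitude = latitude, longitude = longitude,
              elevation = elevation, mat = mat, map = map)
  if (cfg$n_years < 1L) stop("n_years must be >= 1")
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) stop("ar1_rho must be in [0, 1)")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$freeze_noise_damp <= 0 || cfg$freeze_noise_damp > 1) {
    stop("freeze_noise_damp must be in (0, 1]")
  }
  if (cfg$q10 <= 0) stop("q10 must be > 0")
  if (cfg$freeze_re_factor < 0 || cfg$freeze_re_factor > 1) {
    stop("freeze_re_factor must be in [0, 1]")
  }
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    stop("missing_frac must be in [0, 1)")
  }
  if (!cfg$igbp %in% IGBP_CLASSES) stop("igbp must be one of ",
                                        paste(IGBP_CLASSES, collapse = ", "))
  structure(cfg, class = "synthetic_config")
}

# Deterministic seasonal soil-temperature curve: winter minimum on day 15.
seasonal_ts <- function(doy, ts_mean, ts_amplitude) {
  ts_mean - ts_amplitude * cos(2 * pi * (doy - 15) / 365.25)
}

gpp_curve <- function(doy, ts, gpp_summer_max) {
  f <- sin(pi * (doy - 105) / 183)
  f[doy < 105 | doy > 288] <- 0
  gpp_summer_max * pmax(0, f) * (ts > 0)
}

# Multiplicative suppression factor per day. The factor follows the
# *seasonal* frozen state (`frozen`): the bulk soil column freezes on the
# seasonal scale, and the day-to-day AR(1) component represents sensor
# and synoptic variability that does not flip the whole profile. Within
# each frozen run the suppression deepens linearly from ~1 to
# freeze_re_factor over `ramp` days — the soil column and its liquid
# water films freeze progressively, so respiration shuts down over days,
# not instantaneously.
freeze_suppression <- function(frozen, freeze_re_factor, ramp = 5L) {
  f <- rep(1, length(frozen))
  if (!any(frozen)) return(f)
  r <- rle(frozen)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  for (i in which(r$values)) {
    k <- seq_len(r$lengths[i])
    f[start[i]:end[i]] <- freeze_re_factor +
      (1 - freeze_re_factor) * pmax(0, 1 - k / ramp)
  }
  f
}

# Respiration responds to the realized temperature through Q10 and to the
# seasonal frozen state through the suppression factor.
respiration <- function(ts, suppression, q10, r_ref) {
  r_ref * q10^((ts - 10) / 10) * suppression
}

#' Generate a synthetic daily flux series with known truth
#'
#' Builds the series described by a [synthetic_config()] and, from the
#' noiseless construction, the ground truth downstream stages should
#' recover: the prescribed frozen runs and the true NEE/RE resistance
#' ratios (computed on the noiseless series with the default detector's
#' event and pre-event windows, averaged over prescribed events with a
#' complete pre-window).
#'
#' @param config A [synthetic_config()].
#' @return List with `series` (a [daily_series()]) and `truth`: a list of
#'   `events` (data frame `freeze_start`, `frozen_days`),
#'   `true_re_resistance`, `true_nee_resistance`, and the `config`.
#' @export
#' @examples
#' sim <- generate_daily_series(synthetic_config(seed = 7, n_years = 3))
#' sim$series
#' sim$truth$events
generate_daily_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31",
                               config$start_year + config$n_years - 1L)),
               by = "day")
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1

  ts0 <- seasonal_ts(doy, config$ts_mean, config$ts_amplitude)
  frozen0 <- ts0 < 0
  supp <- freeze_suppression(frozen0, config$freeze_re_factor)
  re0 <- respiration(ts0, supp, config$q10, config$r_ref)
  nee0 <- re0 - gpp_curve(doy, ts0, config$gpp_summer_max)

  out <- with_seed(config$seed, {
    e <- numeric(n)
    if (config$noise_sd > 0) {
      # zero-curtain damping: full innovation scale when the seasonal
      # state is 4 degC or warmer, freeze_noise_damp of it at/below 0
      damp <- config$freeze_noise_damp +
        (1 - config$freeze_noise_damp) * pmin(1, pmax(0, ts0 / 4))
      sd_t <- config$noise_sd * damp
      z <- stats::rnorm(n)
      e[1L] <- sd_t[1L] * z[1L]
      scale <- sqrt(1 - config$ar1_rho^2)
      for (t in seq_len(n)[-1L]) {
        e[t] <- config$ar1_rho * e[t - 1L] + scale * sd_t[t] * z[t]
      }
    }
    ts <- ts0 + e
    re <- respiration(ts, supp, config$q10, config$r_ref)
    gpp <- gpp_curve(doy, ts, config$gpp_summer_max)
    nee <- re - gpp
    ta <- ts + 2 + stats::rnorm(n, 0, 1.5)
    p <- round(stats::rexp(n, 1) * (1 + 0.5 * sin(2 * pi * doy / 365.25)), 2)
    rg <- pmax(5, 150 - 130 * cos(2 * pi * (doy - 15) / 365.25) +
                 stats::rnorm(n, 0, 20))
    vpd <- pmax(0.1, 4 + 3 * sin(2 * pi * (doy - 105) / 365.25) +
                  stats::rnorm(n, 0, 1))
    ws <- pmax(0.1, stats::rnorm(n, 3, 1))
    swc <- pmin(95, pmax(2, 30 + 8 * cos(2 * pi * (doy - 105) / 365.25) +
                           stats::rnorm(n, 0, 3)))
    masks <- lapply(FLUX_VARS, function(v) stats::runif(n) < config$missing_frac)
    names(masks) <- FLUX_VARS
    list(ts = ts, re = re, nee = nee, ta = ta, p = p, rg = rg, vpd = vpd,
         ws = ws, swc = swc, masks = masks)
  })

  # prescribed events and truth from the noiseless construction
  series0 <- daily_series(config$site_id, dates, ts = ts0, re = re0,
                          nee = nee0)
  dcfg <- detector_config()
  events0 <- detect_events(series0, dcfg)
  truth_events <- data.frame(freeze_start = events0$freeze_start,
                             frozen_days = events0$frozen_days)
  true_re <- NA_real_
  true_nee <- NA_real_
  if (nrow(events0)) {
    res0 <- site_resistance(events0, series0, dcfg, epsilon_ts = 0)
    res0 <- res0[res0$valid, , drop = FALSE]
    if (nrow(res0)) {
      true_re <- mean(res0$rt_re)
      true_nee <- mean(res0$rt_nee)
    }
  }

  # protect event-defining windows of ts/nee/re from masking
  protected <- rep(FALSE, n)
  if (nrow(events0)) {
    for (i in seq_len(nrow(events0))) {
      span <- seq(events0$freeze_start[i] - dcfg$pre_window,
                  events0$thaw_end[i] + dcfg$post_window, by = "day")
      protected[dates %in% span] <- TRUE
    }
  }
  vals <- list(ts = out$ts, re = out$re, nee = out$nee, ta = out$ta,
               p = out$p, rg = out$rg, vpd = out$vpd, ws = out$ws,
               swc = out$swc)
  for (v in FLUX_VARS) {
    m <- out$masks[[v]]
    if (v %in% c("ts", "nee", "re")) m <- m & !protected
    vals[[v]][m] <- NA_real_
  }

  series <- do.call(daily_series,
                    c(list(site_id = config$site_id, dates = dates), vals))
  list(series = series,
       truth = list(events = truth_events,
                    true_re_resistance = true_re,
                    true_nee_resistance = true_nee,
                    config = config))
}

#' Write a daily series in the FLUXNET daily dialect
#'
#' CSV with `TIMESTAMP` as YYYYMMDD, the [default_variable_map()] column
#' names, and `-9999` for missing cells, so that
#' [read_fluxnet_daily()] recovers the series exactly on non-missing
#' cells.
#'
#' @param series A [daily_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fluxnet_dialect <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  if (nrow(series) == 0L) stop("refusing to write an empty series")
  vmap <- default_variable_map()
  out <- data.frame(TIMESTAMP = format(series$date, "%Y%m%d"))
  for (v in FLUX_VARS) {
    x <- series[[v]]
    col <- formatC(x, digits = 15, format = "g")
    col[is.na(x)] <- as.character(FLUX_MISSING_SENTINEL)
    out[[vmap[[v]]]] <- col
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a ready-to-run bundle of synthetic sites
#'
#' Generates one FLUXNET-dialect CSV per configured site plus a site
#' metadata table and truth tables (prescribed events, true resistance),
#' yielding an input directory [run_pipeline()] can consume directly.
#'
#' @param configs List of [synthetic_config()]s with distinct `site_id`s.
#' @param dir Output directory (created if needed).
#' @return List with `dir`, `site_table` path, per-site `files`, and the
#'   `truth` list keyed by site.
#' @export
simulate_bundle <- function(configs, dir) {
  ids <- vapply(configs, function(cf) cf$site_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate site_id in configs: ", ids[anyDuplicated(ids)])
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  truth <- list()
  meta <- list()
  truth_rows <- list()
  for (cf in configs) {
    sim <- generate_daily_series(cf)
    f <- file.path(dir, paste0(cf$site_id, ".csv"))
    write_fluxnet_dialect(sim$series, f)
    files[cf$site_id] <- f
    truth[[cf$site_id]] <- sim$truth
    meta[[cf$site_id]] <- data.frame(
      site_id = cf$site_id, latitude = cf$latitude,
      longitude = cf$longitude, igbp = cf$igbp, elevation = cf$elevation,
      mat = cf$mat, map = cf$map, stringsAsFactors = FALSE)
    truth_rows[[cf$site_id]] <- data.frame(
      site_id = cf$site_id,
      n_events = nrow(sim$truth$events),
      true_re_resistance = sim$truth$true_re_resistance,
      true_nee_resistance = sim$truth$true_nee_resistance,
      stringsAsFactors = FALSE)
  }
  site_table <- file.path(dir, "site_table.csv")
  write_table(do.call(rbind, meta), site_table)
  write_table(do.call(rbind, truth_rows),
              file.path(dir, "truth_resistance.csv"))
  list(dir = dir, site_table = site_table, files = files, truth = truth)
}
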