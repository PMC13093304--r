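#' Event-level resistance of NEE and RE
#'
#' Quantifies how strongly the carbon fluxes respond to a freeze-thaw
#' perturbation. For one event the resistance of a flux F is
#' `Rt_F = (F_during - F_pre) / (Ts_during - Ts_pre)`, where `during`
#' averages the event span (freeze onset through thaw confirmation) and
#' `pre` averages the reference window immediately before freeze onset.
#' Units: umol CO2 m-2 s-1 per degC of soil cooling; magnitude near zero
#' means the flux barely responded.
#'
#' The ratios are withheld (`valid = FALSE`) when the soil-temperature
#' contrast `|delta_ts|` falls below `epsilon_ts`, when any window mean is
#' undefined, or when the pre-event window is truncated by the record
#' start (`pre_ok` flag from the detector).
#'
#' @param event One row of a [detect_events()] table.
#' @param series The site's [daily_series()].
#' @param config The [detector_config()] supplying the pre-window length.
#' @param epsilon_ts Minimum absolute soil-temperature contrast (degC)
#'   for a defined ratio; default 0.5.
#' @return One-row data frame: window means (`pre_nee`, `pre_re`,
#'   `pre_ts`, `nee_during`, `re_during`, `ts_during`), `delta_ts`,
#'   `rt_nee`, `rt_re`, `valid`.
#' @export
event_resistance <- function(event, series, config = detector_config(),
                             epsilon_ts = 0.5) {
  stopifnot(inherits(series, "daily_series"), nrow(event) == 1L)
  windows <- phase_window_dates(event, config)
  wmean <- function(v, dates) {
    x <- series[[v]][match(dates, series$date)]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }
  pre_nee <- wmean("nee", windows$pre)
  pre_re <- wmean("re", windows$pre)
  pre_ts <- wmean("ts", windows$pre)
  nee_during <- wmean("nee", windows$during)
  re_during <- wmean("re", windows$during)
  ts_during <- wmean("ts", windows$during)
  delta_ts <- ts_during - pre_ts

  valid <- isTRUE(event$pre_ok) &&
    !anyNA(c(pre_nee, pre_re, pre_ts, nee_during, re_during, ts_during)) &&
    is.finite(delta_ts) && abs(delta_ts) >= epsilon_ts
  rt_nee <- if (valid) (nee_during - pre_nee) / delta_ts else NA_real_
  rt_re <- if (valid) (re_during - pre_re) / delta_ts else NA_real_

  data.frame(site_id = event$site_id, event_id = event$event_id,
             pre_nee = pre_nee, pre_re = pre_re, pre_ts = pre_ts,
             nee_during = nee_during, re_during = re_during,
             ts_during = ts_during, delta_ts = delta_ts,
             rt_nee = rt_nee, rt_re = rt_re, valid = valid,
             stringsAsFactors = FALSE)
}

#' Resistance records for all events of a site
#' @param events Event table from [detect_events()].
#' @param series The matching [daily_series()].
#' @inheritParams event_resistance
#' @return Row-bound [event_resistance()] records (possibly zero rows).
#' @export
site_resistance <- function(events, series, config = detector_config(),
                            epsilon_ts = 0.5) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    event_resistance(events[i, , drop = FALSE], series, config, epsilon_ts)
  })
  if (!length(rows)) {
    return(data.frame(site_id = character(), event_id = character(),
                      pre_nee = numeric(), pre_re = numeric(),
                      pre_ts = numeric(), nee_during = numeric(),
                      re_during = numeric(), ts_during = numeric(),
                      delta_ts = numeric(), rt_nee = numeric(),
                      rt_re = numeric(), valid = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Site mean resistance
#'
#' Arithmetic means of the valid per-event ratios, per site overall and
#' per site-year (events keyed to the calendar year of freeze onset) —
#' the annual series feeds the trend analysis.
#'
#' @param records Row-bound [event_resistance()] records.
#' @param events The matching event table (supplies freeze-onset years).
#' @return List with `per_site` and `per_site_year` data frames; both
#'   empty (with a message) when no record is valid.
#' @export
site_mean_resistance <- function(records, events) {
  keep <- records[records$valid, , drop = FALSE]
  if (!nrow(keep)) {
    message("[ftcflux] no valid resistance records to average")
    return(list(per_site = data.frame(site_id = character(),
                                      mean_rt_nee = numeric(),
                                      mean_rt_re = numeric(),
                                      n_events = integer()),
                per_site_year = data.frame(site_id = character(),
                                           year = integer(),
                                           mean_rt_nee = numeric(),
                                           mean_rt_re = numeric(),
                                           n_events = integer())))
  }
  yr <- as.integer(format(
    events$freeze_start[match(keep$event_id, events$event_id)], "%Y"))
  summarise <- function(by) {
    m1 <- aggregate(keep$rt_nee, by = by, FUN = mean)
    m2 <- aggregate(keep$rt_re, by = by, FUN = mean)
    n <- aggregate(keep$rt_re, by = by, FUN = length)
    out <- m1
    names(out)[ncol(out)] <- "mean_rt_nee"
    out$mean_rt_re <- m2$x
    out$n_events <- n$x
    out
  }
  list(per_site = summarise(list(site_id = keep$site_id)),
       per_site_year = summarise(list(site_id = keep$site_id, year = yr)))
}

#' Resistance by plant functional type
#'
#' Pools all valid event records by the IGBP class of their site and
#' reports the class mean of both resistance ratios. Site means of means
#' are reported alongside for sensitivity, but the pooled estimate is
#' primary.
#'
#' @param records Row-bound [event_resistance()] records.
#' @param sites Site table from [read_site_table()].
#' @return Data frame: `igbp`, `mean_rt_nee`, `mean_rt_re`,
#'   `site_mean_rt_nee`, `site_mean_rt_re`, `n_events`, `n_sites`.
#' @export
pft_resistance <- function(records, sites) {
  keep <- records[records$valid, , drop = FALSE]
  idx <- match(keep$site_id, sites$site_id)
  if (anyNA(idx)) {
    stop("site_id not in site table: ",
         paste(unique(keep$site_id[is.na(idx)]), collapse = ", "))
  }
  if (!nrow(keep)) {
    return(data.frame(igbp = character(), mean_rt_nee = numeric(),
                      mean_rt_re = numeric(), site_mean_rt_nee = numeric(),
                      site_mean_rt_re = numeric(), n_events = integer(),
                      n_sites = integer()))
  }
  keep$igbp <- sites$igbp[idx]
  pooled_nee <- aggregate(keep$rt_nee, list(igbp = keep$igbp), mean)
  pooled_re <- aggregate(keep$rt_re, list(igbp = keep$igbp), mean)
  nev <- aggregate(keep$rt_re, list(igbp = keep$igbp), length)
  per_site <- aggregate(keep[, c("rt_nee", "rt_re")],
                        list(igbp = keep$igbp, site_id = keep$site_id), mean)
  sm_nee <- aggregate(per_site$rt_nee, list(igbp = per_site$igbp), mean)
  sm_re <- aggregate(per_site$rt_re, list(igbp = per_site$igbp), mean)
  nsite <- aggregate(per_site$site_id, list(igbp = per_site$igbp),
                     function(x) length(unique(x)))
  data.frame(igbp = pooled_nee$igbp,
             mean_rt_nee = pooled_nee$x,
             mean_rt_re = pooled_re$x,
             site_mean_rt_nee = sm_nee$x,
             site_mean_rt_re = sm_re$x,
             n_events = nev$x,
             n_sites = nsite$x,
             stringsAsFactors = FALSE)
}
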