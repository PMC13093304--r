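#' Percentile rank within a site record
#'
#' Mean-rank percentile of a value against all non-missing observations of
#' one variable at one site: `100 * (n_less + 0.5 * n_equal) / n`. Ties get
#' the midpoint, so a value equal to every record entry ranks 50.
#'
#' @param record Numeric vector of non-missing reference values.
#' @param value Numeric scalar (or vector; ranked elementwise).
#' @return Percentile(s) in \[0, 100\].
#' @export
#' @examples
#' percentile_rank(1:99, 50) # 50
percentile_rank <- function(record, value) {
  record <- record[!is.na(record)]
  if (!length(record)) stop("empty record: cannot rank")
  vapply(value, function(v) {
    if (is.na(v)) return(NA_real_)
    100 * (sum(record < v) + 0.5 * sum(record == v)) / length(record)
  }, numeric(1))
}

PHASES <- c("pre", "during", "post")

phase_window_dates <- function(event, config) {
  list(
    pre = seq(event$freeze_start - config$pre_window,
              event$freeze_start - 1, by = "day"),
    during = seq(event$freeze_start, event$thaw_end, by = "day"),
    post = seq(event$thaw_end + 1,
               event$thaw_end + config$post_window, by = "day"))
}

#' Percentile profile of one event
#'
#' For each of the nine canonical variables and each phase (the
#' `pre_window` days before freeze onset, the event span itself, and the
#' `post_window` days after thaw confirmation), computes the mean of the
#' non-missing daily values in the phase window and ranks it against the
#' site's whole monitoring record of that variable via [percentile_rank()].
#' Rows whose phase window holds no data are omitted.
#'
#' @param event One row of a [detect_events()] table.
#' @param series The site's [daily_series()].
#' @param config The [detector_config()] used for detection (supplies the
#'   window lengths).
#' @param rank_daily If `TRUE`, rank each daily value first and average the
#'   ranks, instead of ranking the window mean (sensitivity variant).
#' @return Data frame: `site_id`, `event_id`, `variable`, `phase`,
#'   `value`, `percentile`, `n_days`.
#' @export
event_phase_profile <- function(event, series, config = detector_config(),
                                rank_daily = FALSE) {
  stopifnot(inherits(series, "daily_series"), nrow(event) == 1L)
  if (event$thaw_end < series$date[1L] ||
      event$freeze_start > series$date[nrow(series)]) {
    stop("event lies entirely outside the record")
  }
  windows <- phase_window_dates(event, config)
  rows <- list()
  for (v in FLUX_VARS) {
    record <- series[[v]][!is.na(series[[v]])]
    if (!length(record)) next
    for (ph in PHASES) {
      x <- series[[v]][match(windows[[ph]], series$date)]
      x <- x[!is.na(x)]
      if (!length(x)) next
      if (rank_daily) {
        val <- mean(x)
        pct <- mean(percentile_rank(record, x))
      } else {
        val <- mean(x)
        pct <- percentile_rank(record, val)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = event$site_id, event_id = event$event_id,
        variable = v, phase = ph, value = val, percentile = pct,
        n_days = length(x), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(site_id = character(), event_id = character(),
                      variable = character(), phase = character(),
                      value = numeric(), percentile = numeric(),
                      n_days = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Profile every event of a site
#'
#' @param events Event table from [detect_events()].
#' @param series The matching [daily_series()].
#' @inheritParams event_phase_profile
#' @return Row-bound [event_phase_profile()] output.
#' @export
site_phase_profiles <- function(events, series, config = detector_config(),
                                rank_daily = FALSE) {
  out <- lapply(seq_len(nrow(events)), function(i) {
    event_phase_profile(events[i, , drop = FALSE], series, config, rank_daily)
  })
  if (!length(out)) return(event_phase_profile(events, series, config))
  do.call(rbind, out)
}

#' Aggregate phase percentiles across events
#'
#' Unweighted mean percentile per (variable, phase) over all contributing
#' events, plus the same breakdown per site.
#'
#' @param profiles Rows from [event_phase_profile()] across events/sites.
#' @return List with `overall` (variable, phase, mean_percentile,
#'   n_events) and `by_site` data frames.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(nrow(profiles) >= 1L)
  agg <- function(df, by) {
    res <- aggregate(df$percentile, by = by, FUN = mean)
    names(res)[ncol(res)] <- "mean_percentile"
    cnt <- aggregate(df$percentile, by = by, FUN = length)
    res$n_events <- cnt$x
    res
  }
  overall <- agg(profiles, list(variable = profiles$variable,
                                phase = profiles$phase))
  by_site <- agg(profiles, list(site_id = profiles$site_id,
                                variable = profiles$variable,
                                phase = profiles$phase))
  list(overall = overall[order(overall$variable, overall$phase), ],
       by_site = by_site[order(by_site$site_id, by_site$variable,
                               by_site$phase), ])
}
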