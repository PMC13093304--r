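#' Detector configuration
#'
#' Parameters of the rule-based freeze-thaw event detector. A freezing
#' period is a run of at least `freeze_run_min` consecutive days with daily
#' mean shallow soil temperature strictly below 0 degC; the event is
#' confirmed when the run is immediately followed by at least
#' `thaw_run_min` consecutive days above 0 degC. With both minima at the
#' default 5 days an event spans at least 10 days, which is also why the
#' pre/post comparison windows default to 10 days.
#'
#' @param freeze_run_min Minimum sub-zero run length (days, >= 1).
#' @param thaw_run_min Minimum super-zero confirmation run (days, >= 1).
#' @param pre_window Days immediately before freeze onset used as the
#'   reference window.
#' @param post_window Days immediately after thaw confirmation.
#' @param max_gap_days Longest run of missing soil-temperature days
#'   tolerated inside a freezing or thawing run (0 = any gap breaks the
#'   run). Tolerated gap days count as continuation, never as frozen days.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(freeze_run_min = 5L, thaw_run_min = 5L,
                            pre_window = 10L, post_window = 10L,
                            max_gap_days = 0L) {
  cfg <- list(freeze_run_min = as.integer(freeze_run_min),
              thaw_run_min = as.integer(thaw_run_min),
              pre_window = as.integer(pre_window),
              post_window = as.integer(post_window),
              max_gap_days = as.integer(max_gap_days))
  with(cfg, {
    if (freeze_run_min < 1L || thaw_run_min < 1L ||
        pre_window < 1L || post_window < 1L) {
      stop("run and window lengths must be >= 1 day")
    }
    if (max_gap_days < 0L) stop("max_gap_days must be >= 0")
  })
  structure(cfg, class = "detector_config")
}

# Day categories: F sub-zero, T super-zero, Z exactly 0 degC, M missing.
# Exactly-0 days are not-frozen (the freeze rule is strict <0) and also do
# not count towards thaw confirmation (strict >0).
ts_category <- function(ts) {
  cat <- rep("M", length(ts))
  cat[!is.na(ts) & ts < 0] <- "F"
  cat[!is.na(ts) & ts > 0] <- "T"
  cat[!is.na(ts) & ts == 0] <- "Z"
  cat
}

# Collapse day categories into maximal segments, absorbing missing runs of
# length <= max_gap into a flanking F or T segment when both neighbours
# share that category. Returns a data.frame of segments with start/end day
# indices, category, and the count of real (non-gap) days.
ts_segments <- function(cat, max_gap) {
  r <- rle(cat)
  k <- length(r$lengths)
  if (k == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      category = character(), real_days = integer()))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts, end = ends, category = r$values,
                    real_days = r$lengths, stringsAsFactors = FALSE)
  if (max_gap > 0L && k >= 3L) {
    merged <- seg[1L, , drop = FALSE]
    i <- 2L
    while (i <= nrow(seg)) {
      cur <- seg[i, ]
      last <- merged[nrow(merged), ]
      if (cur$category == "M" && cur$real_days <= max_gap &&
          i < nrow(seg) && last$category %in% c("F", "T") &&
          seg$category[i + 1L] == last$category) {
        # absorb the gap and the following same-category run
        merged$end[nrow(merged)] <- seg$end[i + 1L]
        merged$real_days[nrow(merged)] <-
          last$real_days + seg$real_days[i + 1L]
        i <- i + 2L
      } else {
        merged <- rbind(merged, cur)
        i <- i + 1L
      }
    }
    seg <- merged
  }
  seg
}

#' Classify the daily soil state
#'
#' Labels every day of a daily soil-temperature sequence as `frozen`
#' (member of a qualifying sub-zero run), `thawing` (one of the first
#' `thaw_run_min` super-zero days immediately following a qualifying
#' frozen run), `undetermined` (missing temperature) or `unfrozen`.
#'
#' @param ts Numeric vector of daily mean shallow soil temperature (degC),
#'   aligned to consecutive calendar days; `NA` = missing.
#' @param config A [detector_config()].
#' @return Character vector, one state per day.
#' @export
#' @examples
#' classify_soil_state(c(rep(-1, 7), rep(1, 7)))
classify_soil_state <- function(ts, config = detector_config()) {
  n <- length(ts)
  state <- rep("unfrozen", n)
  if (n == 0L) return(character())
  cat <- ts_category(ts)
  state[cat == "M"] <- "undetermined"
  seg <- ts_segments(cat, config$max_gap_days)
  frozen_idx <- which(seg$category == "F" &
                        seg$real_days >= config$freeze_run_min)
  for (i in frozen_idx) {
    days <- seg$start[i]:seg$end[i]
    state[days][cat[days] == "F"] <- "frozen"
    # thaw confirmation: the segment immediately after must be super-zero
    if (i < nrow(seg) && seg$category[i + 1L] == "T" &&
        seg$real_days[i + 1L] >= config$thaw_run_min) {
      tdays <- seg$start[i + 1L]:seg$end[i + 1L]
      tdays <- tdays[cat[tdays] == "T"][seq_len(config$thaw_run_min)]
      state[tdays] <- "thawing"
    }
  }
  state
}

#' Detect freeze-thaw events
#'
#' Scans one site's daily series for freeze-thaw events: a qualifying
#' sub-zero run in shallow soil temperature immediately followed by a
#' qualifying super-zero confirmation run. The event spans freeze onset
#' through the last day of the (capped) thaw-confirmation run.
#'
#' @param series A [daily_series()] with soil temperature `ts`.
#' @param config A [detector_config()].
#' @return Data frame with one row per event: `site_id`, `event_id`,
#'   `freeze_start`, `freeze_end` (last frozen day), `thaw_end` (last
#'   thaw-confirmation day), `duration` (days, inclusive), `frozen_days`
#'   (count of sub-zero days in the run), and `pre_ok` (whether the full
#'   pre-event window lies inside the record). Events are disjoint and
#'   chronological.
#' @export
detect_events <- function(series, config = detector_config()) {
  stopifnot(inherits(series, "daily_series"))
  empty <- data.frame(site_id = character(), event_id = character(),
                      freeze_start = as.Date(character()),
                      freeze_end = as.Date(character()),
                      thaw_end = as.Date(character()),
                      duration = integer(), frozen_days = integer(),
                      pre_ok = logical(), stringsAsFactors = FALSE)
  n <- nrow(series)
  if (n == 0L) return(empty)
  ts <- series$ts
  cat <- ts_category(ts)
  seg <- ts_segments(cat, config$max_gap_days)
  sid <- site_id(series)
  rows <- list()
  frozen_idx <- which(seg$category == "F" &
                        seg$real_days >= config$freeze_run_min)
  for (i in frozen_idx) {
    if (i >= nrow(seg) || seg$category[i + 1L] != "T" ||
        seg$real_days[i + 1L] < config$thaw_run_min) next
    fdays <- seg$start[i]:seg$end[i]
    fdays <- fdays[cat[fdays] == "F"]
    tdays <- seg$start[i + 1L]:seg$end[i + 1L]
    tdays <- tdays[cat[tdays] == "T"][seq_len(config$thaw_run_min)]
    freeze_start <- series$date[min(fdays)]
    thaw_end <- series$date[max(tdays)]
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sid,
      event_id = NA_character_,
      freeze_start = freeze_start,
      freeze_end = series$date[max(fdays)],
      thaw_end = thaw_end,
      duration = as.integer(thaw_end - freeze_start) + 1L,
      frozen_days = length(fdays),
      pre_ok = min(fdays) > config$pre_window,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$event_id <- sprintf("%s_%03d", sid, seq_len(nrow(out)))
  out
}

#' Annual freeze-thaw day statistics
#'
#' Allocates each event's days (freeze onset through thaw confirmation,
#' inclusive) to calendar years — events straddling New Year contribute to
#' both — and summarises the site mean as total event days divided by the
#' number of observed years.
#'
#' @param events Event table from [detect_events()] (one site).
#' @param series_span `Date` vector (e.g. `series$date`) giving the
#'   observed record; only its range matters.
#' @return List with `per_year` (data frame `year`, `ftc_days`, covering
#'   every observed calendar year) and `mean_days_per_year`.
#' @export
annual_ftc_days <- function(events, series_span) {
  series_span <- as.Date(series_span)
  if (length(series_span) == 0L) stop("zero-length series span")
  years <- seq(as.integer(format(min(series_span), "%Y")),
               as.integer(format(max(series_span), "%Y")))
  counts <- rep(0L, length(years))
  names(counts) <- years
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev_days <- seq(events$freeze_start[i], events$thaw_end[i], by = "day")
      tab <- table(format(ev_days, "%Y"))
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  list(per_year = data.frame(year = years, ftc_days = as.integer(counts),
                             row.names = NULL),
       mean_days_per_year = sum(counts) / length(years))
}
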