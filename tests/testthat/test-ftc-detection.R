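test_that("soil-state labels follow the run rules on literal sequences", {
  expect_identical(unique(classify_soil_state(rep(5, 30))), "unfrozen")

  st <- classify_soil_state(c(rep(-1, 7), rep(1, 7)))
  expect_identical(st[1:7], rep("frozen", 7))
  expect_identical(st[8:12], rep("thawing", 5))
  expect_identical(st[13:14], rep("unfrozen", 2))

  # a 3-day cold snap is below the 5-day freeze minimum
  st2 <- classify_soil_state(c(rep(2, 5), rep(-1, 3), rep(2, 5)))
  expect_false(any(st2 == "frozen"))

  expect_identical(classify_soil_state(numeric(0)), character(0))
  expect_identical(classify_soil_state(c(NA, 1, NA))[c(1, 3)],
                   rep("undetermined", 2))
})

test_that("exactly 0 degC counts as not-frozen and breaks a freezing run", {
  st <- classify_soil_state(c(rep(-1, 4), 0, rep(-1, 4), rep(1, 6)))
  expect_false(any(st == "frozen")) # two 4-day runs, neither qualifies
  ev <- detect_events(make_ts_series(c(rep(-1, 4), 0, rep(-1, 4), rep(1, 6))))
  expect_identical(nrow(ev), 0L)
})

test_that("detect_events finds the expected events on constructed series", {
  expect_identical(nrow(detect_events(make_ts_series(rep(5, 40)))), 0L)

  s <- make_ts_series(c(rep(-2, 20), rep(2, 20)))
  ev <- detect_events(s)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$frozen_days, 20L)
  expect_identical(ev$duration, 25L) # 20 frozen + 5 thaw-confirmation days
  expect_equal(ev$freeze_start, s$date[1])
  expect_equal(ev$thaw_end, s$date[25])
  expect_false(ev$pre_ok) # record starts frozen

  s2 <- make_ts_series(c(rep(2, 15), rep(-1, 10), rep(1, 6), rep(-1, 10),
                         rep(1, 8)))
  ev2 <- detect_events(s2)
  expect_identical(nrow(ev2), 2L)
  expect_true(ev2$pre_ok[1])
  expect_true(all(diff(ev2$freeze_start) > 0))
})

test_that("a frozen run at record end without thaw confirmation emits no event", {
  ev <- detect_events(make_ts_series(c(rep(2, 15), rep(-3, 30))))
  expect_identical(nrow(ev), 0L)
  # thaw run too short at record end
  ev2 <- detect_events(make_ts_series(c(rep(2, 15), rep(-3, 10), rep(1, 3))))
  expect_identical(nrow(ev2), 0L)
})

test_that("missing days break runs by default and are tolerated with max_gap_days", {
  ts <- c(rep(1, 10), rep(-1, 4), NA, rep(-1, 4), rep(1, 6))
  expect_identical(nrow(detect_events(make_ts_series(ts))), 0L)

  cfg <- detector_config(max_gap_days = 1L)
  ev <- detect_events(make_ts_series(ts), cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$frozen_days, 8L) # the gap day is not a frozen day
  expect_identical(ev$duration, 14L)   # 9-day freeze span (incl. gap) + 5 thaw
  st <- classify_soil_state(ts, cfg)
  expect_identical(st[15], "undetermined")
  expect_identical(sum(st == "frozen"), 8L)

  # a 2-day gap still breaks the run at max_gap_days = 1
  ts2 <- c(rep(1, 10), rep(-1, 4), NA, NA, rep(-1, 4), rep(1, 6))
  expect_identical(nrow(detect_events(make_ts_series(ts2), cfg)), 0L)
})

test_that("detector agrees with the brute-force oracle on random sequences", {
  set.seed(101)
  for (rep in 1:200) {
    ts <- random_ts_sequence(200L)
    s <- make_ts_series(ts)
    ev <- detect_events(s)
    expected <- oracle_detect(ts)
    expect_identical(nrow(ev), nrow(expected))
    if (nrow(ev)) {
      expect_identical(as.integer(ev$freeze_start - s$date[1] + 1),
                       unname(expected[, "freeze_start"]))
      expect_identical(as.integer(ev$thaw_end - s$date[1] + 1),
                       unname(expected[, "thaw_end"]))
      expect_identical(ev$frozen_days, unname(expected[, "frozen_days"]))
    }
  }
})

test_that("detection is a pure threshold rule: warming positives or chilling negatives changes nothing", {
  set.seed(202)
  for (rep in 1:25) {
    ts <- random_ts_sequence(150L)
    pos <- !is.na(ts) & ts > 0
    neg <- !is.na(ts) & ts < 0
    ts2 <- ts
    ts2[pos] <- ts2[pos] + 7           # constant warming of thawed days
    ts2[neg] <- ts2[neg] - runif(sum(neg), 0, 5) # arbitrary extra chill
    a <- detect_events(make_ts_series(ts))
    b <- detect_events(make_ts_series(ts2))
    expect_identical(a, b)
  }
})

test_that("events are disjoint and frozen days are conserved across labels", {
  set.seed(303)
  for (rep in 1:40) {
    ts <- random_ts_sequence(300L)
    s <- make_ts_series(ts)
    ev <- detect_events(s)
    st <- classify_soil_state(ts)
    if (nrow(ev) > 1) {
      expect_true(all(ev$freeze_start[-1] > ev$thaw_end[-nrow(ev)]))
    }
    # every event's frozen days carry the frozen label
    ev_frozen <- sum(ev$frozen_days)
    labeled <- sum(st == "frozen")
    expect_lte(ev_frozen, labeled) # unconfirmed runs are labeled too
    for (i in seq_len(nrow(ev))) {
      idx <- which(s$date >= ev$freeze_start[i] & s$date <= ev$freeze_end[i])
      expect_identical(sum(st[idx] == "frozen"), ev$frozen_days[i])
    }
  }
})

test_that("annual FTC day allocation splits events across calendar years", {
  span10 <- seq(as.Date("2001-01-01"), as.Date("2010-12-31"), by = "day")
  none <- detect_events(make_ts_series(rep(5, 40)))
  expect_equal(annual_ftc_days(none, span10)$mean_days_per_year, 0)

  # one 25-day event fully inside each of two years
  ev <- data.frame(site_id = "TST", event_id = c("e1", "e2"),
                   freeze_start = as.Date(c("2001-02-01", "2002-02-01")),
                   freeze_end = as.Date(c("2001-02-20", "2002-02-20")),
                   thaw_end = as.Date(c("2001-02-25", "2002-02-25")),
                   duration = c(25L, 25L), frozen_days = c(20L, 20L),
                   pre_ok = TRUE)
  span2 <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  out <- annual_ftc_days(ev, span2)
  expect_equal(out$mean_days_per_year, 25)
  expect_equal(out$per_year$ftc_days, c(25L, 25L))

  # event straddling New Year: 10 December days + 15 January days
  ev3 <- data.frame(site_id = "TST", event_id = "e3",
                    freeze_start = as.Date("2001-12-22"),
                    freeze_end = as.Date("2002-01-10"),
                    thaw_end = as.Date("2002-01-15"),
                    duration = 25L, frozen_days = 20L, pre_ok = TRUE)
  out3 <- annual_ftc_days(ev3, span2)
  expect_equal(out3$per_year$ftc_days, c(10L, 15L))
  expect_equal(out3$mean_days_per_year, 12.5)

  expect_error(annual_ftc_days(ev, as.Date(character())), "span")
})

test_that("detector configuration rejects nonsensical values", {
  expect_error(detector_config(freeze_run_min = 0), ">= 1")
  expect_error(detector_config(max_gap_days = -1), "max_gap_days")
})
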