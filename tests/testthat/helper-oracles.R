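# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package: plain day-by-day and
# pair-by-pair scans.

# Wrap a temperature vector in a daily series starting at `start`.
make_ts_series <- function(ts, start = as.Date("2000-01-01"),
                           site = "TST") {
  daily_series(site, seq(start, by = "day", length.out = length(ts)),
               ts = ts)
}

# Brute-force freeze-thaw scan (gap-free rules, max_gap_days = 0):
# enumerate maximal strictly-sub-zero runs by walking the vector; an event
# needs freeze_min frozen days followed immediately by thaw_min days > 0.
oracle_detect <- function(ts, freeze_min = 5L, thaw_min = 5L) {
  n <- length(ts)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (!is.na(ts[i]) && ts[i] < 0) {
      j <- i
      while (j < n && !is.na(ts[j + 1L]) && ts[j + 1L] < 0) j <- j + 1L
      if (j - i + 1L >= freeze_min) {
        # thaw confirmation: the next thaw_min days all present and > 0
        k <- j + thaw_min
        ok <- k <= n && all(!is.na(ts[(j + 1L):k]) & ts[(j + 1L):k] > 0)
        if (ok) {
          events[[length(events) + 1L]] <-
            c(freeze_start = i, freeze_end = j, thaw_end = k,
              frozen_days = j - i + 1L)
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(events)) {
    return(matrix(integer(), ncol = 4,
                  dimnames = list(NULL, c("freeze_start", "freeze_end",
                                          "thaw_end", "frozen_days"))))
  }
  do.call(rbind, events)
}

# O(n^2) Mann-Kendall: explicit pair loops for S, explicit tie groups.
oracle_mk <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- s + sign(x[j] - x[i])
    }
  }
  tie_term <- 0
  for (u in unique(x)) {
    t <- sum(x == u)
    if (t > 1) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s)
       else 0
  list(s = s, var_s = var_s, z = z)
}

# Permutation-average Shapley oracle: mean marginal contribution of each
# feature over all |N|! orderings, with v() evaluated the same
# interventional way (instance values on the coalition, background
# elsewhere).
oracle_perm_shapley <- function(predictor, background, instance,
                                features = names(background)) {
  n <- length(features)
  v_of <- function(coal) {
    rows <- background
    for (f in coal) rows[[f]] <- rep(instance[[f]], nrow(rows))
    mean(predictor(rows))
  }
  cache <- new.env()
  v_cached <- function(coal) {
    key <- paste0("k:", paste(sort(coal), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- v_of(coal)
    cache[[key]]
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  phi <- numeric(n)
  names(phi) <- features
  all_perms <- perms(features)
  for (p in all_perms) {
    prev <- character(0)
    for (f in p) {
      phi[f] <- phi[f] + v_cached(c(prev, f)) - v_cached(prev)
      prev <- c(prev, f)
    }
  }
  phi / length(all_perms)
}

# Random temperature sequence generator for detector stress tests:
# alternating warm/cold stretches with occasional gaps and exact zeros.
random_ts_sequence <- function(max_len = 400L) {
  n <- sample.int(max_len, 1L)
  ts <- numeric(0)
  while (length(ts) < n) {
    run <- sample.int(12L, 1L)
    sgn <- sample(c(-1, 1), 1L)
    ts <- c(ts, sgn * stats::runif(run, 0, 5))
  }
  ts <- ts[seq_len(n)]
  ts[stats::runif(n) < 0.05] <- NA
  ts[stats::runif(n) < 0.02] <- 0
  ts
}

# Random but structured driver tables for model tests.
random_feature_table <- function(n, target_fun, noise_sd = 0) {
  tab <- data.frame(
    event_id = sprintf("e%04d", seq_len(n)),
    site_id = "S",
    duration = sample(10:180, n, replace = TRUE),
    elevation = runif(n, 0, 3000),
    mat = runif(n, -2, 15),
    map = runif(n, 400, 1300),
    igbp = factor(sample(c("DBF", "ENF", "MF", "GRA", "CRO"), n, TRUE),
                  levels = c("DBF", "ENF", "MF", "GRA", "CRO")),
    stringsAsFactors = FALSE)
  tab$target <- target_fun(tab) + rnorm(n, 0, noise_sd)
  attr(tab, "target_name") <- "rt_re"
  tab
}
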