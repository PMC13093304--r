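#' Mann-Kendall trend test
#'
#' Nonparametric trend test for annual series (FTC days per year, annual
#' mean resistance). The statistic is `S = sum_{i<j} sign(x_j - x_i)`; its
#' null variance carries the standard tie correction
#' `var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie groups of
#' size t, and the normal deviate uses the continuity correction:
#' `z = (S - 1)/sqrt(var)` for positive S, 0 at S = 0, `(S + 1)/sqrt(var)`
#' for negative S. Sen's median pairwise slope is reported as an effect
#' size alongside.
#'
#' Series shorter than `min_n` non-missing values are not tested: short
#' event records preclude a robust trend call, so the result is withheld
#' with a reason instead.
#'
#' @param x Numeric vector (annual values, `NA` allowed and dropped).
#' @param min_n Minimum non-missing length to attempt the test (default 4).
#' @return An object of class `mk_trend`: list with `n`, `s`, `var_s`,
#'   `z`, `p_two_sided`, `sen_slope`, `klass` (see [classify_trend()]),
#'   `status` (`"tested"` or `"withheld"`) and `reason`.
#' @export
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10))
mann_kendall <- function(x, min_n = 4L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < min_n) {
    return(structure(list(n = n, s = NA_integer_, var_s = NA_real_,
                          z = NA_real_, p_two_sided = NA_real_,
                          sen_slope = NA_real_, klass = NA_character_,
                          status = "withheld",
                          reason = sprintf("only %d value(s); need >= %d",
                                           n, min_n)),
                     class = "mk_trend"))
  }
  d <- outer(x, x, "-")          # d[i, j] = x[i] - x[j]
  s <- sum(sign(d[lower.tri(d)]))  # lower triangle: i > j, i.e. later - earlier
  ties <- table(x)
  t <- as.numeric(ties[ties > 1])
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s)
       else 0
  idx <- which(lower.tri(d), arr.ind = TRUE)
  slopes <- d[lower.tri(d)] / (idx[, 1L] - idx[, 2L])
  structure(list(n = n, s = as.integer(s), var_s = var_s, z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z)),
                 sen_slope = stats::median(slopes),
                 klass = classify_trend(z), status = "tested",
                 reason = NA_character_),
            class = "mk_trend")
}

#' @export
print.mk_trend <- function(x, ...) {
  if (x$status == "withheld") {
    cat("Mann-Kendall trend test: withheld (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Mann-Kendall trend test (n = %d)\n", x$n))
  cat(sprintf("  S = %d, var(S) = %.4g, Z = %.4f, p = %.4g\n",
              x$s, x$var_s, x$z, x$p_two_sided))
  cat(sprintf("  Sen slope = %.4g per step; class: %s\n",
              x$sen_slope, x$klass))
  invisible(x)
}

#' Three-way trend classification
#'
#' Classifies a Mann-Kendall normal deviate at the two-sided 5% level:
#' `significant_decrease` for Z < -1.96, `significant_increase` for
#' Z > 1.96, otherwise `no_significant_change` (the boundaries themselves
#' are not significant).
#'
#' @param z Finite normal deviate(s).
#' @return Character vector of classes.
#' @export
classify_trend <- function(z) {
  stopifnot(all(is.finite(z)))
  ifelse(z < -1.96, "significant_decrease",
         ifelse(z > 1.96, "significant_increase", "no_significant_change"))
}

#' Per-site trend table
#'
#' Runs [mann_kendall()] on each annual metric series of each site and
#' stacks the results, keeping withheld rows (with their reason) so the
#' output enumerates every site x metric pair.
#'
#' @param annual_series Named list: `annual_series[[site]][[metric]]` is a
#'   numeric annual series.
#' @param min_n Passed to [mann_kendall()].
#' @return Data frame: `site_id`, `metric`, `n`, `s`, `var_s`, `z`, `p`,
#'   `sen_slope`, `klass`, `status`, `reason`.
#' @export
site_trend_table <- function(annual_series, min_n = 4L) {
  rows <- list()
  for (sid in names(annual_series)) {
    for (metric in names(annual_series[[sid]])) {
      r <- mann_kendall(annual_series[[sid]][[metric]], min_n = min_n)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sid, metric = metric, n = r$n, s = r$s, var_s = r$var_s,
        z = r$z, p = r$p_two_sided, sen_slope = r$sen_slope,
        klass = r$klass, status = r$status, reason = r$reason,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(site_id = character(), metric = character(),
                      n = integer(), s = integer(), var_s = numeric(),
                      z = numeric(), p = numeric(), sen_slope = numeric(),
                      klass = character(), status = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
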