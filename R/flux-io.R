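# Canonical daily variables (FLUXNET2015-style daily product, 9 variables).
FLUX_VARS <- c("ta", "p", "rg", "vpd", "ws", "swc", "ts", "nee", "re")

# IGBP plant functional types covered by the site network.
IGBP_CLASSES <- c("DBF", "ENF", "MF", "GRA", "CRO")

FLUX_MISSING_SENTINEL <- -9999

#' Default FLUXNET2015 column mapping
#'
#' Maps the nine canonical daily variables onto FLUXNET2015 FULLSET daily
#' column names. Gap-filled meteorology (`_F`), the shallowest (~5 cm) soil
#' sensor (`_1` depth suffix), the variable-USTAR-threshold reference NEE,
#' and daytime-partitioned ecosystem respiration are used by default; any
#' entry can be overridden via the `variable_map` argument of
#' [read_fluxnet_daily()].
#'
#' @return Named character vector: canonical name -> file column name.
#' @export
#' @examples
#' default_variable_map()
default_variable_map <- function() {
  c(ta  = "TA_F",
    p   = "P_F",
    rg  = "SW_IN_F",
    vpd = "VPD_F",
    ws  = "WS_F",
    swc = "SWC_F_MDS_1",
    ts  = "TS_F_MDS_1",
    nee = "NEE_VUT_REF",
    re  = "RECO_DT_VUT_REF")
}

#' Construct a daily flux series
#'
#' Builds the package's canonical per-site container: a data frame with a
#' `date` column (consecutive calendar days) and the nine canonical
#' variables (`ta`, `p`, `rg`, `vpd`, `ws`, `swc`, `ts`, `nee`, `re`),
#' missing values as `NA`. Calendar gaps in `dates` are filled with
#' all-missing rows so the result always has a strict daily step.
#'
#' @param site_id Site identifier, e.g. `"FI-Sod"`.
#' @param dates `Date` vector (strictly increasing, no duplicates).
#' @param ... Numeric vectors named after canonical variables, each the
#'   length of `dates`. Omitted variables are all-`NA`.
#' @return A `daily_series` (data frame) with attribute `site_id`.
#' @export
daily_series <- function(site_id, dates, ...) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("dates must parse to valid calendar days")
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be strictly increasing with no duplicates")
  }
  vars <- list(...)
  bad <- setdiff(names(vars), FLUX_VARS)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  n <- length(dates)
  for (v in names(vars)) {
    if (length(vars[[v]]) != n) stop("variable ", v, " has wrong length")
  }

  if (n > 0L) {
    full <- seq(dates[1L], dates[n], by = "day")
  } else {
    full <- dates
  }
  idx <- match(full, dates)
  df <- data.frame(date = full)
  for (v in FLUX_VARS) {
    col <- if (v %in% names(vars)) as.numeric(vars[[v]])[idx] else rep(NA_real_, length(full))
    df[[v]] <- col
  }
  swc_bad <- !is.na(df$swc) & (df$swc < 0 | df$swc > 100)
  if (any(swc_bad)) stop("swc outside [0, 100] on ", sum(swc_bad), " day(s)")
  structure(df, site_id = site_id, class = c("daily_series", "data.frame"))
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> site %s: %d days", attr(x, "site_id"), nrow(x)))
  if (nrow(x)) cat(sprintf(" (%s to %s)", format(x$date[1L]), format(x$date[nrow(x)])))
  cat("\n")
  miss <- vapply(FLUX_VARS, function(v) mean(is.na(x[[v]])), numeric(1))
  cat("missing fraction:\n")
  print(round(miss, 3))
  invisible(x)
}

#' @export
summary.daily_series <- function(object, ...) {
  summary(as.data.frame(object)[FLUX_VARS], ...)
}

#' Site identifier of a daily series
#' @param series A `daily_series`.
#' @return Character scalar.
#' @export
site_id <- function(series) attr(series, "site_id")

#' Read a FLUXNET2015-style daily CSV
#'
#' Parses one site's daily product into the canonical [daily_series()]
#' container. The `TIMESTAMP` column (YYYYMMDD) is mandatory; `-9999` and
#' any cell that fails numeric parsing become missing; calendar gaps are
#' filled with all-missing rows so dates are consecutive. A canonical
#' variable whose mapped column is absent from the file is returned
#' all-missing with a warning.
#'
#' @param path CSV file path.
#' @param site Site identifier to attach; defaults to the file name minus
#'   extension.
#' @param variable_map Named character vector overriding entries of
#'   [default_variable_map()].
#' @return A `daily_series`.
#' @export
read_fluxnet_daily <- function(path, site = NULL,
                               variable_map = default_variable_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  vmap <- default_variable_map()
  vmap[names(variable_map)] <- variable_map
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (!"TIMESTAMP" %in% names(raw)) {
    stop("TIMESTAMP column missing in ", path)
  }
  if (is.null(site)) site <- sub("\\.[^.]*$", "", basename(path))
  if (nrow(raw) == 0L) {
    return(daily_series(site, as.Date(character())))
  }
  dates <- as.Date(raw$TIMESTAMP, format = "%Y%m%d")
  if (anyNA(dates)) stop("unparseable TIMESTAMP values in ", path)
  ord <- order(dates)
  dates <- dates[ord]
  if (anyDuplicated(dates)) stop("duplicate TIMESTAMP values in ", path)

  vals <- list()
  for (v in FLUX_VARS) {
    col <- vmap[[v]]
    if (!col %in% names(raw)) {
      warning("[ftcflux] variable ", v, " (column ", col, ") not in ", path,
              "; returned all-missing", call. = FALSE)
      vals[[v]] <- rep(NA_real_, length(dates))
    } else {
      x <- suppressWarnings(as.numeric(raw[[col]][ord]))
      x[!is.na(x) & x == FLUX_MISSING_SENTINEL] <- NA_real_
      vals[[v]] <- x
    }
  }
  do.call(daily_series, c(list(site_id = site, dates = dates), vals))
}

#' Read the site-metadata table
#'
#' Reads a delimited table of flux-tower metadata: one row per site with
#' identifier, coordinates, IGBP vegetation class (one of DBF, ENF, MF,
#' GRA, CRO), elevation (m), mean annual temperature MAT (degC) and mean
#' annual precipitation MAP (mm). The 24-tower network the package was
#' developed around ships as a fixture; see the example.
#'
#' @param path CSV path with header columns `site_id`, `latitude`,
#'   `longitude`, `igbp`, `elevation`, `mat`, `map`.
#' @return Data frame of validated site records.
#' @export
#' @examples
#' sites <- read_site_table(system.file("extdata", "site_table.csv",
#'                                      package = "ftcflux"))
#' head(sites)
read_site_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, strip.white = TRUE, stringsAsFactors = FALSE)
  need <- c("site_id", "latitude", "longitude", "igbp", "elevation", "mat", "map")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(df[, need])
  bad <- which(!df$igbp %in% IGBP_CLASSES)
  if (length(bad)) {
    stop("unknown IGBP code '", df$igbp[bad[1L]], "' in row ", bad[1L],
         " (site ", df$site_id[bad[1L]], ")")
  }
  for (col in c("latitude", "longitude", "elevation", "mat", "map")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(abs(df$latitude) > 90, na.rm = TRUE) ||
      any(abs(df$longitude) > 180, na.rm = TRUE)) {
    stop("coordinates outside valid ranges")
  }
  df[, need]
}

#' Write a result table as CSV
#'
#' Writes rows with a stable, schema-defined column order and full float
#' precision (15 significant digits), so that identical inputs yield
#' byte-identical files.
#'
#' @param rows Data frame.
#' @param path Output path.
#' @param schema Character vector of required columns in output order;
#'   defaults to `names(rows)`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, schema = names(rows)) {
  missing_cols <- setdiff(schema, names(rows))
  if (length(missing_cols)) {
    stop("rows lack schema column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- rows[, schema, drop = FALSE]
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !inherits(out[[col]], "Date")) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
      out[[col]][out[[col]] %in% c("NA", " NA")] <- NA
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
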