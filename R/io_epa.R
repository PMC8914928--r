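# US-EPA daily pollution CSV layout: 28 fields, one row per site-day, with
# per-pollutant blocks (Units, Mean, 1st Max Value, 1st Max Hour, AQI; the
# O3 block has no Mean column in the published layout). Headers are matched
# by name after normalisation, so column order and minor punctuation do not
# matter.

norm_header <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

find_col <- function(headers, wanted) {
  hn <- norm_header(headers)
  for (w in wanted) {
    i <- match(norm_header(w), hn)
    if (!is.na(i)) return(i)
  }
  NA_integer_
}

#' Read the US-EPA daily pollution CSV into a point dataset
#'
#' Reads a daily air-quality table in the 28-field EPA layout, selects one
#' pollutant and date range, resolves each site's longitude/latitude from a
#' sidecar site-coordinates CSV (the published table carries street
#' addresses, not coordinates), and returns one observation per site-day.
#' Duplicate site-day rows are averaged with a warning; rows with a missing
#' value or an unmapped site are dropped and counted, and row conservation
#' (`rows_in == rows_used + rows_dropped`) is asserted.
#'
#' @param path daily CSV path.
#' @param sites_path sidecar CSV with columns `State Code, County Code,
#'   Site Num, Longitude, Latitude` (header-name matched).
#' @param pollutant one of `"NO2"`, `"O3"`, `"SO2"`, `"CO"`.
#' @param value `"aqi"` (default, the pollutant's AQI column) or `"mean"`
#'   (the pollutant's Mean concentration column).
#' @param date_range optional `c(from, to)` ISO dates (inclusive).
#' @return A lon/lat [point_data()]; `meta$dates` keeps each point's date,
#'   `meta$site_key` its site key, `meta$drop_log` the drop accounting.
#' @export
read_epa_daily <- function(path, sites_path, pollutant = c("O3", "NO2",
                                                           "SO2", "CO"),
                           value = c("aqi", "mean"), date_range = NULL) {
  pollutant <- match.arg(pollutant)
  value <- match.arg(value)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  key_cols <- c("State Code", "County Code", "Site Num", "Date Local")
  idx <- vapply(key_cols, function(k) find_col(names(raw), k), integer(1))
  vcol_name <- if (value == "aqi") paste(pollutant, "AQI")
               else paste(pollutant, "Mean")
  vcol <- find_col(names(raw), vcol_name)
  missing_cols <- c(key_cols[is.na(idx)], if (is.na(vcol)) vcol_name)
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rows_in <- nrow(raw)
  if (!rows_in) stop("empty-data: no rows in ", path, call. = FALSE)
  key <- paste(raw[[idx[1]]], raw[[idx[2]]], raw[[idx[3]]], sep = "-")
  date <- as.Date(raw[[idx[4]]])
  if (any(is.na(date)))
    stop("unparseable dates in 'Date Local'", call. = FALSE)
  val <- suppressWarnings(as.numeric(raw[[vcol]]))

  dropped_missing <- sum(!is.finite(val))
  keep <- is.finite(val)
  dropped_date <- 0L
  if (!is.null(date_range)) {
    inr <- date >= as.Date(date_range[1]) & date <= as.Date(date_range[2])
    dropped_date <- sum(keep & !inr)
    keep <- keep & inr
  }
  key <- key[keep]; date <- date[keep]; val <- val[keep]

  # duplicate site-day rows: average deterministically
  dup_key <- paste(key, date)
  if (anyDuplicated(dup_key)) {
    warning(sprintf("%d duplicate site-day row(s) averaged",
                    sum(duplicated(dup_key))))
    agg <- tapply(val, dup_key, mean)
    first <- !duplicated(dup_key)
    ord <- dup_key[first]
    key <- key[first]; date <- date[first]
    val <- as.numeric(agg[ord])
  }

  sites <- utils::read.csv(sites_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  sidx <- vapply(c("State Code", "County Code", "Site Num",
                   "Longitude", "Latitude"),
                 function(k) find_col(names(sites), k), integer(1))
  if (any(is.na(sidx)))
    stop("site sidecar missing columns", call. = FALSE)
  skey <- paste(sites[[sidx[1]]], sites[[sidx[2]]], sites[[sidx[3]]],
                sep = "-")
  m <- match(key, skey)
  dropped_nosite <- sum(is.na(m))
  if (dropped_nosite)
    warning(sprintf("%d row(s) dropped: site not in coordinate sidecar",
                    dropped_nosite))
  ok <- !is.na(m)
  if (!any(ok)) stop("empty-data: zero usable rows", call. = FALSE)
  lon <- sites[[sidx[4]]][m[ok]]
  lat <- sites[[sidx[5]]][m[ok]]
  drop_log <- list(rows_in = rows_in,
                   rows_used = sum(ok),
                   dropped_missing_value = dropped_missing,
                   dropped_outside_dates = dropped_date,
                   dropped_duplicates_merged = rows_in - dropped_missing -
                     dropped_date - length(dup_key[!duplicated(dup_key)]),
                   dropped_unmapped_site = dropped_nosite)
  point_data(lon, lat, val[ok], crs = "lonlat",
             meta = list(pollutant = pollutant, value = value,
                         dates = date[ok], site_key = key[ok],
                         drop_log = drop_log))
}

#' Reduce site-day observations to one value per site
#'
#' Collapses repeated observations of each site over a period (whole years,
#' months or days) with a summary statistic — e.g. the annual mean AQI per
#' monitor that feeds the areal-unit analysis.
#'
#' @param data a [point_data()] from [read_epa_daily()] (needs
#'   `meta$site_key`; `meta$dates` used for sub-year periods).
#' @param period `"year"` (default: all dates pooled per site), `"month"`
#'   or `"day"`; sub-year periods reduce within site-period groups and
#'   return the per-site mean of the period summaries.
#' @param statistic `"mean"`, `"median"` or `"max"`.
#' @return A [point_data()] with one point per site.
#' @export
temporal_reduce <- function(data, period = c("year", "month", "day"),
                            statistic = c("mean", "median", "max")) {
  stopifnot(inherits(data, "point_data"))
  period <- match.arg(period)
  statistic <- match.arg(statistic)
  fun <- switch(statistic, mean = mean, median = stats::median, max = max)
  site <- data$meta$site_key
  if (is.null(site))
    stop("dataset carries no site keys; read it with read_epa_daily()",
         call. = FALSE)
  grp <- switch(period,
    year = site,
    month = paste(site, format(data$meta$dates, "%Y-%m")),
    day = paste(site, data$meta$dates))
  per <- tapply(data$values, grp, fun)
  per_site <- sub(" .*$", "", names(per))
  v <- tapply(as.numeric(per), per_site, mean)
  first <- match(names(v), site)
  point_data(data$x[first], data$y[first], as.numeric(v), crs = data$crs,
             meta = list(pollutant = data$meta$pollutant,
                         site_key = names(v), period = period,
                         statistic = statistic))
}

#' Write a dataset as the canonical points CSV
#'
#' Columns `site_key, lon, lat, date, value` (`site_key`/`date` empty when
#' unknown).
#'
#' @param data a [point_data()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(data, path) {
  stopifnot(inherits(data, "point_data"))
  n <- length(data$x)
  utils::write.csv(data.frame(
    site_key = if (is.null(data$meta$site_key)) rep("", n) else data$meta$site_key,
    lon = data$x, lat = data$y,
    date = if (is.null(data$meta$dates)) rep("", n) else as.character(data$meta$dates),
    value = data$values), path, row.names = FALSE)
  invisible(path)
}
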