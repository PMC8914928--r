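# AQI category table: integer index ranges and their levels of concern.
# Hazardous is open-ended above 301.
AQI_CATEGORIES <- data.frame(
  name = c("Good", "Moderate", "Unhealthy for Sensitive Groups",
           "Unhealthy", "Very Unhealthy", "Hazardous"),
  color = c("Green", "Yellow", "Orange", "Red", "Purple", "Maroon"),
  lo = c(0, 51, 101, 151, 201, 301),
  hi = c(50, 100, 150, 200, 300, Inf),
  stringsAsFactors = FALSE
)

#' Load an AQI breakpoint table
#'
#' Breakpoint tables map pollutant concentration intervals
#' `[BP_LO, BP_Hi]` to index intervals `[I_LO, I_Hi]`. The packaged table
#' carries the published US-EPA technical-guidance breakpoints for O3
#' (8-hour ppm), NO2 (1-hour ppb), SO2 (1-hour ppb) and CO (8-hour ppm);
#' supply `path` to use your own CSV with the same columns
#' (`pollutant, units, bp_lo, bp_hi, i_lo, i_hi, truncation_decimals`).
#'
#' @param pollutant `"O3"`, `"NO2"`, `"SO2"` or `"CO"` (case-insensitive).
#' @param path optional CSV overriding the packaged table.
#' @return Object of class `aqi_breakpoints`: data frame of rows for the
#'   pollutant, sorted by `bp_lo`, with attribute `truncation_decimals`.
#' @export
aqi_breakpoints <- function(pollutant, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aqi_breakpoints.csv", package = "spatgran")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pollutant", "bp_lo", "bp_hi", "i_lo", "i_hi",
            "truncation_decimals")
  if (!all(need %in% names(tab)))
    stop("breakpoint table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  rows <- tab[toupper(tab$pollutant) == toupper(pollutant), , drop = FALSE]
  if (!nrow(rows))
    stop("no breakpoints for pollutant '", pollutant, "'", call. = FALSE)
  rows <- rows[order(rows$bp_lo), , drop = FALSE]
  if (any(rows$bp_lo > rows$bp_hi) || any(rows$i_lo > rows$i_hi))
    stop("malformed breakpoint table: reversed interval", call. = FALSE)
  if (nrow(rows) > 1 &&
      (any(diff(rows$bp_lo) <= 0) || any(rows$bp_lo[-1] <= rows$bp_hi[-nrow(rows)])))
    stop("malformed breakpoint table: overlapping concentration rows",
         call. = FALSE)
  structure(rows, class = c("aqi_breakpoints", "data.frame"),
            truncation_decimals = rows$truncation_decimals[1],
            pollutant = toupper(pollutant))
}

truncate_decimals <- function(x, digits) {
  f <- 10^digits
  trunc(x * f) / f
}

#' Compute the AQI for a pollutant concentration
#'
#' Piecewise-linear index: with the breakpoint row bracketing the truncated
#' concentration \eqn{C_P},
#' \deqn{I_P = \frac{I_{Hi}-I_{LO}}{BP_{Hi}-BP_{LO}}(C_P - BP_{LO}) + I_{LO}}
#' The concentration is truncated (not rounded) to the table's decimals
#' first, and the final index is rounded half-up to an integer to match the
#' integer category ranges.
#'
#' @param cp concentration value(s), in the table's units.
#' @param table an [aqi_breakpoints()] table.
#' @param round logical; return the integer index (default) or the raw
#'   piecewise-linear value.
#' @return Numeric AQI value(s).
#' @examples
#' tab <- aqi_breakpoints("O3")
#' compute_aqi(0.054, tab)  # upper edge of the Good row -> 50
#' @export
compute_aqi <- function(cp, table, round = TRUE) {
  stopifnot(inherits(table, "aqi_breakpoints"))
  cp <- as.numeric(cp)
  if (any(!is.finite(cp)) || any(cp < 0))
    stop("concentration must be finite and non-negative", call. = FALSE)
  cp <- truncate_decimals(cp, attr(table, "truncation_decimals"))
  out <- numeric(length(cp))
  for (k in seq_along(cp)) {
    i <- which(cp[k] >= table$bp_lo & cp[k] <= table$bp_hi)
    if (!length(i)) {
      if (cp[k] > max(table$bp_hi))
        stop(sprintf(
          "concentration %g exceeds the last breakpoint %g for %s",
          cp[k], max(table$bp_hi), attr(table, "pollutant")), call. = FALSE)
      # between rows after truncation cannot happen with contiguous tables;
      # fall back to the row below
      i <- max(which(cp[k] >= table$bp_lo))
    }
    i <- i[1]
    out[k] <- (table$i_hi[i] - table$i_lo[i]) /
      (table$bp_hi[i] - table$bp_lo[i]) * (cp[k] - table$bp_lo[i]) +
      table$i_lo[i]
  }
  if (round) floor(out + 0.5) else out
}

#' Classify an AQI value into its level of concern
#'
#' Maps a (rounded) index to the six levels of concern: Good (Green, 0-50),
#' Moderate (Yellow, 51-100), Unhealthy for Sensitive Groups (Orange,
#' 101-150), Unhealthy (Red, 151-200), Very Unhealthy (Purple, 201-300) and
#' Hazardous (Maroon, 301 and higher).
#'
#' @param index numeric AQI value(s), non-negative.
#' @return Data frame with columns `index, name, color, lo, hi`.
#' @examples
#' classify_aqi(c(0, 151, 301))$name
#' @export
classify_aqi <- function(index) {
  index <- as.numeric(index)
  if (any(!is.finite(index)) || any(index < 0))
    stop("invalid index: AQI values must be finite and >= 0", call. = FALSE)
  r <- floor(index + 0.5)
  i <- vapply(r, function(v)
    which(v >= AQI_CATEGORIES$lo & v <= AQI_CATEGORIES$hi)[1], integer(1))
  data.frame(index = index, name = AQI_CATEGORIES$name[i],
             color = AQI_CATEGORIES$color[i], lo = AQI_CATEGORIES$lo[i],
             hi = AQI_CATEGORIES$hi[i], stringsAsFactors = FALSE)
}

#' Index bounds of an AQI category
#'
#' @param name category name (exact, e.g. `"Very Unhealthy"`).
#' @return Numeric `c(lo, hi)`; `hi` is `Inf` for Hazardous.
#' @export
category_bounds <- function(name) {
  i <- match(name, AQI_CATEGORIES$name)
  if (is.na(i)) stop("unknown AQI category '", name, "'", call. = FALSE)
  c(lo = AQI_CATEGORIES$lo[i], hi = AQI_CATEGORIES$hi[i])
}
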