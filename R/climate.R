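# Agroclimatic covariates from daily weather over crop growth phases.
# "Night temperature" statistics are computed over daily minimum temperature,
# "day temperature" over daily maximum, following the convention of the
# agroclimatic-index literature for tmin/tmax series.

#' Growth-phase windows of a cropping cycle
#'
#' Defines the half-open phase windows: vegetative `[planting, flowering)`,
#' reproductive `[flowering, maturity)`, grain filling `[maturity, harvest)`
#' and the full cycle `[planting, harvest)`. A day equal to `flowering_date`
#' belongs to the reproductive phase only.
#'
#' @param planting_date,flowering_date,maturity_date,harvest_date `Date`s
#'   (or strings coercible to `Date`), strictly increasing.
#' @return a `phase_windows` list with elements `veg`, `rep`, `gf`, `full`,
#'   each `c(start, end)` (end exclusive).
#' @export
phase_windows <- function(planting_date, flowering_date, maturity_date,
                          harvest_date) {
  d <- as.Date(c(planting_date, flowering_date, maturity_date, harvest_date))
  if (any(is.na(d)) || any(diff(d) <= 0))
    stop("phase dates must be valid and strictly increasing")
  structure(list(veg = c(d[1], d[2]), rep = c(d[2], d[3]),
                 gf = c(d[3], d[4]), full = c(d[1], d[4])),
            class = "phase_windows")
}

max_run <- function(flag) {
  if (!length(flag) || !any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

roll_max_sum <- function(x, k) {
  k <- min(k, length(x))
  cs <- cumsum(c(0, x))
  max(cs[(k + 1):length(cs)] - cs[seq_len(length(cs) - k)])
}

phase_indices <- function(tmin, tmax, precip, gdd_base) {
  c(minNT = min(tmin), maxNT = max(tmin), meanNT = mean(tmin),
    minDT = min(tmax), maxDT = max(tmax), meanDT = mean(tmax),
    DTR = mean(tmax - tmin),
    GDD = sum(pmax(0, (tmax + tmin) / 2 - gdd_base)),
    rain_total = sum(precip),
    rain_days = sum(precip >= 1),
    max_dry_run = max_run(precip < 1),
    max_wet_run = max_run(precip >= 1),
    rain_max_1d = max(precip),
    rain_max_5d = roll_max_sum(precip, 5))
}

#' Agroclimatic covariates over growth phases
#'
#' Computes, for each phase window (vegetative, reproductive, grain filling,
#' full cycle), a fixed set of temperature and rainfall indices from a daily
#' weather series: min/max/mean night temperature (statistics of daily tmin,
#' suffix `NT`), min/max/mean day temperature (daily tmax, `DT`), mean
#' diurnal temperature range (`DTR`), growing degree days
#' (`GDD = sum(max(0, (tmax + tmin)/2 - base))`), total rainfall, rainy-day
#' count (>= 1 mm), longest dry and wet runs, and maximum 1-day and 5-day
#' rainfall. Windows are half-open `[start, end)`.
#'
#' @param weather data.frame with columns `date` (Date or ISO-8601 string),
#'   `tmin`, `tmax` (deg C) and `precip` (mm), strictly increasing daily
#'   dates with no gaps over the used windows.
#' @param phases a [phase_windows()].
#' @param gdd_base GDD base temperature in deg C (default 0, the wheat
#'   convention).
#' @return a one-row data.frame with columns `<index>_<phase>` for phases
#'   `veg`, `rep`, `gf`, `full` (56 covariates).
#' @examples
#' w <- data.frame(date = as.Date("2020-01-01") + 0:9,
#'                 tmin = 10, tmax = 20, precip = 0)
#' p <- phase_windows("2020-01-01", "2020-01-04", "2020-01-07", "2020-01-10")
#' climate_indices(w, p)$minNT_veg  # 10
#' @export
climate_indices <- function(weather, phases, gdd_base = 0) {
  stopifnot(inherits(phases, "phase_windows"))
  need <- c("date", "tmin", "tmax", "precip")
  if (!all(need %in% names(weather)))
    stop("'weather' needs columns date, tmin, tmax, precip")
  dates <- as.Date(weather$date)
  if (any(is.na(dates)) || any(diff(as.integer(dates)) <= 0))
    stop("weather dates must be strictly increasing")
  if (any(weather$tmin > weather$tmax)) stop("tmin must be <= tmax")
  out <- list()
  for (ph in c("veg", "rep", "gf", "full")) {
    win <- phases[[ph]]
    want <- seq(win[1], win[2] - 1, by = "day")
    idx <- match(want, dates)
    if (anyNA(idx))
      stop("weather does not cover ", ph, " phase; missing date(s): ",
           paste(head(want[is.na(idx)], 4), collapse = ", "))
    vals <- phase_indices(weather$tmin[idx], weather$tmax[idx],
                          weather$precip[idx], gdd_base)
    names(vals) <- paste0(names(vals), "_", ph)
    out[[ph]] <- vals
  }
  as.data.frame(as.list(do.call(c, unname(out))))
}

#' Representative sowing dates from observed planting dates
#'
#' Splits the planting-date distribution into `k` equiprobable intervals and
#' returns their midpoints, i.e. the empirical quantiles at probabilities
#' `(2j - 1) / (2k)`, `j = 1..k` (linear interpolation between order
#' statistics).
#'
#' @param planting_dates vector of `Date`s (or strings), non-empty.
#' @param k number of sowing windows (default 3 -> quantiles at 1/6, 1/2,
#'   5/6).
#' @return `k` `Date`s.
#' @export
sowing_windows <- function(planting_dates, k = 3) {
  d <- as.Date(planting_dates)
  if (!length(d) || any(is.na(d))) stop("planting dates must be non-empty Dates")
  if (k < 1) stop("k must be >= 1")
  probs <- (2 * seq_len(k) - 1) / (2 * k)
  as.Date(round(quantile(as.numeric(d), probs = probs, type = 7, names = FALSE)),
          origin = "1970-01-01")
}
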