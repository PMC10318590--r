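#' Daily growing degree days (base 10, capped at 30/10)
#'
#' Daily maximum and minimum temperatures are first clamped into
#' `[10, 30]` degrees C, then `GDD = (Tmax' + Tmin')/2 - 10`, so the daily
#' value always lies in `[0, 20]` degree-days.
#'
#' @param t_max,t_min daily maximum and minimum air temperature, degrees C
#'   (vectorized; `t_max >= t_min` required).
#' @return Daily GDD (degree C day).
#' @export
#' @examples
#' daily_gdd(32, 8)  # caps to (30, 10) -> 10
#' daily_gdd(28, 16) # 12
daily_gdd <- function(t_max, t_min) {
  if (any(t_max < t_min)) {
    stop("t_max must be >= t_min", call. = FALSE)
  }
  hi <- pmin(pmax(t_max, 10), 30)
  lo <- pmin(pmax(t_min, 10), 30)
  (hi + lo) / 2 - 10
}

#' Cumulative GDD from planting to a flight date
#'
#' Sums [daily_gdd()] over every day from `planting_date` through
#' `flight_date`, both inclusive. The weather series must cover the whole
#' interval with no gaps.
#'
#' @param weather data frame with columns `date`, `tmax_c`, `tmin_c`.
#' @param planting_date,flight_date `Date`s (or strings);
#'   `planting_date <= flight_date` required.
#' @return Cumulative GDD at the flight date.
#' @export
cumulative_gdd <- function(weather, planting_date, flight_date) {
  planting_date <- as.Date(planting_date)
  flight_date <- as.Date(flight_date)
  if (planting_date > flight_date) {
    stop("planting_date must be on or before flight_date", call. = FALSE)
  }
  days <- seq(planting_date, flight_date, by = "day")
  idx <- match(days, as.Date(weather$date))
  if (anyNA(idx)) {
    stop(sprintf("weather series is missing %s",
                 format(days[which(is.na(idx))[1]])), call. = FALSE)
  }
  sum(daily_gdd(weather$tmax_c[idx], weather$tmin_c[idx]))
}

#' Assign a cumulative GDD to a growth stage
#'
#' Half-open thermal-time windows: vegetative `[0, 650)`, flowering
#' `[650, 900)`, grain filling `[900, Inf)`; a boundary value belongs to the
#' later stage.
#'
#' @param gdd cumulative GDD, `>= 0` (vectorized).
#' @return Factor with levels `vegetative`, `flowering`, `grain_filling`.
#' @export
#' @examples
#' assign_stage(c(649.9, 650, 1500))
assign_stage <- function(gdd) {
  if (any(gdd < 0)) stop("gdd must be >= 0", call. = FALSE)
  cut(gdd, breaks = c(0, 650, 900, Inf), right = FALSE,
      labels = c("vegetative", "flowering", "grain_filling"))
}
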