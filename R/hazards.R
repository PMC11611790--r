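#' Piecewise-constant calendar trend
#'
#' Log-linear calendar trends for hazards are specified as piecewise-constant
#' slopes (per year, on the log scale) over calendar-year segments. A trend is
#' a data frame with columns `from` (first calendar year of the segment) and
#' `slope` (log-hazard change per year while the segment is active). Segments
#' run from their `from` year to the next segment's `from` year (the last one
#' is open-ended).
#'
#' @param from Integer vector of segment start years (strictly increasing).
#' @param slope Numeric vector of per-year log slopes, same length as `from`.
#' @return A tibble with columns `from`, `slope`, usable as the `theta_cal` /
#'   `eta_cal` fields of [sim_config()].
#' @examples
#' cal_trend(c(1992, 2010), c(-0.02, -0.003))
#' @export
cal_trend <- function(from, slope) {
  stopifnot(length(from) == length(slope), length(from) >= 1)
  if (is.unsorted(from, strictly = TRUE)) {
    stop("`from` years must be strictly increasing", call. = FALSE)
  }
  tibble::tibble(from = as.numeric(from), slope = as.numeric(slope))
}

#' Cumulative log trend at a calendar year
#'
#' Integrates a piecewise-constant slope from `origin` to `year`. Years before
#' the first segment take the first segment's slope; this keeps the trend
#' defined for run-in periods.
#'
#' @param year Numeric vector of calendar years (may be fractional; hazards are
#'   evaluated on the integer-year grid, so callers usually pass `floor()`ed
#'   years).
#' @param trend A trend from [cal_trend()], a single number (constant slope), or
#'   `NULL` (no trend).
#' @param origin Calendar year at which the cumulative trend is zero.
#' @return Numeric vector: the cumulative log-multiplier at `year`.
#' @export
cal_log_trend <- function(year, trend, origin) {
  if (is.null(trend)) return(rep(0, length(year)))
  if (is.numeric(trend) && is.null(dim(trend)) && length(trend) == 1 &&
      !is.data.frame(trend)) {
    return(trend * (year - origin))
  }
  stopifnot(is.data.frame(trend), all(c("from", "slope") %in% names(trend)))
  brk <- c(-Inf, trend$from[-1], Inf)
  out <- numeric(length(year))
  for (k in seq_len(nrow(trend))) {
    lo <- brk[k]
    hi <- brk[k + 1]
    # overlap of [origin, year] (signed) with segment [lo, hi)
    seg <- pmin(pmax(year, lo), hi) - pmin(pmax(origin, lo), hi)
    out <- out + trend$slope[k] * seg
  }
  out
}

#' Disease incidence hazard
#'
#' Log-linear in age with a piecewise log-linear calendar trend:
#' `b0 * exp(theta_age * (age - 65) + integral of theta_cal)`.
#'
#' @param age Attained age in years (>= 65); evaluated at integer ages on the
#'   simulation grid.
#' @param year Calendar year.
#' @param params List with `b0` (hazard at age 65 in the origin year,
#'   events/person-year), `theta_age` (log slope per year of age), `theta_cal`
#'   (calendar trend; see [cal_trend()]), and `origin` (calendar year anchoring
#'   the trend).
#' @return Hazard in events per person-year.
#' @examples
#' incidence_hazard(65, 1992, list(b0 = 0.02, theta_age = 0, theta_cal = NULL, origin = 1992))
#' @export
incidence_hazard <- function(age, year, params) {
  stopifnot(all(age >= 65))
  params$b0 * exp(params$theta_age * (age - 65) +
                    cal_log_trend(year, params$theta_cal, params$origin))
}

#' General-population (background) mortality hazard
#'
#' Gompertz in age with a log-linear calendar trend:
#' `m0 * exp(gamma * (age - 65) + delta_cal * (year - origin))`.
#'
#' @param age Attained age in years (>= 65).
#' @param year Calendar year.
#' @param params List with `m0` (hazard at 65), `gamma` (Gompertz slope per year
#'   of age), `delta_cal` (log trend per calendar year), `origin`.
#' @return Hazard in events per person-year.
#' @export
background_hazard <- function(age, year, params) {
  stopifnot(all(age >= 65))
  params$m0 * exp(params$gamma * (age - 65) +
                    params$delta_cal * (year - params$origin))
}

#' Post-diagnosis excess mortality hazard
#'
#' `e0 * rho_dur^floor(duration) * exp(integral of eta_cal)`: a first-year
#' excess that decays multiplicatively with each completed year since
#' diagnosis, scaled by a piecewise log-linear calendar trend.
#'
#' @param duration Years since diagnosis (>= 0).
#' @param year Calendar year.
#' @param params List with `e0`, `rho_dur`, `eta_cal` (see [cal_trend()]),
#'   `origin`.
#' @return Hazard in events per person-year.
#' @export
excess_hazard <- function(duration, year, params) {
  stopifnot(all(duration >= 0))
  params$e0 * params$rho_dur^floor(duration) *
    exp(cal_log_trend(year, params$eta_cal, params$origin))
}
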