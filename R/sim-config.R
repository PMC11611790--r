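#' Configuration for the synthetic beneficiary cohort simulator
#'
#' Bundles every parameter of the data-generating process: an illness-death
#' model for persons aged 65-99 observed over a calendar window, with
#' age- and calendar-dependent disease incidence, Gompertz background
#' mortality, duration-dependent post-diagnosis excess mortality, pre-existing
#' prevalent cases at age 65 and at the calendar boundary, partial Medicare-like
#' coverage, and diagnosis-coded claim streams with unconfirmed noise claims.
#'
#' The defaults emulate the published heart-failure setting: age-standardized
#' incidence starting near 29.4 per 1000 person-years in 1992 and declining to
#' about 19.9 per 1000 by 2017 (declining steeply to 2010, then levelling off),
#' 1-year survival near 76% in the early 1990s improving toward 79% by the late
#' 2000s and then slowly worsening, and realistic elderly background mortality
#' (about 1.3% per year at 65, doubling roughly every 8 years of age).
#'
#' @param year_start First calendar year of observation (annual analysis cells
#'   start here).
#' @param year_end Exclusive upper time bound of observation: follow-up stops at
#'   `year_end`, so the last complete annual cell is `year_end - 1`. The default
#'   2018 covers analysis years 1992-2017.
#' @param age_min,age_max Analysis age range in years (cells `age_min` to
#'   `age_max`); the simulation itself covers ages 65 (entry) to 100 (exit at
#'   the 100th birthday). The 65th year is an ascertainment run-in.
#' @param n_persons Number of beneficiaries to simulate.
#' @param incidence List: `b0` (hazard at age 65 in `year_start`,
#'   events/person-year), `theta_age` (log slope per year of age), `theta_cal`
#'   (piecewise calendar trend, see [cal_trend()]). The default `b0` is
#'   calibrated so the uniformly age-standardized incidence over
#'   `age_min:age_max` equals 29.4/1000 in `year_start`.
#' @param background List: `m0` (hazard at 65), `gamma` (Gompertz slope),
#'   `delta_cal` (calendar log trend per year).
#' @param excess List: `e0` (first-year excess hazard at `year_start`),
#'   `rho_dur` (multiplicative decay per completed year since diagnosis),
#'   `eta_cal` (piecewise calendar trend on the excess, see [cal_trend()]).
#' @param prev65_frac Probability that a person entering at their 65th birthday
#'   is already diagnosed (onset before 65).
#' @param prevboundary_frac Probability that a person alive at `year_start` with
#'   attained age > 65 is already diagnosed (onset before `year_start`).
#' @param coverage List of mixture weights for the coverage-fraction
#'   distribution: `p_full` (coverage 1), `p_partial` (uniform on [0.2, 1)),
#'   `p_low` (uniform on [0, 0.2), later excluded by the 20% coverage filter).
#' @param claims List: `p_unconfirmed` (probability that a never-diagnosed
#'   person emits one stray disease-coded claim), `claim_rate` (claims per year
#'   emitted after true onset).
#' @param seed Integer seed; required, so that every simulated cohort is
#'   reproducible.
#' @return An object of class `sim_config` (a named list, validated).
#' @examples
#' cfg <- sim_config(n_persons = 1000, seed = 1)
#' cfg$incidence$b0
#' @export
sim_config <- function(year_start = 1992,
                       year_end = 2018,
                       age_min = 66,
                       age_max = 99,
                       n_persons = 50000,
                       incidence = list(),
                       background = list(),
                       excess = list(),
                       prev65_frac = 0.02,
                       prevboundary_frac = 0.11,
                       coverage = list(p_full = 0.90, p_partial = 0.05, p_low = 0.05),
                       claims = list(p_unconfirmed = 0.02, claim_rate = 4),
                       seed = NULL) {
  if (is.null(seed)) {
    stop("`seed` is required: simulated cohorts must be reproducible", call. = FALSE)
  }
  if (!is.numeric(n_persons) || n_persons < 1) {
    stop("`n_persons` must be a positive integer", call. = FALSE)
  }
  if (year_start >= year_end) stop("`year_start` must precede `year_end`", call. = FALSE)
  stopifnot(age_min >= 65, age_max <= 99, age_min <= age_max)

  inc_default <- list(
    b0 = NULL,
    theta_age = 0.07,
    theta_cal = cal_trend(c(year_start, 2010), c(-0.0205, -0.003))
  )
  incidence <- utils::modifyList(inc_default, incidence)
  if (is.null(incidence$b0)) {
    # calibrate the age-65 baseline so the uniformly weighted age-standardized
    # incidence over the analysis ages equals 29.4/1000 in year_start
    incidence$b0 <- 0.0294 / mean(exp(incidence$theta_age * (age_min:age_max - 65)))
  }
  incidence$origin <- year_start

  bg_default <- list(m0 = 0.013, gamma = 0.085, delta_cal = -0.003)
  background <- utils::modifyList(bg_default, background)
  background$origin <- year_start

  exc_default <- list(
    e0 = 0.19,
    rho_dur = 0.65,
    eta_cal = cal_trend(c(year_start, 2007, 2013), c(-0.010, 0.005, 0.030))
  )
  excess <- utils::modifyList(exc_default, excess)
  excess$origin <- year_start

  probs <- c(prev65_frac, prevboundary_frac, claims$p_unconfirmed)
  if (any(probs < 0 | probs > 1)) {
    stop("prev65_frac, prevboundary_frac and p_unconfirmed must lie in [0, 1]",
         call. = FALSE)
  }
  hz <- c(incidence$b0, background$m0, excess$e0, excess$rho_dur,
          claims$claim_rate, unlist(coverage))
  if (any(hz < 0)) stop("hazard, rate and mixture parameters must be >= 0", call. = FALSE)

  structure(
    list(
      year_start = year_start, year_end = year_end,
      age_min = age_min, age_max = age_max,
      n_persons = as.integer(n_persons),
      incidence = incidence, background = background, excess = excess,
      prev65_frac = prev65_frac, prevboundary_frac = prevboundary_frac,
      coverage = coverage, claims = claims,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  window: [%s, %s), analysis ages %d-%d, n = %d, seed = %d\n",
              x$year_start, x$year_end, x$age_min, x$age_max, x$n_persons, x$seed))
  cat(sprintf("  incidence: b0 = %.5f, theta_age = %.3f\n",
              x$incidence$b0, x$incidence$theta_age))
  cat(sprintf("  background: m0 = %.4f, gamma = %.3f, delta_cal = %.4f\n",
              x$background$m0, x$background$gamma, x$background$delta_cal))
  cat(sprintf("  excess: e0 = %.3f, rho_dur = %.2f\n", x$excess$e0, x$excess$rho_dur))
  cat(sprintf("  prev65 = %.3f, prevboundary = %.3f, p_unconfirmed = %.3f\n",
              x$prev65_frac, x$prevboundary_frac, x$claims$p_unconfirmed))
  invisible(x)
}
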