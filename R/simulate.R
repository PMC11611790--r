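#' Simulate a synthetic beneficiary cohort with diagnosis-coded claims
#'
#' Generates person-level enrollment records and disease-coded claim streams
#' from an illness-death model with known ground truth. Persons enter at
#' `max(year_start, 65th birthday)` and are followed to death, the 100th
#' birthday, or the end of observation. Time is continuous; hazards are
#' piecewise-constant on (integer calendar year x integer age x completed
#' duration) cells, and waiting times are exponential within cells, so the
#' simulation is exact for the hazard model of [sim_config()].
#'
#' Disease onset arises three ways: pre-existing at age 65 (probability
#' `prev65_frac` for persons entering at their 65th birthday; onset planted
#' 1-10 years before 65), pre-existing at the calendar boundary (probability
#' `prevboundary_frac` for persons older than 65 at `year_start`; onset planted
#' up to 10 years before `year_start` but after the 65th birthday), or incident
#' (thinned from the incidence hazard during follow-up). After onset the death
#' hazard is background + excess; before onset it is background alone.
#'
#' Every true case emits a confirming claim pair (two claims within 0.3 years);
#' for incident cases the first claim falls exactly at onset, so downstream
#' two-claim ascertainment recovers the true onset date. Pre-existing cases get
#' their pair planted right after first observation (within 0.3 years of entry
#' for pre-65 cases, within 0.55 years for boundary cases), which is what the
#' cohort module's proxy classification rules key on. Cases additionally emit a
#' Poisson claim stream (`claim_rate`/year) from onset (or entry, if later) to
#' exit. A `p_unconfirmed` share of never-diagnosed persons emits one stray,
#' never-confirmed claim.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `persons` (tibble:
#'   `person_id`, `birth_date`, `entry_date`, `exit_date`, `death_date`,
#'   `coverage_fraction`, `true_onset_date`; dates in decimal calendar years)
#'   and `claims` (tibble: `person_id`, `service_date`, `dx_code`), plus the
#'   `config` used.
#' @examples
#' sim <- simulate_cohort(sim_config(n_persons = 500, seed = 42))
#' nrow(sim$persons)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  y0 <- config$year_start
  yB <- config$year_end

  birth <- stats::runif(n, y0 - 100, yB - 65)
  entry <- pmax(y0, birth + 65)
  cap <- pmin(yB, birth + 100)

  # pre-existing prevalent cases ------------------------------------------
  at_boundary <- birth + 65 < y0
  u <- stats::runif(n)
  pre65 <- !at_boundary & u < config$prev65_frac
  preb <- at_boundary & u < config$prevboundary_frac
  onset <- rep(NA_real_, n)
  onset[pre65] <- birth[pre65] + 65 - stats::runif(sum(pre65), 1, 10)
  age_over65 <- (y0 - birth) - 65
  onset[preb] <- y0 - stats::runif(sum(preb)) * pmin(10, age_over65[preb])
  diseased <- pre65 | preb

  # illness-death event engine --------------------------------------------
  alive <- rep(TRUE, n)
  death <- rep(NA_real_, n)
  tcur <- entry
  p_inc <- config$incidence
  p_bg <- config$background
  p_exc <- config$excess

  for (y in seq(floor(y0), ceiling(yB) - 1)) {
    end_y <- pmin(y + 1, cap)
    repeat {
      idx <- which(alive & tcur < end_y & tcur >= y)
      if (length(idx) == 0L) break
      ti <- tcur[idx]
      bi <- birth[idx]
      di <- diseased[idx]
      age_int <- floor(ti - bi + 1e-9)
      seg_end <- pmin(end_y[idx], bi + age_int + 1)
      lam_bg <- background_hazard(age_int, y, p_bg)
      lam_inc <- rep(0, length(idx))
      lam_exc <- rep(0, length(idx))
      dstep <- rep(0L, length(idx))
      if (any(!di)) {
        lam_inc[!di] <- incidence_hazard(age_int[!di], y, p_inc)
      }
      if (any(di)) {
        dur <- ti[di] - onset[idx][di]
        dstep[di] <- floor(dur + 1e-9)
        seg_end[di] <- pmin(seg_end[di], onset[idx][di] + dstep[di] + 1)
        lam_exc[di] <- excess_hazard(dstep[di], y, p_exc)
      }
      tot <- lam_bg + lam_inc + lam_exc
      t_ev <- ti + ifelse(tot > 0, stats::rexp(length(idx)) / tot, Inf)
      has_ev <- t_ev < seg_end
      # event type: onset with probability lam_inc / tot (healthy only)
      is_onset <- has_ev & !di & (stats::runif(length(idx)) * tot < lam_inc)
      is_death <- has_ev & !is_onset

      new_t <- ifelse(has_ev, t_ev, seg_end)
      tcur[idx] <- new_t
      if (any(is_onset)) {
        j <- idx[is_onset]
        diseased[j] <- TRUE
        onset[j] <- t_ev[is_onset]
      }
      if (any(is_death)) {
        j <- idx[is_death]
        alive[j] <- FALSE
        death[j] <- t_ev[is_death]
      }
    }
  }

  exit <- ifelse(alive, cap, death)

  # coverage fraction: mass at full coverage, some partial, a small
  # below-threshold mass that the 20% filter later removes
  cov <- config$coverage
  pr <- c(cov$p_full, cov$p_partial, cov$p_low)
  pr <- pr / sum(pr)
  grp <- sample.int(3L, n, replace = TRUE, prob = pr)
  coverage <- ifelse(grp == 1L, 1,
                     ifelse(grp == 2L, stats::runif(n, 0.2, 1),
                            stats::runif(n, 0, 0.2)))

  persons <- tibble::tibble(
    person_id = seq_len(n),
    birth_date = birth,
    entry_date = entry,
    exit_date = exit,
    death_date = ifelse(alive, NA_real_, death),
    coverage_fraction = coverage,
    true_onset_date = onset
  )

  claims <- simulate_claims(persons, config)

  structure(list(persons = persons, claims = claims, config = config),
            class = "sim_cohort")
}

# claim streams for a simulated person table (internal)
simulate_claims <- function(persons, config) {
  y0 <- config$year_start
  p <- persons
  has_onset <- !is.na(p$true_onset_date)
  onset <- p$true_onset_date
  len <- p$exit_date - p$entry_date

  pid <- integer(0)
  svc <- numeric(0)

  # confirming pair: category decides where the pair is planted
  cat_pre65 <- has_onset & onset < p$birth_date + 65
  cat_preb <- has_onset & !cat_pre65 & onset < y0
  cat_inc <- has_onset & !cat_pre65 & !cat_preb

  if (any(cat_inc)) {
    i <- which(cat_inc)
    c1 <- onset[i]
    gap <- pmin(stats::runif(length(i), 0.02, 0.29),
                0.9 * (p$exit_date[i] - onset[i]))
    pid <- c(pid, rep(p$person_id[i], 2L))
    svc <- c(svc, c1, c1 + gap)
  }
  if (any(cat_pre65)) {
    i <- which(cat_pre65)
    sq <- 0.45 * len[i]
    c1 <- p$entry_date[i] + pmin(stats::runif(length(i), 0, 0.15), sq)
    c2 <- c1 + pmin(stats::runif(length(i), 0.01, 0.14), sq)
    pid <- c(pid, rep(p$person_id[i], 2L))
    svc <- c(svc, c1, c2)
  }
  if (any(cat_preb)) {
    i <- which(cat_preb)
    sq <- 0.45 * len[i]
    c1 <- p$entry_date[i] + pmin(stats::runif(length(i), 0, 0.35), sq)
    c2 <- c1 + pmin(stats::runif(length(i), 0.01, 0.2), sq)
    pid <- c(pid, rep(p$person_id[i], 2L))
    svc <- c(svc, c1, c2)
  }

  # ongoing post-onset claim stream
  rate <- config$claims$claim_rate
  if (rate > 0 && any(has_onset)) {
    i <- which(has_onset)
    s <- pmax(onset[i], p$entry_date[i])
    dur <- p$exit_date[i] - s
    m <- stats::rpois(length(i), rate * dur)
    keep <- m > 0
    if (any(keep)) {
      reps <- m[keep]
      pid <- c(pid, rep(p$person_id[i][keep], reps))
      svc <- c(svc, rep(s[keep], reps) +
                 stats::runif(sum(reps)) * rep(dur[keep], reps))
    }
  }

  # stray single claims among never-diagnosed persons
  pu <- config$claims$p_unconfirmed
  if (pu > 0) {
    i <- which(!has_onset & stats::runif(nrow(p)) < pu)
    if (length(i)) {
      pid <- c(pid, p$person_id[i])
      svc <- c(svc, p$entry_date[i] + stats::runif(length(i)) *
                 (p$exit_date[i] - p$entry_date[i]))
    }
  }

  tibble::tibble(
    person_id = pid,
    service_date = svc,
    dx_code = ifelse(svc < 2015.75, "428", "I50")
  ) |>
    dplyr::arrange(.data$person_id, .data$service_date)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d persons, %d claims, window [%s, %s)\n",
              nrow(x$persons), nrow(x$claims),
              x$config$year_start, x$config$year_end))
  cat(sprintf("  true cases: %d (%.1f%%), deaths: %d\n",
              sum(!is.na(x$persons$true_onset_date)),
              100 * mean(!is.na(x$persons$true_onset_date)),
              sum(!is.na(x$persons$death_date))))
  invisible(x)
}

#' Write / read a simulated cohort as plain CSV
#'
#' `write_cohort()` writes `persons.csv` and `claims.csv` (dates as decimal
#' years with 6 decimals) plus `config.yaml`; `read_cohort()` reads them back.
#'
#' @param cohort A `sim_cohort`, or any list with `persons` and `claims`
#'   tibbles following the same schema.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_cohort()` returns the directory invisibly; `read_cohort()`
#'   returns a list with `persons` and `claims`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  persons <- dplyr::mutate(cohort$persons,
                           dplyr::across(dplyr::where(is.double), ~ round(.x, 6)))
  claims <- dplyr::mutate(cohort$claims,
                          service_date = round(.data$service_date, 6))
  readr::write_csv(persons, file.path(dir, "persons.csv"), na = "")
  readr::write_csv(claims, file.path(dir, "claims.csv"), na = "")
  if (!is.null(cohort$config)) {
    yaml::write_yaml(config_as_list(cohort$config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  persons <- readr::read_csv(
    file.path(dir, "persons.csv"),
    col_types = readr::cols(
      person_id = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  claims <- readr::read_csv(
    file.path(dir, "claims.csv"),
    col_types = readr::cols(
      person_id = readr::col_integer(),
      service_date = readr::col_double(),
      dx_code = readr::col_character()
    )
  )
  list(persons = persons, claims = claims)
}

# sim_config as a plain list for YAML serialization (internal)
config_as_list <- function(config) {
  out <- unclass(config)
  flat_trend <- function(tr) {
    if (is.data.frame(tr)) list(from = tr$from, slope = tr$slope) else tr
  }
  out$incidence$theta_cal <- flat_trend(out$incidence$theta_cal)
  out$excess$eta_cal <- flat_trend(out$excess$eta_cal)
  out
}
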