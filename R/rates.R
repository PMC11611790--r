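#' Standard weights for direct age standardization
#'
#' A standard population expressed as one weight per single year of age,
#' renormalized to sum to 1. The default is uniform over the analysis ages,
#' which keeps every synthetic-cohort check transparent; a custom standard
#' (e.g. the US 2000 standard population collapsed to these ages) can be
#' supplied as a data frame or CSV with columns `age`, `weight`.
#'
#' @param ages Integer vector of ages covered (default 66:99).
#' @param weights Optional data frame (`age`, `weight`) or path to a CSV with
#'   those columns; `NULL` gives uniform weights.
#' @return Tibble `age`, `w` with `sum(w) == 1`.
#' @export
standard_weights <- function(ages = 66:99, weights = NULL) {
  if (is.null(weights)) {
    out <- tibble::tibble(age = as.numeric(ages), w = 1 / length(ages))
  } else {
    if (is.character(weights)) {
      weights <- readr::read_csv(weights, col_types = readr::cols(
        age = readr::col_double(), weight = readr::col_double()
      ))
    }
    stopifnot(all(c("age", "weight") %in% names(weights)))
    out <- weights |>
      dplyr::filter(.data$age %in% ages) |>
      dplyr::transmute(age = .data$age, w = .data$weight)
    if (any(out$w < 0)) stop("weights must be non-negative", call. = FALSE)
    out$w <- out$w / sum(out$w)
  }
  out
}

#' Directly age-standardize a set of age-specific rates
#'
#' Computes `sum_a w(a) * rate(a)`. Ages carrying positive weight but no
#' observed rate are handled per `na_policy`: `"renormalize"` reweights over
#' the observed ages (and says so once via a message), `"fail"` errors.
#'
#' @param rate_by_age Tibble with `age` and `value` columns (`value` may be
#'   `NA` for unobserved ages).
#' @param weights From [standard_weights()].
#' @param na_policy `"renormalize"` (default) or `"fail"`.
#' @return A single number.
#' @export
age_adjust <- function(rate_by_age, weights, na_policy = c("renormalize", "fail")) {
  na_policy <- match.arg(na_policy)
  x <- dplyr::left_join(weights, rate_by_age, by = "age")
  miss <- is.na(x$value) & x$w > 0
  if (any(miss)) {
    if (na_policy == "fail") {
      stop("missing rate at age(s) with positive weight: ",
           paste(x$age[miss], collapse = ", "), call. = FALSE)
    }
    message(sprintf("age_adjust: renormalizing weights over %d of %d ages",
                    sum(!miss), nrow(x)))
    x <- x[!miss, ]
    x$w <- x$w / sum(x$w)
  }
  sum(x$w * x$value)
}

# Weighted per-year aggregation sum_a w * num/den over cells with den > 0.
# Weights are renormalized per year over the usable cells when the policy
# allows; all columns in `num_cols` share the same renormalization, so
# additive identities across columns survive it. Internal.
weighted_series <- function(table, num_cols, den_col, weights,
                            na_policy = c("renormalize", "fail")) {
  na_policy <- match.arg(na_policy)
  x <- dplyr::inner_join(tibble::as_tibble(table), weights, by = "age")
  x$.den <- x[[den_col]]
  bad <- x$.den <= 0 & x$w > 0
  if (any(bad) && na_policy == "fail") {
    stop("empty ", den_col, " cell(s) at positive weight, e.g. year ",
         x$year[bad][1], " age ", x$age[bad][1], call. = FALSE)
  }
  x <- x[x$.den > 0, ]
  x |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(num_cols),
                    ~ sum(.data$w / sum(.data$w) * .x / .data$.den)),
      .groups = "drop"
    )
}

#' Age-adjusted prevalence series with pre-existing components
#'
#' Per calendar year, the age-standardized prevalent fraction of person-time,
#' split by onset category: `P = P0 + P00 + Pis` holds exactly, where `P0` is
#' the contribution of cases diagnosed before age 65, `P00` of cases diagnosed
#' before the calendar boundary, and `Pis` of cases diagnosed inside the
#' observation window.
#'
#' @param table A [build_person_year_table()] result.
#' @param weights From [standard_weights()].
#' @param na_policy See [age_adjust()].
#' @return Tibble `year`, `P`, `P0`, `P00`, `Pis`, per 100 person-years.
#' @export
prevalence_series <- function(table, weights, na_policy = "renormalize") {
  out <- weighted_series(table, c("C0", "C00", "Cis"), "N", weights, na_policy)
  out |>
    dplyr::transmute(
      .data$year,
      P = 100 * (.data$C0 + .data$C00 + .data$Cis),
      P0 = 100 * .data$C0, P00 = 100 * .data$C00, Pis = 100 * .data$Cis
    )
}

#' Age-adjusted incidence series
#'
#' Confirmed incident onsets per person-year never previously diagnosed,
#' age-standardized, per 1000 person-years.
#'
#' @inheritParams prevalence_series
#' @return Tibble `year`, `incidence` (per 1000 person-years).
#' @export
incidence_series <- function(table, weights, na_policy = "renormalize") {
  out <- weighted_series(table, "I", "R", weights, na_policy)
  dplyr::transmute(out, .data$year, incidence = 1000 * .data$I)
}

#' Age-adjusted incidence-based mortality series with components
#'
#' Incidence-based mortality (IBM) is the all-cause death rate among persons
#' previously diagnosed, expressed per 100,000 *total population* person-years
#' and age-standardized. It is decomposed exactly as
#' `M = Mmu + M0 + M00 + Mis`: the part expected under general-population
#' mortality acting on the prevalent pool (`Mmu`, with
#' `mu(y,a) = Dall/N`), plus the excess parts contributed by each onset
#' category (`M_c = sum_a w * (D_c - C_c * mu) / N`).
#'
#' @inheritParams prevalence_series
#' @return Tibble `year`, `M`, `Mmu`, `M0`, `M00`, `Mis`, `mu_adj` (the
#'   age-adjusted general-population mortality), all per 100,000 person-years.
#' @export
ibm_series <- function(table, weights, na_policy = "renormalize") {
  x <- tibble::as_tibble(table) |>
    dplyr::mutate(
      mu = ifelse(.data$N > 0, .data$Dall / .data$N, 0),
      Cprev = .data$C0 + .data$C00 + .data$Cis,
      mmu_num = .data$Cprev * .data$mu,
      m0_num = .data$D0 - .data$C0 * .data$mu,
      m00_num = .data$D00 - .data$C00 * .data$mu,
      mis_num = .data$Dis - .data$Cis * .data$mu,
      mall_num = .data$D0 + .data$D00 + .data$Dis
    )
  out <- weighted_series(x, c("mmu_num", "m0_num", "m00_num", "mis_num",
                              "mall_num", "Dall"),
                         "N", weights, na_policy)
  dplyr::transmute(out, .data$year,
                   M = 1e5 * .data$mall_num,
                   Mmu = 1e5 * .data$mmu_num,
                   M0 = 1e5 * .data$m0_num,
                   M00 = 1e5 * .data$m00_num,
                   Mis = 1e5 * .data$mis_num,
                   mu_adj = 1e5 * .data$Dall)
}

#' Kaplan-Meier survival after diagnosis, by diagnosis year
#'
#' Observed k-year survival for incident cases (onset inside the observation
#' window), cohorted by calendar year of diagnosis. Follow-up runs from onset
#' to death, censoring at the end of observation or the 100th-birthday exit.
#' Horizons whose follow-up would extend past the data (`diag_year + k >
#' last_year`) are not emitted.
#'
#' @param persons Person tibble (filtered).
#' @param onsets Classified onsets from [classify_onset()].
#' @param horizons Survival horizons in years (default `c(1, 3, 5)`).
#' @param last_year Last complete calendar year of observation; defaults to
#'   the year containing the latest exit.
#' @return Tibble `diag_year`, `horizon`, `observed`, `n_cases`.
#' @export
km_survival <- function(persons, onsets, horizons = c(1, 3, 5),
                        last_year = NULL) {
  if (is.null(last_year)) last_year <- floor(max(persons$exit_date) - 1e-9)
  inc <- onsets |>
    dplyr::filter(.data$category == "INCIDENT") |>
    dplyr::inner_join(persons, by = "person_id") |>
    dplyr::mutate(
      time = .data$exit_date - .data$onset_date,
      event = as.integer(!is.na(.data$death_date)),
      diag_year = floor(.data$onset_date)
    ) |>
    dplyr::filter(.data$time > 0)

  fit_year <- function(d) {
    u <- d$diag_year[1]
    ks <- horizons[u + horizons <= last_year]
    if (!length(ks)) return(NULL)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    s <- summary(fit, times = ks, extend = TRUE)
    tibble::tibble(diag_year = u, horizon = ks, observed = s$surv,
                   n_cases = nrow(d))
  }
  out <- inc |>
    dplyr::group_by(.data$diag_year) |>
    dplyr::group_split() |>
    purrr::map(fit_year) |>
    purrr::compact() |>
    purrr::list_rbind()
  if (!nrow(out)) {
    message("km_survival: no incident cases with emittable horizons")
  }
  out
}

#' Relative survival against a demographically matched expected cohort
#'
#' Divides observed Kaplan-Meier survival by the expected survival of a
#' disease-free cohort matched on age and calendar year, computed per case as
#' `exp(-integral of mu(y, a))` along the case's own (year, age) diagonal and
#' averaged within each diagnosis year (an Ederer-style matched-cohort
#' estimator). `mu(y, a) = Dall/N` comes from the person-year table; paths
#' beyond the table's age or year range reuse the nearest available cell.
#'
#' @param observed Output of [km_survival()].
#' @param table The person-year table supplying `mu(y, a)`.
#' @param persons,onsets The inputs used for `observed` (needed for the
#'   incident cases' ages and onset dates).
#' @param background `"total"` (default) estimates `mu` from the whole cohort
#'   including cases, matching standard expected-survival practice;
#'   `"noncases"` removes prevalent person-time and their deaths first, giving
#'   a background rate uncontaminated by the disease's own excess (the two
#'   differ by roughly prevalence times excess hazard).
#' @return `observed` with added `expected` and `relative` columns.
#' @export
relative_survival <- function(observed, table, persons, onsets,
                              background = c("total", "noncases")) {
  background <- match.arg(background)
  tab <- tibble::as_tibble(table)
  mu_tab <- if (background == "total") {
    dplyr::transmute(tab, .data$year, .data$age,
                     mu = ifelse(.data$N > 0, .data$Dall / .data$N, 0))
  } else {
    dplyr::transmute(
      tab, .data$year, .data$age,
      mu = {
        nn <- .data$N - .data$C0 - .data$C00 - .data$Cis
        dd <- .data$Dall - .data$D0 - .data$D00 - .data$Dis
        ifelse(nn > 0, dd / nn, 0)
      })
  }
  yr <- range(tab$year)
  ar <- range(tab$age)
  inc <- onsets |>
    dplyr::filter(.data$category == "INCIDENT") |>
    dplyr::inner_join(persons, by = "person_id") |>
    dplyr::mutate(diag_year = floor(.data$onset_date))

  horizons <- sort(unique(observed$horizon))
  exp_k <- purrr::map(horizons, function(k) {
    seg <- split_person_time(seq_len(nrow(inc)), inc$onset_date,
                             inc$onset_date + k, inc$birth_date)
    seg$year <- pmin(pmax(seg$year, yr[1]), yr[2])
    seg$age <- pmin(pmax(seg$age, ar[1]), ar[2])
    seg <- dplyr::left_join(seg, mu_tab, by = c("year", "age"))
    ch <- seg |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(H = sum(.data$mu * .data$dur), .groups = "drop")
    tibble::tibble(
      diag_year = inc$diag_year[ch$id],
      horizon = k,
      s_exp = exp(-ch$H)
    ) |>
      dplyr::group_by(.data$diag_year, .data$horizon) |>
      dplyr::summarise(expected = mean(.data$s_exp), .groups = "drop")
  }) |>
    purrr::list_rbind()

  observed |>
    dplyr::left_join(exp_k, by = c("diag_year", "horizon")) |>
    dplyr::mutate(relative = .data$observed / .data$expected)
}
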