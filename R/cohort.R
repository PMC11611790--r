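#' Identify disease onset from claims by two-claim confirmation
#'
#' Onset is the service date of the earliest disease-coded claim that is
#' confirmed by a second claim strictly later but within `window` years
#' (inclusive). Same-day duplicate claims do not confirm each other (a
#' double-billed encounter must not self-confirm); the scan continues past
#' unconfirmed claims, so a person's onset can be a later claim than their
#' first.
#'
#' @param claims Tibble with `person_id`, `service_date` (decimal years), and
#'   optionally `dx_code` (ignored here: callers pass disease-coded claims).
#' @param persons Optional person table; when given, claims referencing unknown
#'   `person_id`s are rejected with an error naming them.
#' @param window Confirmation window in years (default 0.3).
#' @return Tibble `person_id`, `onset_date` with one row per confirmed case.
#' @examples
#' cl <- tibble::tibble(person_id = c(1, 1, 1), service_date = c(2000.0, 2000.4, 2000.5))
#' identify_onset(cl) # onset 2000.4: the first claim is never confirmed
#' @export
identify_onset <- function(claims, persons = NULL, window = 0.3) {
  stopifnot(all(c("person_id", "service_date") %in% names(claims)))
  if (!is.null(persons)) {
    unknown <- setdiff(unique(claims$person_id), persons$person_id)
    if (length(unknown)) {
      stop("claims reference unknown person_id(s): ",
           paste(utils::head(unknown, 10), collapse = ", "),
           if (length(unknown) > 10) " ..." else "", call. = FALSE)
    }
  }
  claims |>
    dplyr::distinct(.data$person_id, .data$service_date) |>
    dplyr::arrange(.data$person_id, .data$service_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(gap = dplyr::lead(.data$service_date) - .data$service_date) |>
    dplyr::filter(!is.na(.data$gap), .data$gap <= window) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$person_id, onset_date = .data$service_date)
}

#' Exclude persons with insufficient coverage
#'
#' Retains persons whose coverage fraction (share of months enrolled since age
#' 65) is at least `threshold`. The threshold is inclusive: exactly 20%
#' coverage is kept, matching an exclusion rule phrased as "less than 20%".
#'
#' @param persons Tibble with a `coverage_fraction` column in `[0, 1]`.
#' @param threshold Minimum retained coverage fraction (default 0.2).
#' @return The filtered person tibble.
#' @export
apply_coverage_filter <- function(persons, threshold = 0.2) {
  if (!"coverage_fraction" %in% names(persons) ||
      anyNA(persons$coverage_fraction)) {
    stop("`persons` must carry a complete `coverage_fraction` column", call. = FALSE)
  }
  dplyr::filter(persons, .data$coverage_fraction >= threshold)
}

#' Classify confirmed onsets into pre-existing and incident categories
#'
#' Onset timing relative to the age-65 and calendar boundaries is only partly
#' observable in 65+ claims, so classification combines the literal boundaries
#' with proxy rules for cases that were plainly already diagnosed when first
#' observed:
#'
#' * `PRE65`: onset before the 65th birthday, or - for persons first observed
#'   at their 65th birthday - a confirmed onset within the first
#'   `pre65_window` years after it (pre-existing disease surfacing immediately
#'   in claims).
#' * `PREBOUNDARY`: onset before `boundary_year`, or - for persons already
#'   older than 65 when observation starts at the boundary - a confirmed onset
#'   within the first `lookback` years after the boundary.
#' * `INCIDENT`: everything else (diagnosed after age 65 and after the
#'   boundary).
#'
#' @param onsets Tibble `person_id`, `onset_date` (from [identify_onset()]).
#' @param persons Person table with `birth_date`, `entry_date`, `exit_date`.
#' @param boundary_year Calendar-year boundary of the observation window.
#' @param pre65_window Proxy window (years after the 65th birthday) for
#'   pre-existing-at-65 ascertainment. Default 0.5.
#' @param lookback Proxy window (years after the boundary) for
#'   pre-existing-at-boundary ascertainment. Default 1.
#' @return `onsets` with an added `category` factor
#'   (`PRE65`, `PREBOUNDARY`, `INCIDENT`).
#' @export
classify_onset <- function(onsets, persons, boundary_year,
                           pre65_window = 0.5, lookback = 1) {
  x <- dplyr::inner_join(onsets, persons, by = "person_id")
  if (any(x$onset_date > x$exit_date)) {
    stop("onset after exit for person_id(s): ",
         paste(utils::head(x$person_id[x$onset_date > x$exit_date], 10),
               collapse = ", "), call. = FALSE)
  }
  b65 <- x$birth_date + 65
  enters_at_65 <- b65 >= boundary_year
  pre65 <- x$onset_date < b65 |
    (enters_at_65 & x$onset_date <= b65 + pre65_window)
  preb <- !pre65 &
    (x$onset_date < boundary_year |
       (!enters_at_65 & x$onset_date <= boundary_year + lookback))
  category <- factor(
    ifelse(pre65, "PRE65", ifelse(preb, "PREBOUNDARY", "INCIDENT")),
    levels = c("PRE65", "PREBOUNDARY", "INCIDENT")
  )
  dplyr::bind_cols(
    dplyr::select(x, "person_id", "onset_date"),
    tibble::tibble(category = category)
  )
}

# Split observation intervals into exact (calendar year x integer age)
# person-time contributions. `start`/`stop` are decimal years, `birth` the
# birth dates; returns one row per (interval x cell) with the exact overlap
# duration. Internal workhorse shared by the table builder and the
# expected-survival integral.
split_person_time <- function(id, start, stop, birth) {
  keep <- which(stop > start)
  id <- id[keep]; start <- start[keep]; stop <- stop[keep]; birth <- birth[keep]
  if (!length(id)) {
    return(tibble::tibble(id = integer(0), year = numeric(0),
                          age = numeric(0), dur = numeric(0)))
  }
  y0 <- floor(start)
  ny <- pmax(ceiling(stop) - y0, 1)
  ii <- rep(seq_along(id), ny)
  year <- y0[ii] + sequence(ny) - 1
  seg_start <- pmax(start[ii], year)
  seg_end <- pmin(stop[ii], year + 1)
  age0 <- floor(seg_start - birth[ii] + 1e-12)
  bday <- birth[ii] + age0 + 1
  d1 <- pmin(seg_end, bday) - seg_start
  d2 <- seg_end - pmax(seg_start, bday)
  out <- tibble::tibble(
    id = c(id[ii], id[ii]),
    year = c(year, year),
    age = c(age0, age0 + 1),
    dur = c(d1, d2)
  )
  dplyr::filter(out, .data$dur > 0)
}

#' Build the analysis person-year table
#'
#' Apportions each person's observed time exactly (continuously) over
#' half-open annual cells `[year, year + 1) x [age, age + 1)` and aggregates
#' the counts every estimator needs. A person is prevalent from their
#' (identified) onset forward, at risk of incidence until onset, and deaths
#' fall in the cell containing the death date. Person-time outside the
#' configured year/age ranges is dropped; deaths and onsets falling outside are
#' dropped too and their counts recorded in the `dropped` attribute.
#'
#' @param persons Filtered person tibble (`person_id`, `birth_date`,
#'   `entry_date`, `exit_date`, `death_date`).
#' @param onsets Classified onsets from [classify_onset()].
#' @param year_range Length-2 integer vector: first and last analysis year.
#' @param age_range Length-2 integer vector: first and last analysis age
#'   (default `c(66, 99)`).
#' @param lag_cap Diagnosis-year lags `>= lag_cap` are pooled in the
#'   lag-resolved side table (default 10; post-diagnosis excess mortality is
#'   negligible at such durations).
#' @return A tibble of class `person_year_table`, one row per (year, age) cell:
#'   `N` (person-years), `R` (never-diagnosed person-years at risk of
#'   incidence), `C0`, `C00`, `Cis` (prevalent person-years by onset category),
#'   `Cis_new` (the part of `Cis` from onsets during that calendar year), `I`
#'   (confirmed incident onsets), `D0`, `D00`, `Dis` (deaths among prevalent
#'   cases by category), `Dall` (all deaths). The attribute `incident_lag`
#'   holds the incident pool resolved by diagnosis-year lag
#'   (`year - floor(onset_date)`, capped at `lag_cap`): columns `year`, `age`,
#'   `lag`, `py` (person-years) and `deaths`; the partition module uses it to
#'   separate incidence-history from survival effects at fixed duration.
#' @export
build_person_year_table <- function(persons, onsets, year_range,
                                    age_range = c(66, 99), lag_cap = 10) {
  ymin <- year_range[1]; ymax <- year_range[2]
  amin <- age_range[1]; amax <- age_range[2]
  p <- persons
  ons <- dplyr::semi_join(onsets, p, by = "person_id")
  p <- dplyr::left_join(
    p, dplyr::select(ons, "person_id", "onset_date", "category"),
    by = "person_id"
  )

  start <- pmax(p$entry_date, p$birth_date + amin, ymin)
  stop <- pmin(p$exit_date, p$birth_date + amax + 1, ymax + 1)

  grid <- tidyr::expand_grid(year = ymin:ymax, age = amin:amax)

  sum_cells <- function(st) {
    dplyr::summarise(dplyr::group_by(st, .data$year, .data$age),
                     t = sum(.data$dur), .groups = "drop")
  }

  n_t <- sum_cells(split_person_time(p$person_id, start, stop, p$birth_date))

  has_on <- !is.na(p$onset_date)
  prev_start <- pmax(start, p$onset_date)[has_on]
  prev <- split_person_time(which(has_on), prev_start, stop[has_on],
                            p$birth_date[has_on])
  prev$category <- p$category[prev$id]
  prev$onset_year <- floor(p$onset_date[prev$id])
  c_t <- prev |>
    dplyr::group_by(.data$year, .data$age) |>
    dplyr::summarise(
      C0 = sum(.data$dur[.data$category == "PRE65"]),
      C00 = sum(.data$dur[.data$category == "PREBOUNDARY"]),
      Cis = sum(.data$dur[.data$category == "INCIDENT"]),
      Cis_new = sum(.data$dur[.data$category == "INCIDENT" &
                                .data$onset_year == .data$year]),
      .groups = "drop"
    )
  lag_py <- prev |>
    dplyr::filter(.data$category == "INCIDENT",
                  .data$year >= ymin, .data$year <= ymax,
                  .data$age >= amin, .data$age <= amax) |>
    dplyr::mutate(lag = pmin(.data$year - .data$onset_year, lag_cap)) |>
    dplyr::group_by(.data$year, .data$age, .data$lag) |>
    dplyr::summarise(py = sum(.data$dur), .groups = "drop")

  r_stop <- pmin(stop, ifelse(has_on, p$onset_date, Inf))
  r_t <- sum_cells(split_person_time(p$person_id, start, r_stop, p$birth_date))

  # incident onsets and deaths are point events assigned to their cell
  inc <- p[has_on & p$category == "INCIDENT" & !is.na(p$category), ]
  inc_cells <- tibble::tibble(
    year = floor(inc$onset_date),
    age = floor(inc$onset_date - inc$birth_date + 1e-12)
  )
  dropped_onsets <- sum(inc_cells$year < ymin | inc_cells$year > ymax |
                          inc_cells$age < amin | inc_cells$age > amax)
  i_t <- inc_cells |>
    dplyr::filter(.data$year >= ymin, .data$year <= ymax,
                  .data$age >= amin, .data$age <= amax) |>
    dplyr::count(.data$year, .data$age, name = "I")

  dd <- p[!is.na(p$death_date), ]
  d_cells <- tibble::tibble(
    year = floor(dd$death_date),
    age = floor(dd$death_date - dd$birth_date + 1e-12),
    category = as.character(dd$category),
    prevalent = !is.na(dd$onset_date) & dd$onset_date <= dd$death_date
  )
  dropped_deaths <- sum(d_cells$year < ymin | d_cells$year > ymax |
                          d_cells$age < amin | d_cells$age > amax)
  lag_d <- d_cells |>
    dplyr::mutate(onset_year = floor(dd$onset_date)) |>
    dplyr::filter(.data$prevalent, .data$category == "INCIDENT",
                  .data$year >= ymin, .data$year <= ymax,
                  .data$age >= amin, .data$age <= amax) |>
    dplyr::mutate(lag = pmin(.data$year - .data$onset_year, lag_cap)) |>
    dplyr::count(.data$year, .data$age, .data$lag, name = "deaths")
  incident_lag <- dplyr::full_join(lag_py, lag_d,
                                   by = c("year", "age", "lag")) |>
    dplyr::mutate(py = tidyr::replace_na(.data$py, 0),
                  deaths = tidyr::replace_na(.data$deaths, 0)) |>
    dplyr::arrange(.data$year, .data$age, .data$lag)
  d_t <- d_cells |>
    dplyr::filter(.data$year >= ymin, .data$year <= ymax,
                  .data$age >= amin, .data$age <= amax) |>
    dplyr::group_by(.data$year, .data$age) |>
    dplyr::summarise(
      D0 = sum(.data$prevalent & .data$category == "PRE65"),
      D00 = sum(.data$prevalent & .data$category == "PREBOUNDARY"),
      Dis = sum(.data$prevalent & .data$category == "INCIDENT"),
      Dall = dplyr::n(),
      .groups = "drop"
    )

  out <- grid |>
    dplyr::left_join(dplyr::rename(n_t, N = "t"), by = c("year", "age")) |>
    dplyr::left_join(dplyr::rename(r_t, R = "t"), by = c("year", "age")) |>
    dplyr::left_join(c_t, by = c("year", "age")) |>
    dplyr::left_join(i_t, by = c("year", "age")) |>
    dplyr::left_join(d_t, by = c("year", "age")) |>
    dplyr::mutate(dplyr::across(-c("year", "age"), ~ tidyr::replace_na(.x, 0)))

  if (dropped_onsets + dropped_deaths > 0) {
    message(sprintf("person_year_table: dropped %d onset(s) and %d death(s) outside the year/age ranges",
                    dropped_onsets, dropped_deaths))
  }
  structure(out,
            class = c("person_year_table", class(out)),
            year_range = c(ymin, ymax), age_range = c(amin, amax),
            lag_cap = lag_cap, incident_lag = incident_lag,
            dropped = c(onsets = dropped_onsets, deaths = dropped_deaths))
}

#' Write / read a person-year table as CSV
#'
#' The lag-resolved incident side table (needed by the partition module) is
#' written to / read from a companion file when `lag_path` is given.
#'
#' @param table A `person_year_table`.
#' @param path File path for the CSV.
#' @param lag_path Optional path for the `incident_lag` side table.
#' @return `write_person_year_table()` returns `path` invisibly;
#'   `read_person_year_table()` the table (attributes restored from the data).
#' @export
write_person_year_table <- function(table, path, lag_path = NULL) {
  readr::write_csv(tibble::as_tibble(table), path)
  if (!is.null(lag_path)) {
    readr::write_csv(attr(table, "incident_lag"), lag_path)
  }
  invisible(path)
}

#' @rdname write_person_year_table
#' @export
read_person_year_table <- function(path, lag_path = NULL) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  lag <- if (!is.null(lag_path)) {
    readr::read_csv(lag_path, col_types = readr::cols(.default = readr::col_double()))
  }
  structure(out,
            class = c("person_year_table", class(out)),
            year_range = range(out$year), age_range = range(out$age),
            lag_cap = if (!is.null(lag)) max(lag$lag), incident_lag = lag)
}
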