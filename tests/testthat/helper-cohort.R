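# Shared fixtures: simulate a cohort and run the ascertainment pipeline up to
# the person-year table. All fixtures are generated in code at test time.

run_cohort <- function(config, year_range = NULL, age_range = c(66, 99)) {
  if (is.null(year_range)) {
    year_range <- c(config$year_start, ceiling(config$year_end) - 1)
  }
  sim <- simulate_cohort(config)
  persons <- apply_coverage_filter(sim$persons)
  claims <- dplyr::semi_join(sim$claims, persons, by = "person_id")
  onsets <- classify_onset(identify_onset(claims, persons), persons,
                           boundary_year = config$year_start)
  table <- suppressMessages(
    build_person_year_table(persons, onsets, year_range, age_range)
  )
  list(sim = sim, persons = persons, claims = claims, onsets = onsets,
       table = table, config = config)
}

# a small synthetic person-year table built directly from cell values, with a
# consistent lag-resolved incident side table (constant lag mix unless given)
toy_table <- function(years, ages, N, C0 = 0, C00 = 0, Cis = 0,
                      D0 = 0, D00 = 0, Dis = 0, Dall = NULL,
                      lag_cap = 3, lag_weights = NULL, I = 0,
                      lag_tbl = NULL) {
  grid <- tidyr::expand_grid(year = years, age = ages)
  f <- function(v) {
    if (is.function(v)) mapply(v, grid$year, grid$age) else v
  }
  out <- dplyr::mutate(grid,
                       N = f(N), C0 = f(C0), C00 = f(C00), Cis = f(Cis),
                       I = f(I), D0 = f(D0), D00 = f(D00), Dis = f(Dis))
  out$Cis_new <- 0
  out$R <- out$N - out$C0 - out$C00 - out$Cis
  out$Dall <- if (is.null(Dall)) out$D0 + out$D00 + out$Dis else f(Dall)
  if (is.null(lag_tbl)) {
    if (is.null(lag_weights)) lag_weights <- rep(1 / (lag_cap + 1), lag_cap + 1)
    lag_tbl <- tidyr::expand_grid(year = years, age = ages, lag = 0:lag_cap) |>
      dplyr::left_join(out[, c("year", "age", "Cis", "Dis")],
                       by = c("year", "age")) |>
      dplyr::mutate(py = .data$Cis * lag_weights[.data$lag + 1],
                    deaths = .data$Dis * lag_weights[.data$lag + 1]) |>
      dplyr::select("year", "age", "lag", "py", "deaths")
  }
  out$Cis_new <- lag_tbl$py[lag_tbl$lag == 0][match(
    paste(out$year, out$age), paste(lag_tbl$year[lag_tbl$lag == 0],
                                    lag_tbl$age[lag_tbl$lag == 0]))]
  out$Cis_new[is.na(out$Cis_new)] <- 0
  structure(out,
            class = c("person_year_table", class(out)),
            year_range = range(years), age_range = range(ages),
            lag_cap = lag_cap, incident_lag = lag_tbl)
}

closure_err <- function(part) {
  terms <- if (inherits(part, "ibm_partition")) {
    c("Tmu", "T0", "T00", "Tinc", "Tsur")
  } else {
    c("T0", "T00", "Tinc", "Ts")
  }
  x <- as.data.frame(part)
  max(abs(rowSums(x[, terms]) - x$D) / pmax(abs(x$D), 1e-12))
}

phase_has_sequence <- function(phases, pattern) {
  v <- rle(as.character(phases))$values
  i <- 1
  for (x in v) if (i <= length(pattern) && identical(x, pattern[i])) i <- i + 1
  i > length(pattern)
}
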