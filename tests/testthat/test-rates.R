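test_that("direct standardization is an exact weighted dot product", {
  w <- standard_weights()
  # uniform rates pass through
  r <- tibble::tibble(age = 66:99, value = 7.3)
  expect_equal(age_adjust(r, w), 7.3)
  # two-age example
  w2 <- standard_weights(ages = 70:71)
  expect_equal(age_adjust(tibble::tibble(age = 70:71, value = c(10, 20)), w2), 15)
  # random weights and rates against an independent dot product
  set.seed(1)
  for (i in 1:20) {
    ww <- standard_weights(weights = tibble::tibble(age = 66:99,
                                                    weight = runif(34)))
    vals <- tibble::tibble(age = 66:99, value = rnorm(34))
    expect_equal(age_adjust(vals, ww), sum(ww$w * vals$value), tolerance = 1e-12)
  }
  # missing ages: renormalize (with message) or fail
  miss <- tibble::tibble(age = 66:98, value = 1)
  expect_message(v <- age_adjust(miss, w), "renormalizing")
  expect_equal(v, 1)
  expect_error(age_adjust(miss, w, na_policy = "fail"), "99")
})

test_that("standard weights load from a CSV and renormalize", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(age = 66:99, weight = rep(2, 34)), f)
  w <- standard_weights(weights = f)
  expect_equal(sum(w$w), 1)
  expect_equal(w$w, rep(1 / 34, 34))
})

test_that("prevalence components sum to the total exactly", {
  w <- standard_weights(66:68)
  tab <- toy_table(2000:2004, 66:68, N = 100, C0 = 4, C00 = 9, Cis = 0)
  pr <- prevalence_series(tab, w)
  expect_equal(pr$P, pr$P0 + pr$P00)   # Cis = 0
  expect_equal(pr$P0, rep(4, 5))
  # uniform 13% prevalence gives 13 per 100 person-years
  tab2 <- toy_table(2000:2004, 66:68, N = 200, Cis = 26)
  expect_equal(prevalence_series(tab2, w)$P, rep(13, 5))
  # simulated cohort: exact conservation every year
  cc <- run_cohort(sim_config(n_persons = 5000, seed = 17))
  pr3 <- prevalence_series(cc$table, standard_weights())
  expect_lt(max(abs(pr3$P - pr3$P0 - pr3$P00 - pr3$Pis) / pr3$P), 1e-12)
})

test_that("incidence series is the weighted at-risk rate", {
  w1 <- standard_weights(70)
  tab <- toy_table(2000, 70, N = 100, Cis = 20, I = 2)
  expect_equal(tab$R, 80)
  expect_equal(incidence_series(tab, w1)$incidence, 1000 * 2 / 80)
  tab0 <- toy_table(2000:2002, 66:70, N = 50, I = 0)
  expect_equal(incidence_series(tab0, standard_weights(66:70))$incidence,
               rep(0, 3))
})

test_that("IBM decomposition cancels excess exactly when cases die like everyone", {
  w <- standard_weights(66:70)
  # no deaths anywhere: every component is zero
  tab0 <- toy_table(2000:2003, 66:70, N = 100, C0 = 5, C00 = 5, Cis = 10)
  ib0 <- ibm_series(tab0, w)
  expect_equal(unlist(ib0[, c("M", "Mmu", "M0", "M00", "Mis")]),
               rep(0, 20), ignore_attr = TRUE)
  # uniform death rate: h_c = mu in every cell, so all excess terms vanish
  r <- 0.08
  tabu <- toy_table(2000:2003, 66:70, N = 100, C0 = 5, C00 = 5, Cis = 10,
                    D0 = 5 * r, D00 = 5 * r, Dis = 10 * r, Dall = 100 * r)
  ibu <- ibm_series(tabu, w)
  expect_equal(ibu$M0, rep(0, 4), tolerance = 1e-12)
  expect_equal(ibu$M00, rep(0, 4), tolerance = 1e-12)
  expect_equal(ibu$Mis, rep(0, 4), tolerance = 1e-12)
  expect_equal(ibu$M, ibu$Mmu, tolerance = 1e-12)
  # simulated cohort: M = Mmu + M0 + M00 + Mis exactly, every year
  cc <- run_cohort(sim_config(n_persons = 5000, seed = 18))
  ib <- ibm_series(cc$table, standard_weights())
  expect_lt(max(abs(ib$M - ib$Mmu - ib$M0 - ib$M00 - ib$Mis) /
                  pmax(ib$M, 1)), 1e-12)
})

test_that("aggregated rates equal an independent person-level recount", {
  cc <- run_cohort(sim_config(n_persons = 6000, seed = 19))
  w <- standard_weights()
  tt <- tibble::as_tibble(cc$table)
  p <- merge(cc$persons, cc$onsets, by = "person_id", all.x = TRUE)
  # recount one (year, age) cell at a time from raw person records
  recount_cell <- function(y, a) {
    s <- pmax(p$entry_date, p$birth_date + a, y)
    e <- pmin(p$exit_date, p$birth_date + a + 1, y + 1)
    n_t <- sum(pmax(e - s, 0))
    prev_s <- pmax(s, p$onset_date, na.rm = FALSE)
    prev_t <- ifelse(is.na(p$onset_date), 0, pmax(e - pmax(s, p$onset_date), 0))
    dead <- !is.na(p$death_date) & p$death_date >= y & p$death_date < y + 1 &
      p$death_date - p$birth_date >= a & p$death_date - p$birth_date < a + 1
    c(N = n_t, C = sum(prev_t), Dall = sum(dead))
  }
  set.seed(5)
  for (i in 1:12) {
    y <- sample(1993:2016, 1)
    a <- sample(67:95, 1)
    cell <- recount_cell(y, a)
    row <- tt[tt$year == y & tt$age == a, ]
    expect_equal(row$N, unname(cell["N"]), tolerance = 1e-9)
    expect_equal(row$C0 + row$C00 + row$Cis, unname(cell["C"]), tolerance = 1e-9)
    expect_equal(row$Dall, unname(cell["Dall"]))
  }
})

test_that("Kaplan-Meier survival matches the hand-computed 4-person fixture", {
  lv <- c("PRE65", "PREBOUNDARY", "INCIDENT")
  persons <- tibble::tibble(
    person_id = 1:4,
    birth_date = rep(1925, 4),
    entry_date = rep(1995, 4),
    exit_date = 2000 + c(0.5, 2.0, 0.8, 5.0),
    death_date = c(2000.5, 2002.0, NA, NA)
  )
  onsets <- tibble::tibble(person_id = 1:4, onset_date = rep(2000, 4),
                           category = factor(rep("INCIDENT", 4), levels = lv))
  sv <- km_survival(persons, onsets, last_year = 2005)
  expect_equal(sv$observed[sv$horizon == 1], 0.75)
  expect_equal(sv$observed[sv$horizon == 3], 0.375)
  expect_equal(sv$observed[sv$horizon == 5], 0.375)
  expect_true(all(diff(sv$observed) <= 1e-12)) # monotone in horizon
  # horizons beyond the data bound are absent
  sv2 <- km_survival(persons, onsets, last_year = 2002)
  expect_setequal(sv2$horizon, 1)
})

test_that("survival is monotone over horizons on simulated cohorts", {
  cc <- run_cohort(sim_config(n_persons = 6000, seed = 23))
  sv <- km_survival(cc$persons, cc$onsets, last_year = 2017)
  wide <- tidyr::pivot_wider(sv, id_cols = "diag_year",
                             names_from = "horizon", values_from = "observed")
  ok <- stats::complete.cases(wide)
  expect_true(all(wide$`1`[ok] >= wide$`3`[ok] & wide$`3`[ok] >= wide$`5`[ok]))
})

test_that("relative survival reduces to observed survival without background risk", {
  lv <- c("PRE65", "PREBOUNDARY", "INCIDENT")
  persons <- tibble::tibble(
    person_id = 1:3, birth_date = rep(1930, 3), entry_date = rep(1995, 3),
    exit_date = c(2001.2, 2004, 2006), death_date = c(2001.2, NA, NA)
  )
  onsets <- tibble::tibble(person_id = 1:3, onset_date = rep(2000.5, 3),
                           category = factor(rep("INCIDENT", 3), levels = lv))
  tab <- toy_table(1995:2006, 66:76, N = 100) # no deaths: mu = 0
  sv <- km_survival(persons, onsets, last_year = 2005) |>
    relative_survival(tab, persons, onsets)
  expect_equal(sv$expected, rep(1, nrow(sv)))
  expect_equal(sv$relative, sv$observed)
})

test_that("relative survival recovers the excess hazard scale", {
  # duration-flat excess e = 0.15 on top of realistic background mortality:
  # one-year relative survival should sit near exp(-0.15)
  cfg <- sim_config(n_persons = 30000, seed = 29,
                    incidence = list(theta_cal = cal_trend(1992, 0)),
                    excess = list(e0 = 0.15, rho_dur = 1,
                                  eta_cal = cal_trend(1992, 0)),
                    background = list(delta_cal = 0))
  cc <- run_cohort(cfg)
  sv <- km_survival(cc$persons, cc$onsets, last_year = 2017) |>
    relative_survival(cc$table, cc$persons, cc$onsets,
                      background = "noncases")
  r1 <- sv$relative[sv$horizon == 1 & sv$diag_year %in% 1995:2014]
  expect_equal(mean(r1), exp(-0.15), tolerance = 0.02)
  # with the disease-contaminated total-population rate the ratio shifts up
  # by about prevalence x excess
  svt <- km_survival(cc$persons, cc$onsets, last_year = 2017) |>
    relative_survival(cc$table, cc$persons, cc$onsets)
  r1t <- svt$relative[svt$horizon == 1 & svt$diag_year %in% 1995:2014]
  expect_gt(mean(r1t), mean(r1))
})
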