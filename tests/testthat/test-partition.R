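test_that("log-derivative uses central differences with one-sided edges", {
  d <- log_derivative(tibble::tibble(year = 1:3, value = c(1, 2, 3)))
  expect_equal(d$deriv[2], (3 - 1) / (2 * 2))
  expect_equal(d$interior, c(FALSE, TRUE, FALSE))
  dc <- log_derivative(tibble::tibble(year = 2000:2010, value = rep(4, 11)))
  expect_equal(dc$deriv, rep(0, 11))
  # exponential series: the central stencil returns sinh(g)
  g <- 0.05
  de <- log_derivative(tibble::tibble(year = 1:9, value = exp(g * (1:9))))
  expect_equal(de$deriv[5], sinh(g), tolerance = 1e-12)
  expect_message(
    log_derivative(tibble::tibble(year = 1:4, value = c(1, 0, 2, 3))),
    "zero value")
})

test_that("a decaying pre-boundary pool is attributed to T00 alone", {
  yrs <- 2000:2012
  tab <- toy_table(yrs, 66:70, N = 100,
                   C0 = 10, C00 = function(y, a) 20 * 0.8^(y - 2000), Cis = 12)
  pp <- partition_prevalence(tab, standard_weights(66:70), "raw")
  expect_lt(closure_err(pp), 1e-10)
  inner <- dplyr::filter(tibble::as_tibble(pp), .data$interior)
  expect_true(all(inner$T00 < 0))
  expect_equal(inner$T0, rep(0, nrow(inner)), tolerance = 1e-12)
  expect_equal(inner$Tinc, rep(0, nrow(inner)), tolerance = 1e-12)
  expect_equal(inner$Ts, rep(0, nrow(inner)), tolerance = 1e-12)
})

test_that("general-population mortality alone moves the IBM derivative", {
  yrs <- 2000:2012
  mu <- function(y, a) 0.05 * exp(0.02 * (y - 2000))
  tab <- toy_table(yrs, 66:70, N = 100, C0 = 10, C00 = 10, Cis = 20,
                   D0 = function(y, a) 10 * mu(y, a),
                   D00 = function(y, a) 10 * mu(y, a),
                   Dis = function(y, a) 20 * mu(y, a),
                   Dall = function(y, a) 100 * mu(y, a))
  pi <- partition_ibm(tab, standard_weights(66:70), "raw")
  expect_lt(closure_err(pi), 1e-10)
  inner <- dplyr::filter(tibble::as_tibble(pi), .data$interior)
  expect_equal(inner$Tmu, inner$D, tolerance = 1e-10)
  expect_equal(inner$T0 + inner$T00 + inner$Tinc + inner$Tsur,
               rep(0, nrow(inner)), tolerance = 1e-10)
})

test_that("growing incidence inflow is attributed to the incidence term", {
  yrs <- 2000:2014
  cap <- 3
  # lag-resolved pool: cohort of onset year c has size g(c) growing 3%/yr,
  # surviving each year with ratio 0.8; death rate 0.1 at every lag
  lag_tbl <- tidyr::expand_grid(year = yrs, age = 66:70, lag = 0:cap) |>
    dplyr::mutate(py = 10 * 1.03^(.data$year - .data$lag - 2000) * 0.8^.data$lag,
                  deaths = 0.1 * .data$py)
  cis <- dplyr::summarise(dplyr::group_by(lag_tbl, .data$year, .data$age),
                          v = sum(.data$py), .groups = "drop")
  tab <- toy_table(yrs, 66:70, N = 200,
                   Cis = function(y, a) cis$v[cis$year == y & cis$age == a][1],
                   Dis = function(y, a) 0.1 * cis$v[cis$year == y & cis$age == a][1],
                   Dall = function(y, a) 0,
                   lag_cap = cap, lag_tbl = lag_tbl)
  pp <- partition_prevalence(tab, standard_weights(66:70), "raw")
  expect_lt(closure_err(pp), 1e-10)
  # interior years past the boundary-edge cohorts: D carried by Tinc
  inner <- dplyr::filter(tibble::as_tibble(pp), .data$interior,
                         .data$year >= 2000 + cap + 5)
  expect_equal(inner$Tinc, inner$D, tolerance = 1e-8)
  expect_equal(inner$Ts, rep(0, nrow(inner)), tolerance = 1e-8)
  pi <- partition_ibm(tab, standard_weights(66:70), "raw")
  expect_lt(closure_err(pi), 1e-10)
  innm <- dplyr::filter(tibble::as_tibble(pi), .data$interior,
                        .data$year >= 2000 + cap + 5)
  expect_equal(innm$Tinc, innm$D, tolerance = 1e-8)
})

test_that("derivative closure is exact on simulated cohorts, raw and smoothed", {
  for (sd in c(41, 42)) {
    cc <- run_cohort(sim_config(n_persons = 8000, seed = sd))
    w <- standard_weights()
    for (src in c("raw", "smoothed")) {
      pp <- suppressMessages(partition_prevalence(cc$table, w, src))
      pi <- suppressMessages(partition_ibm(cc$table, w, src))
      expect_lt(closure_err(pp), 1e-10)
      expect_lt(closure_err(pi), 1e-10)
      # level identities hold too
      expect_lt(max(abs(pp$P - pp$P0 - pp$P00 - pp$Pis) / pp$P), 1e-10)
      expect_lt(max(abs(pi$M - pi$Mmu - pi$M0 - pi$M00 - pi$Mis) / pi$M), 1e-10)
    }
  }
})

test_that("the partition is invariant to rescaling all counts", {
  cc <- run_cohort(sim_config(n_persons = 5000, seed = 43))
  tab <- cc$table
  t2 <- tab
  for (col in setdiff(names(t2), c("year", "age"))) t2[[col]] <- t2[[col]] * 11
  lag2 <- dplyr::mutate(attr(tab, "incident_lag"),
                        py = .data$py * 11, deaths = .data$deaths * 11)
  attr(t2, "incident_lag") <- lag2
  attr(t2, "lag_cap") <- attr(tab, "lag_cap")
  w <- standard_weights()
  for (src in c("raw", "smoothed")) {
    a <- suppressMessages(partition_prevalence(tab, w, src))
    b <- suppressMessages(partition_prevalence(t2, w, src))
    for (col in c("D", "T0", "T00", "Tinc", "Ts")) {
      expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
    }
  }
})

test_that("time reversal negates the central-difference derivative", {
  cc <- run_cohort(sim_config(n_persons = 5000, seed = 44))
  pr <- prevalence_series(cc$table, standard_weights())
  fwd <- log_derivative(pr[, c("year", "P")])
  rev <- log_derivative(tibble::tibble(year = 2 * 2017 - rev(pr$year),
                                       P = rev(pr$P)))
  expect_equal(rev$deriv, -rev(fwd$deriv), tolerance = 1e-12)
})

test_that("relative contributions express the terms as shares of D", {
  lv <- tibble::tibble(
    year = 2000:2004, D = c(0.02, 0.01, -0.01, -0.02, 1e-8),
    interior = c(FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  part <- structure(
    dplyr::mutate(lv, T0 = 0.5 * D, T00 = 0.5 * D, Tinc = -0.25 * D,
                  Ts = 0.25 * D),
    class = c("prevalence_partition", class(lv))
  )
  ct <- relative_contributions(part)
  x <- tibble::as_tibble(ct)
  expect_setequal(unique(x$year), 2001:2003) # boundary years dropped
  expect_equal(sort(unique(round(x$share_pct, 6))), c(-25, 25, 50))
  sums <- dplyr::summarise(dplyr::group_by(x, .data$year),
                           s = sum(.data$share_pct))
  expect_equal(sums$s, rep(100, 3), tolerance = 0.1)
  # a single nonzero determinant takes 100%
  p2 <- structure(
    dplyr::mutate(lv, T0 = 0 * D, T00 = 0 * D, Tinc = D, Ts = 0 * D),
    class = c("prevalence_partition", class(lv)))
  x2 <- tibble::as_tibble(relative_contributions(p2))
  expect_equal(x2$share_pct[x2$determinant == "incidence"], rep(100, 3))
  # near-zero derivatives are suppressed, not divided through
  p3 <- part
  p3$D[2] <- 1e-9
  expect_message(ct3 <- relative_contributions(p3), "near-zero")
  expect_false(2001 %in% tibble::as_tibble(ct3)$year)
})

test_that("phase labels follow the signs of D and its difference", {
  ph <- classify_phases(tibble::tibble(year = 1:3, D = c(0.03, 0.02, 0.01)))
  expect_equal(as.character(ph$phase[2]), "decelerated increasing")
  ph2 <- classify_phases(tibble::tibble(year = 1:3, D = c(-0.01, -0.02, -0.03)))
  expect_equal(as.character(ph2$phase[2]), "accelerated declining")
  ph3 <- classify_phases(tibble::tibble(year = 1:5,
                                        D = c(0.02, 0.01, 0, -0.01, -0.02)))
  expect_equal(as.character(ph3$phase[3]), "accelerated declining") # inflection
  expect_error(classify_phases(tibble::tibble(year = 1:2, D = c(1, 2))),
               "3 consecutive")
})

test_that("partition objects tidy into long term tables", {
  cc <- run_cohort(sim_config(n_persons = 4000, seed = 45))
  pp <- suppressMessages(partition_prevalence(cc$table, standard_weights()))
  td <- tidy(pp)
  expect_setequal(unique(td$term), c("T0", "T00", "Tinc", "Ts"))
  expect_equal(nrow(td), nrow(pp) * 4)
  gl <- glance(pp)
  expect_lt(gl$max_closure_err, 1e-10)
})
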