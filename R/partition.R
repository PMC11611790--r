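#' Central-difference logarithmic derivative of an annual series
#'
#' `[X(y+1) - X(y-1)] / (2 X(y))` at interior years, with one-sided
#' differences at the first and last year (flagged `interior = FALSE`).
#' Years with `X(y) = 0` get `NA` with a message.
#'
#' @param series Tibble with `year` and a single value column (its name is
#'   free; the first non-`year` column is used).
#' @return Tibble `year`, `deriv` (1/year), `interior`.
#' @examples
#' log_derivative(tibble::tibble(year = 1:3, value = c(1, 2, 3))) # 0.5 at year 2
#' @export
log_derivative <- function(series) {
  stopifnot("year" %in% names(series), nrow(series) >= 2)
  series <- dplyr::arrange(series, .data$year)
  v <- series[[setdiff(names(series), "year")[1]]]
  n <- length(v)
  up <- c(v[2], v[3:n], v[n])
  lo <- c(v[1], v[1:(n - 2)], v[n - 1])
  span <- c(1, rep(2, n - 2), 1)
  d <- (up - lo) / (span * v)
  if (any(v == 0)) {
    message(sprintf("log_derivative: undefined at %d year(s) with zero value",
                    sum(v == 0)))
    d[v == 0] <- NA_real_
  }
  tibble::tibble(year = series$year, deriv = d,
                 interior = c(FALSE, rep(TRUE, n - 2), FALSE))
}

# ---------------------------------------------------------------------------
# Cell-level machinery shared by both partitions.
#
# The incident prevalent pool is resolved by diagnosis-year lag
# l = year - floor(onset): the cohort occupying cell (y, a, l) moves exactly
# to (y+1, a+1, l+1), so the pool obeys the cohort-diagonal recursion
#     q(y, a, 0) = iota(y, a)                       (newly diagnosed)
#     q(y, a, l) = sigma_l(y, a) * q(y-1, a-1, l-1)  (survivors, 1 <= l < L)
#     q(y, a, L) = sigma_L(y, a) * (q(y-1, a-1, L-1) + q(y-1, a-1, L))
# with L the lag cap (excess mortality is negligible past it) and sigma the
# empirical continuation ratio at fixed lag. Differencing the recursion with
# the midpoint (Bennet) product rule and unrolling along the diagonals splits
# any s-year difference of pis = sum_l q exactly into
#   A: incidence history (iota differences),
#   B: survival at fixed duration (sigma differences),
#   C: boundary carry (diagonal parts that leave the observed window, i.e.
#      the replacement transient of the pre-boundary cohort).
# Because sigma is compared at fixed lag, drift in the pool's duration
# composition (maturation) never contaminates the survival term; A, B and C
# all vanish when incidence and survival are time-constant, which makes the
# decomposition a trend attribution rather than a gross inflow/outflow
# ledger, while A + B + C = pis(y,a) - pis(y-s,a) holds exactly.
# ---------------------------------------------------------------------------

# cell quantities as year x age matrices / year x age x lag arrays (internal)
partition_cells <- function(table, weights, series_source = c("smoothed", "raw"),
                            df = 4) {
  series_source <- match.arg(series_source)
  x <- tibble::as_tibble(table)
  lag <- attr(table, "incident_lag")
  if (is.null(lag)) {
    stop("`table` lacks the `incident_lag` attribute; build it with ",
         "build_person_year_table() or restore it via read_person_year_table(lag_path=)",
         call. = FALSE)
  }
  lag_cap <- attr(table, "lag_cap")
  yrs <- sort(unique(x$year))
  # ages usable in every year (a fixed weight vector keeps every additive
  # identity exact across years)
  age_ok <- x |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(ok = all(.data$N > 0), .groups = "drop")
  if (any(!age_ok$ok)) {
    message(sprintf("partition: dropping %d age(s) with empty cells; weights renormalized",
                    sum(!age_ok$ok)))
  }
  ages <- age_ok$age[age_ok$ok]
  w <- dplyr::filter(weights, .data$age %in% ages)
  w$w <- w$w / sum(w$w)

  x <- x |>
    dplyr::filter(.data$age %in% ages) |>
    dplyr::mutate(
      pi0 = .data$C0 / .data$N,
      pi00 = .data$C00 / .data$N,
      mu = .data$Dall / .data$N,
      h0 = ifelse(.data$C0 > 0, .data$D0 / .data$C0, 0),
      h00 = ifelse(.data$C00 > 0, .data$D00 / .data$C00, 0),
      inflow = .data$I / .data$N,
      outflow_is = .data$Dis / .data$N
    )
  vals <- c("pi0", "pi00", "mu", "h0", "h00", "inflow", "outflow_is")

  # lag-resolved incident pool: prevalent fraction q and case death rate h
  lx <- lag |>
    dplyr::filter(.data$age %in% ages) |>
    dplyr::left_join(dplyr::select(x, "year", "age", "N"), by = c("year", "age")) |>
    dplyr::mutate(q = .data$py / .data$N,
                  h = ifelse(.data$py > 0, .data$deaths / .data$py, 0)) |>
    dplyr::select("year", "age", "lag", "q", "h")
  lx <- tidyr::expand_grid(year = yrs, age = ages, lag = 0:lag_cap) |>
    dplyr::left_join(lx, by = c("year", "age", "lag")) |>
    dplyr::mutate(q = tidyr::replace_na(.data$q, 0),
                  h = tidyr::replace_na(.data$h, 0))

  # structural zeros: a lag-l pool cannot exist before any onset cohort old
  # enough to fill it; keep such cells at exactly zero (smoothing must not
  # interpolate into them, or stencils across the filling edge would read the
  # pool's appearance as a survival/case-fatality trend)
  y0on <- min(lx$year[lx$q > 0] - lx$lag[lx$q > 0], Inf)
  structural <- lx$year - lx$lag < y0on
  # boundary-edge cohorts (onset in or before the window's first year) are
  # ascertainment-depleted; keep them raw so the spline does not ramp across
  # the dip, and let the split route their differences to boundary carry
  edge_cohort <- lx$lag < lag_cap & (lx$year - lx$lag) <= yrs[1]
  sigma_model <- NULL
  if (series_source == "smoothed") {
    # Death counts in single (year, age, lag) cells are far too sparse to
    # carry a calendar trend, so the smoothed source uses a pooled excess
    # model in the spirit of parametric relative-survival modelling:
    # e(y, l) = Ebar_l * phi(y), a fixed duration profile scaled by a smooth
    # calendar multiplier estimated from all excess deaths jointly. The
    # case death rate is then h = mu + e, and the cohort continuation ratio
    # sigma_l(y) = kappa_l * exp(-Es_l * phibar(y)) responds to calendar
    # changes in excess only; everything the model misses stays in the
    # remainder and is routed to boundary carry, keeping the split exact.
    mu_raw <- dplyr::transmute(x, .data$year, .data$age, mu0 = .data$mu)
    pooled <- lag |>
      dplyr::filter(.data$age %in% ages) |>
      dplyr::inner_join(mu_raw, by = c("year", "age")) |>
      dplyr::mutate(expd = .data$py * .data$mu0) |>
      dplyr::group_by(.data$year, .data$lag) |>
      dplyr::summarise(tot = sum(.data$py),
                       exc = sum(.data$deaths) - sum(.data$expd),
                       .groups = "drop")
    prof <- pooled |>
      dplyr::group_by(.data$lag) |>
      dplyr::summarise(Ebar = max(sum(.data$exc) / max(sum(.data$tot), 1e-12), 0),
                       .groups = "drop")
    Ebar <- prof$Ebar[match(0:lag_cap, prof$lag)]
    Ebar[is.na(Ebar)] <- 0
    cal <- pooled |>
      dplyr::mutate(wgt = .data$tot * Ebar[.data$lag + 1L]) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(num = sum(.data$exc[.data$wgt > 0]),
                       den = sum(.data$wgt), .groups = "drop")
    # the calendar multiplier pools every excess death, so it supports more
    # flexibility than the sparse cell series
    phi_df <- min(df + 2, max(df, length(yrs) - 2))
    phi <- rep(1, length(yrs))
    ok <- cal$den > 0
    if (sum(ok) >= phi_df + 2 && sum(Ebar) > 0) {
      bx <- cbind(1, splines::ns(cal$year[ok], df = phi_df))
      fit <- stats::lm.wfit(bx, cal$num[ok] / cal$den[ok], cal$den[ok])
      phi[match(cal$year[ok], yrs)] <- pmax(bx %*% fit$coefficients, 0)
    }

    x <- smooth_cells(x, vals, df = df, group = "age")
    lx <- smooth_cells(lx, "q", df = df, group = c("age", "lag"),
                       fit_rows = !(structural | edge_cohort))
    # model-based case death rate replaces the sparse empirical one
    lx <- dplyr::left_join(
      lx, dplyr::select(x, "year", "age", "mu"), by = c("year", "age"))
    lx$h <- lx$mu + Ebar[lx$lag + 1L] * phi[match(lx$year, yrs)]
    lx$mu <- NULL

    lx$q[structural] <- 0
    lx$h[structural] <- 0

    # model continuation ratio: excess integrated over the transition year,
    # with a per-lag baseline kappa fitted to the observed pools (kappa
    # absorbs timing factors such as the partial first-year person-time of
    # new cases, which roughly doubles the lag-0 to lag-1 ratio)
    nl <- lag_cap + 1L
    Es <- c(0, (Ebar[-nl] + Ebar[-1]) / 2) # excess crossed entering bin l
    phibar <- c(phi[1], (phi[-1] + phi[-length(phi)]) / 2)
    sigma_model <- exp(-outer(phibar, Es))
    qm <- array(0, c(length(yrs), length(ages), nl))
    qm[cbind(match(lx$year, yrs), match(lx$age, ages), lx$lag + 1L)] <- lx$q
    kap <- rep(1, nl)
    for (l in 2:nl) {
      num <- 0; den <- 0
      for (yi in 2:length(yrs)) {
        prev <- qm[yi - 1, -length(ages), l - 1]
        if (l == nl) prev <- prev + qm[yi - 1, -length(ages), nl]
        use <- prev > 1e-7
        num <- num + sum(qm[yi, -1, l][use])
        den <- den + sum(sigma_model[yi, l] * prev[use])
      }
      if (den > 0) kap[l] <- num / den
    }
    sigma_model <- sweep(sigma_model, 2, kap, `*`)
  } else {
    lx$q[structural] <- 0
    lx$h[structural] <- 0
  }
  m <- lapply(vals, function(v) {
    mm <- matrix(0, length(yrs), length(ages))
    mm[cbind(match(x$year, yrs), match(x$age, ages))] <- x[[v]]
    mm
  })
  names(m) <- vals
  nl <- lag_cap + 1L
  q <- array(0, c(length(yrs), length(ages), nl))
  h <- array(0, c(length(yrs), length(ages), nl))
  idx <- cbind(match(lx$year, yrs), match(lx$age, ages), lx$lag + 1L)
  q[idx] <- lx$q
  h[idx] <- lx$h
  m$pis <- rowSums(q, dims = 2)
  list(cells = m, q = q, h = h, sigma_model = sigma_model,
       years = yrs, ages = ages, w = w$w,
       source = series_source, df = df)
}

# Exact A/B/C split of the s-year difference of the lag-resolved incident
# pool (see block comment above). Returns year x age matrices summed over
# lags: A, B, C (for the prevalence partition) and their case-death-rate
# weighted versions AH, BH, CH plus QDH = sum_l qbar_l * dh_l and
# QBAR = sum_l qbar_l (for the IBM partition; bars and differences are over
# the same s-year stencil). Rows 1..s are NA. Internal.
ab_split <- function(pc, s) {
  q <- pc$q
  h <- pc$h
  yr <- pc$years
  ny <- dim(q)[1]; na <- dim(q)[2]; nl <- dim(q)[3]
  rows <- (s + 1):ny
  deep <- rows[rows - s - 1 >= 1] # recursion needs year y-s-1 inside window
  shallow <- setdiff(rows, deep)
  # onset cohorts at or before the window's first year are boundary-edge:
  # ascertainment proxies deplete them, so comparisons against them read as
  # boundary carry, never as incidence or survival trends
  y_clean <- yr[1] + 1
  FA <- array(0, dim(q)); FB <- FA; FC <- FA
  for (j in seq_len(na)) {
    for (l in seq_len(nl)) {
      dq <- q[rows, j, l] - q[rows - s, j, l]
      edge <- if (l == nl) rep(FALSE, length(rows)) else
        (yr[rows] - s - (l - 1)) < y_clean
      if (l == 1L || j == 1L) {
        # newly diagnosed, or aging in at the youngest analysis age:
        # incidence inflow
        FA[rows, j, l] <- ifelse(edge, 0, dq)
        FC[rows, j, l] <- ifelse(edge, dq, 0)
        next
      }
      if (length(shallow)) {
        # window edge: no prior-year pool to define sigma
        FC[shallow, j, l] <- q[shallow, j, l] - q[shallow - s, j, l]
      }
      if (length(deep)) {
        den_now <- q[deep - 1, j - 1, l - 1]
        den_prev <- q[deep - s - 1, j - 1, l - 1]
        anc_A <- FA[deep - 1, j - 1, l - 1]
        anc_B <- FB[deep - 1, j - 1, l - 1]
        anc_C <- FC[deep - 1, j - 1, l - 1]
        if (l == nl) { # capped bin also absorbs its own survivors
          den_now <- den_now + q[deep - 1, j - 1, nl]
          den_prev <- den_prev + q[deep - s - 1, j - 1, nl]
          anc_A <- anc_A + FA[deep - 1, j - 1, nl]
          anc_B <- anc_B + FB[deep - 1, j - 1, nl]
          anc_C <- anc_C + FC[deep - 1, j - 1, nl]
        }
        # the continuation ratio can only be compared when both stencil sides
        # have a non-negligible pool to continue from; one-sided cells (the
        # filling edge of the window) and boundary-edge cohorts are carry,
        # not survival signal. sigma is clamped (a cohort cannot much more
        # than double its prevalent share in a year; the lag-1 ratio is ~2 by
        # construction because new cases contribute partial first-year time):
        # the clamp residue lands in the remainder and hence in carry, so the
        # split stays exact while sparse-cell ratios cannot amplify along the
        # diagonals.
        flo <- 1e-7
        comparable <- den_now > flo & den_prev > flo & !edge[match(deep, rows)]
        if (is.null(pc$sigma_model)) {
          sig_now <- ifelse(den_now > flo, pmin(q[deep, j, l] / den_now, 2.5), 0)
          sig_prev <- ifelse(den_prev > flo, pmin(q[deep - s, j, l] / den_prev, 2.5), 0)
        } else {
          sig_now <- pc$sigma_model[deep, l]
          sig_prev <- pc$sigma_model[deep - s, l]
        }
        r_now <- q[deep, j, l] - sig_now * den_now
        r_prev <- q[deep - s, j, l] - sig_prev * den_prev
        sbar <- (sig_now + sig_prev) / 2
        FA[deep, j, l] <- ifelse(comparable, sbar * anc_A, 0)
        FB[deep, j, l] <- ifelse(comparable,
                                 (sig_now - sig_prev) * (den_now + den_prev) / 2 +
                                   sbar * anc_B, 0)
        FC[deep, j, l] <- ifelse(comparable,
                                 (r_now - r_prev) + sbar * anc_C,
                                 dq[match(deep, rows)])
      }
    }
  }
  # case-death-rate stencil: a trend in h is only readable when the pool
  # exists on both sides; across a one-sided (filling-edge) stencil the whole
  # product change is attributed to the pool change at the observed h level
  qn <- q[rows, , , drop = FALSE]; qp <- q[rows - s, , , drop = FALSE]
  hn <- h[rows, , , drop = FALSE]; hp <- h[rows - s, , , drop = FALSE]
  both <- qn > 0 & qp > 0
  hbar <- ifelse(both, (hn + hp) / 2, ifelse(qn > 0, hn, hp))
  dh <- ifelse(both, hn - hp, 0)
  qbar <- (qn + qp) / 2
  pad <- function(mm) { # restore full year rows, NA where undefined
    out <- matrix(NA_real_, ny, na)
    out[rows, ] <- mm
    out
  }
  fa <- FA[rows, , , drop = FALSE]
  fb <- FB[rows, , , drop = FALSE]
  fc <- FC[rows, , , drop = FALSE]
  list(
    A = pad(rowSums(fa, dims = 2)),
    B = pad(rowSums(fb, dims = 2)),
    C = pad(rowSums(fc, dims = 2)),
    AH = pad(rowSums(fa * hbar, dims = 2)),
    BH = pad(rowSums(fb * hbar, dims = 2)),
    CH = pad(rowSums(fc * hbar, dims = 2)),
    QDH = pad(rowSums(qbar * dh, dims = 2)),
    QBAR = pad(rowSums(qbar, dims = 2))
  )
}

# stencil differences/means for every analysis year; returns per-year list of
# (upper row index r, step s, divisor span). Internal.
year_stencils <- function(ny) {
  lapply(seq_len(ny), function(i) {
    if (i == 1) list(r = 2L, s = 1L, span = 1, interior = FALSE)
    else if (i == ny) list(r = ny, s = 1L, span = 1, interior = FALSE)
    else list(r = i + 1L, s = 2L, span = 2, interior = TRUE)
  })
}

#' Partition the prevalence trend into determinant contributions
#'
#' Decomposes the logarithmic derivative of age-adjusted prevalence exactly
#' into additive per-year contributions (1/year): `T0` from the pre-age-65
#' prevalent pool, `T00` from the pre-boundary pool, `Tinc` from disease
#' incidence, and `Ts` from survival of cases diagnosed inside the window,
#' with `T0 + T00 + Tinc + Ts` equal to the central-difference log-derivative
#' of `P` in every year. `Tinc` and `Ts` come from an exact cohort-diagonal
#' split of the incident-pool change into inflow-history and
#' survival-continuation parts, so both vanish when incidence and survival are
#' time-constant. `T00` carries, besides the drainage of the pre-boundary
#' prevalent pool itself, the boundary carry of the incident pool: the
#' replacement transient by which incident cases fill the space the boundary
#' cohort vacates, plus any part of a cohort diagonal that leaves the observed
#' window. Gross inflow and mortality-outflow rates are attached as
#' diagnostics (`tinc_gross`, `touflow_gross`, also 1/year).
#'
#' @param table A [build_person_year_table()] result (the `incident_lag`
#'   attribute is required).
#' @param weights From [standard_weights()].
#' @param series_source `"smoothed"` (default): cell series are
#'   spline-smoothed across years and the sparse lag-resolved death rates are
#'   replaced by a pooled excess-hazard model (a fixed duration profile times
#'   a smooth calendar multiplier), stabilizing the derivatives the way the
#'   field's parametric trend models do. `"raw"` differences the empirical
#'   cells directly (useful for identity checks; noisy derivatives).
#' @param df Spline degrees of freedom for `"smoothed"`.
#' @return Tibble of class `prevalence_partition`: `year`, levels `P`, `P0`,
#'   `P00`, `Pis` (per 100 person-years), derivative `D` and contributions
#'   `T0`, `T00`, `Tinc`, `Ts` (1/year), diagnostics, and an `interior` flag
#'   (first/last year use one-sided differences).
#' @export
partition_prevalence <- function(table, weights,
                                 series_source = c("smoothed", "raw"), df = 4) {
  pc <- partition_cells(table, weights, series_source, df)
  m <- pc$cells
  w <- pc$w
  ny <- length(pc$years)
  if (ny < 3) stop("need at least 3 years to partition", call. = FALSE)

  P0 <- as.numeric(m$pi0 %*% w)
  P00 <- as.numeric(m$pi00 %*% w)
  Pis <- as.numeric(m$pis %*% w)
  P <- P0 + P00 + Pis
  if (any(P <= 0)) stop("prevalence is zero in some year; cannot partition", call. = FALSE)

  ab1 <- ab_split(pc, 1L)
  ab2 <- ab_split(pc, 2L)

  st <- year_stencils(ny)
  res <- purrr::map(seq_len(ny), function(i) {
    z <- st[[i]]
    ab <- if (z$s == 1L) ab1 else ab2
    den <- z$span * P[i]
    tibble::tibble(
      D = (P[z$r] - P[z$r - z$s]) / den,
      T0 = (P0[z$r] - P0[z$r - z$s]) / den,
      T00 = (P00[z$r] - P00[z$r - z$s] + sum(ab$C[z$r, ] * w)) / den,
      Tinc = sum(ab$A[z$r, ] * w) / den,
      Ts = sum(ab$B[z$r, ] * w) / den,
      interior = z$interior
    )
  }) |> purrr::list_rbind()

  out <- dplyr::bind_cols(
    tibble::tibble(year = pc$years,
                   P = 100 * P, P0 = 100 * P0, P00 = 100 * P00,
                   Pis = 100 * Pis),
    res,
    tibble::tibble(
      tinc_gross = as.numeric(m$inflow %*% w) / P,
      touflow_gross = -as.numeric(m$outflow_is %*% w) / P
    )
  )
  structure(out, class = c("prevalence_partition", class(out)),
            source = pc$source, df = pc$df, ages = pc$ages)
}

#' Partition the incidence-based mortality trend into determinant contributions
#'
#' Decomposes the logarithmic derivative of age-adjusted IBM exactly into
#' additive per-year contributions (1/year): `Tmu` from general-population
#' mortality, `T0` and `T00` from the two pre-existing prevalent pools,
#' `Tinc` from disease incidence, and `Tsur` from survival after diagnosis
#' (both the size of the surviving prevalent pool and the case-fatality level
#' of its members at fixed duration), with the five terms summing to the
#' central-difference log-derivative of `M` in every year. Cell-level
#' products `pi_c(y,a) * h_c(y,a)` are differenced with the exact midpoint
#' (Bennet) product rule; the incident-pool change is split with the same
#' cohort-diagonal recursion as [partition_prevalence()], and `T00` likewise
#' absorbs the boundary carry. Duration-composition drift of the incident
#' pool (maturation) is excluded from `Tsur` by construction: death rates are
#' compared at fixed diagnosis-year lag only.
#'
#' @inheritParams partition_prevalence
#' @return Tibble of class `ibm_partition`: `year`, levels `M`, `Mmu`, `M0`,
#'   `M00`, `Mis` (per 100,000 person-years), derivative `D` and contributions
#'   `Tmu`, `T0`, `T00`, `Tinc`, `Tsur` (1/year), the prevalence log-derivative
#'   `tp_prev` as a diagnostic, and an `interior` flag.
#' @export
partition_ibm <- function(table, weights,
                          series_source = c("smoothed", "raw"), df = 4) {
  pc <- partition_cells(table, weights, series_source, df)
  m <- pc$cells
  w <- pc$w
  ny <- length(pc$years)
  if (ny < 3) stop("need at least 3 years to partition", call. = FALSE)

  rho0 <- m$pi0 * m$h0
  rho00 <- m$pi00 * m$h00
  rhois <- rowSums(pc$q * pc$h, dims = 2)
  his <- ifelse(m$pis > 0, rhois / m$pis, 0)
  pprev <- m$pi0 + m$pi00 + m$pis

  M <- as.numeric((rho0 + rho00 + rhois) %*% w)
  Mmu <- as.numeric((pprev * m$mu) %*% w)
  M0 <- as.numeric((m$pi0 * (m$h0 - m$mu)) %*% w)
  M00 <- as.numeric((m$pi00 * (m$h00 - m$mu)) %*% w)
  Mis <- as.numeric((m$pis * (his - m$mu)) %*% w)
  P <- as.numeric(pprev %*% w)
  if (any(M <= 0)) stop("IBM is zero in some year; cannot partition", call. = FALSE)

  ab1 <- ab_split(pc, 1L)
  ab2 <- ab_split(pc, 2L)

  st <- year_stencils(ny)
  res <- purrr::map(seq_len(ny), function(i) {
    z <- st[[i]]
    r <- z$r; s <- z$s
    dd <- function(x) x[r, ] - x[r - s, ]
    bb <- function(x) (x[r, ] + x[r - s, ]) / 2
    adj <- function(pi_mat, h_mat) { # one-sided pools: no readable h trend
      ok <- pi_mat[r, ] > 0 & pi_mat[r - s, ] > 0
      list(hbar = ifelse(ok, (h_mat[r, ] + h_mat[r - s, ]) / 2,
                         ifelse(pi_mat[r, ] > 0, h_mat[r, ], h_mat[r - s, ])),
           dh = ifelse(ok, h_mat[r, ] - h_mat[r - s, ], 0))
    }
    a0 <- adj(m$pi0, m$h0)
    a00 <- adj(m$pi00, m$h00)
    ab <- if (s == 1L) ab1 else ab2
    den <- z$span * M[i]
    dmu <- dd(m$mu)
    tibble::tibble(
      D = (M[z$r] - M[z$r - z$s]) / den,
      Tmu = sum((bb(m$pi0) + bb(m$pi00) + ab$QBAR[r, ]) * dmu * w) / den,
      T0 = sum((dd(m$pi0) * a0$hbar + bb(m$pi0) * (a0$dh - dmu)) * w) / den,
      T00 = sum((dd(m$pi00) * a00$hbar + bb(m$pi00) * (a00$dh - dmu) +
                   ab$CH[r, ]) * w) / den,
      Tinc = sum(ab$AH[r, ] * w) / den,
      Tsur = sum((ab$BH[r, ] + ab$QDH[r, ] - ab$QBAR[r, ] * dmu) * w) / den,
      tp_prev = (P[z$r] - P[z$r - z$s]) / (z$span * P[i]),
      interior = z$interior
    )
  }) |> purrr::list_rbind()

  out <- dplyr::bind_cols(
    tibble::tibble(year = pc$years,
                   M = 1e5 * M, Mmu = 1e5 * Mmu, M0 = 1e5 * M0,
                   M00 = 1e5 * M00, Mis = 1e5 * Mis),
    res
  )
  structure(out, class = c("ibm_partition", class(out)),
            source = pc$source, df = pc$df, ages = pc$ages)
}

#' Relative contributions of the partitioned determinants
#'
#' Expresses each contribution as a percentage of the derivative,
#' `100 * T_k(y) / D(y)`, so that the percentages sum to 100 within a year. A
#' positive percentage means the determinant pushes in the same direction as
#' the overall trend, a negative one the opposite. Years where `|D|` falls
#' below `floor` are suppressed (the division blows up near trend reversals);
#' boundary years (one-sided differences) are excluded unless requested.
#'
#' @param partition A [partition_prevalence()] or [partition_ibm()] result.
#' @param floor Minimum `|D|` (1/year) for a year to be emitted.
#' @param include_boundary Keep the first/last (one-sided) years?
#' @return Tibble of class `contribution_table`: `year`, `determinant`,
#'   `share_pct`; suppressed years are recorded in the `suppressed` attribute.
#' @export
relative_contributions <- function(partition, floor = 1e-6,
                                   include_boundary = FALSE) {
  terms <- if (inherits(partition, "ibm_partition")) {
    c(general_mortality = "Tmu", pre65 = "T0", preboundary = "T00",
      incidence = "Tinc", survival = "Tsur")
  } else {
    c(pre65 = "T0", preboundary = "T00", incidence = "Tinc", survival = "Ts")
  }
  x <- tibble::as_tibble(partition)
  if (!include_boundary) x <- dplyr::filter(x, .data$interior)
  suppressed <- x$year[abs(x$D) < floor]
  if (length(suppressed)) {
    message("relative_contributions: suppressing year(s) with near-zero derivative: ",
            paste(suppressed, collapse = ", "))
  }
  x <- dplyr::filter(x, abs(.data$D) >= floor)
  out <- purrr::imap(terms, function(col, det) {
    tibble::tibble(year = x$year, determinant = det,
                   share_pct = 100 * x[[col]] / x$D)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(determinant = factor(.data$determinant, levels = names(terms))) |>
    dplyr::arrange(.data$year, .data$determinant)
  structure(out, class = c("contribution_table", class(out)),
            suppressed = suppressed)
}

#' Classify trend phases from the derivative series
#'
#' Labels each year by the signs of the derivative `D` and of its central
#' difference `dD`: increasing vs declining from `sign(D)`, accelerated vs
#' decelerated from whether the trend is moving away from or toward zero
#' change. A year with `D = 0` is an inflection and inherits its label from
#' the neighboring years.
#'
#' @param partition A partition object, or any tibble with `year` and `D`
#'   columns.
#' @return Tibble `year`, `D`, `dD`, `phase` (factor with levels
#'   `accelerated increasing`, `decelerated increasing`,
#'   `accelerated declining`, `decelerated declining`).
#' @export
classify_phases <- function(partition) {
  x <- dplyr::arrange(tibble::as_tibble(partition), .data$year)
  stopifnot("D" %in% names(x))
  if (nrow(x) < 3) stop("need D on at least 3 consecutive years", call. = FALSE)
  D <- x$D
  n <- length(D)
  dD <- (c(D[2], D[3:n], D[n]) - c(D[1], D[1:(n - 2)], D[n - 1])) /
    c(1, rep(2, n - 2), 1)
  lab <- dplyr::case_when(
    D > 0 & dD >= 0 ~ "accelerated increasing",
    D > 0 & dD < 0 ~ "decelerated increasing",
    D < 0 & dD <= 0 ~ "accelerated declining",
    D < 0 & dD > 0 ~ "decelerated declining",
    TRUE ~ NA_character_
  )
  # D exactly zero: inflection, take the next year's label (else previous)
  if (anyNA(lab)) {
    for (i in which(is.na(lab))) {
      lab[i] <- if (i < n && !is.na(lab[i + 1])) lab[i + 1] else lab[max(i - 1, 1)]
    }
  }
  tibble::tibble(
    year = x$year, D = D, dD = dD,
    phase = factor(lab, levels = c("accelerated increasing",
                                   "decelerated increasing",
                                   "accelerated declining",
                                   "decelerated declining"))
  )
}

#' @export
tidy.prevalence_partition <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("T0", "T00", "Tinc", "Ts"),
                        names_to = "term", values_to = "contribution") |>
    dplyr::select("year", "D", "term", "contribution", "interior")
}

#' @export
tidy.ibm_partition <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("Tmu", "T0", "T00", "Tinc", "Tsur"),
                        names_to = "term", values_to = "contribution") |>
    dplyr::select("year", "D", "term", "contribution", "interior")
}

#' @export
glance.prevalence_partition <- function(x, ...) {
  closure <- abs(x$T0 + x$T00 + x$Tinc + x$Ts - x$D)
  tibble::tibble(
    n_years = nrow(x),
    source = attr(x, "source"),
    max_closure_err = max(closure / pmax(abs(x$D), 1e-12))
  )
}

#' @export
glance.ibm_partition <- function(x, ...) {
  closure <- abs(x$Tmu + x$T0 + x$T00 + x$Tinc + x$Tsur - x$D)
  tibble::tibble(
    n_years = nrow(x),
    source = attr(x, "source"),
    max_closure_err = max(closure / pmax(abs(x$D), 1e-12))
  )
}
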