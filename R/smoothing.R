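#' Fit a smooth model-based trend to an annual rate or proportion series
#'
#' Empirical annual series are noisy; model-based trend curves supply the
#' smooth series used for plotting and for derivative-based partitioning. The
#' model is a natural cubic spline in calendar year, fitted by least squares on
#' the log scale for rates (guaranteeing positive fitted values) and on the
#' logit scale for survival proportions (keeping fitted values inside (0, 1)).
#'
#' @param series Tibble with `year` and `value` columns.
#' @param kind `"rate"` (log link) or `"proportion"` (logit link).
#' @param df Spline degrees of freedom (default 4); must be >= 2, and the
#'   series must have at least `df + 2` years.
#' @return Object of class `trend_fit`: the data with fitted values, the
#'   model, and agreement statistics (see [goodness_of_fit()]).
#' @examples
#' s <- tibble::tibble(year = 1992:2017, value = 25 * exp(-0.02 * (0:25)))
#' fit <- fit_trend(s, "rate", df = 3)
#' glance(fit)
#' @export
fit_trend <- function(series, kind = c("rate", "proportion"), df = 4) {
  kind <- match.arg(kind)
  stopifnot(all(c("year", "value") %in% names(series)))
  if (df < 2) stop("`df` must be at least 2", call. = FALSE)
  series <- dplyr::arrange(series, .data$year)
  n <- nrow(series)
  if (n < df + 2) {
    stop(sprintf("need at least df + 2 = %d years, got %d", df + 2, n),
         call. = FALSE)
  }
  if (kind == "rate" && any(series$value <= 0)) {
    stop("rates must be positive for log-scale fitting", call. = FALSE)
  }
  if (kind == "proportion" && any(series$value <= 0 | series$value >= 1)) {
    stop("proportions must lie strictly inside (0, 1)", call. = FALSE)
  }
  link <- if (kind == "rate") log else stats::qlogis
  inv <- if (kind == "rate") exp else stats::plogis
  d <- data.frame(year = series$year, ty = link(series$value))
  model <- stats::lm(ty ~ splines::ns(year, df = df), data = d)
  fitted <- unname(inv(stats::predict(model, newdata = d)))
  out <- structure(
    list(
      series = dplyr::mutate(series, fitted = fitted),
      kind = kind, df = df, model = model,
      coefficients = stats::coef(model)
    ),
    class = "trend_fit"
  )
  out$fit_stats <- goodness_of_fit(out)
  out
}

#' Agreement between empirical and model-based estimates
#'
#' Maximum and mean absolute relative deviation of fitted from observed values
#' over the years of the series; small values indicate the smooth model tracks
#' the empirical estimates closely. Years with a zero observed value are
#' excluded (with a message) since relative deviation is undefined there.
#'
#' @param fit A [fit_trend()] object.
#' @return Tibble with `max_abs_rel_dev`, `mean_abs_rel_dev`, `n_years`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  s <- fit$series
  zero <- s$value == 0
  if (any(zero)) {
    message(sprintf("goodness_of_fit: excluding %d year(s) with zero observed value",
                    sum(zero)))
    s <- s[!zero, ]
  }
  rel <- abs(s$fitted - s$value) / s$value
  tibble::tibble(
    max_abs_rel_dev = max(rel),
    mean_abs_rel_dev = mean(rel),
    n_years = nrow(s)
  )
}

#' Average annual log-slope of a fitted trend
#'
#' Convenience summary: `(log f(last) - log f(first)) / (last - first)` of the
#' fitted curve, i.e. the mean exponential growth rate per year.
#'
#' @param fit A [fit_trend()] object.
#' @return A single number (1/year).
#' @export
trend_log_slope <- function(fit) {
  s <- fit$series
  span <- s$year[nrow(s)] - s$year[1]
  (log(s$fitted[nrow(s)]) - log(s$fitted[1])) / span
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s, natural spline df = %d, %d years\n",
              x$kind, x$df, nrow(x$series)))
  cat(sprintf("  max |rel dev| = %.4f, mean = %.4f\n",
              x$fit_stats$max_abs_rel_dev, x$fit_stats$mean_abs_rel_dev))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.trend_fit <- function(x, ...) {
  dplyr::mutate(x$series,
                rel_dev = ifelse(.data$value != 0,
                                 (.data$fitted - .data$value) / .data$value,
                                 NA_real_))
}

#' @export
glance.trend_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(kind = x$kind, df = x$df),
    x$fit_stats,
    tibble::tibble(rss = sum(stats::resid(x$model)^2))
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.trend_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 1.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8) +
    ggplot2::labs(x = "calendar year",
                  y = if (object$kind == "rate") "rate" else "proportion",
                  title = "Empirical estimates (dots) and model-based trend (line)") +
    ggplot2::theme_minimal()
}

# Smooth a cell-level quantity across years within each age with a natural
# spline on the identity scale, clamping at zero. Used by the partition module
# to stabilize derivative estimation; identity-scale fitting tolerates empty
# cells, and every additive identity is re-derived from the smoothed cells so
# exact closure survives smoothing. Internal.
smooth_cells <- function(x, value_cols, df = 4, group = "age", fit_rows = NULL) {
  yrs <- sort(unique(x$year))
  if (length(yrs) < df + 2) return(x)
  basis <- splines::ns(yrs, df = df)
  x$.fit <- if (is.null(fit_rows)) TRUE else fit_rows
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$year), ]
      use <- d$.fit
      if (sum(use) < df + 2) return(d)
      bx <- basis[match(d$year, yrs), , drop = FALSE]
      for (v in value_cols) {
        if (all(d[[v]][use] == 0)) next
        fit <- stats::lm.fit(cbind(1, bx[use, , drop = FALSE]), d[[v]][use])
        d[[v]][use] <- pmax(
          as.numeric(cbind(1, bx[use, , drop = FALSE]) %*% fit$coefficients), 0)
      }
      d
    }) |>
    dplyr::ungroup()
  out$.fit <- NULL
  out
}
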