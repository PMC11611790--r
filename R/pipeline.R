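#' Run the full synthetic partitioning study end to end
#'
#' Orchestrates simulate (or load) -> coverage filter -> onset ascertainment ->
#' person-year table -> rates and survival -> trend smoothing -> partitioning,
#' and writes every table, four figures, and a run manifest to `out_dir`. The
#' run is deterministic given the configuration seed: rerunning with the same
#' config reproduces byte-identical CSVs.
#'
#' Files written: `persons.csv`, `claims.csv`, `person_year_table.csv`,
#' `rates.csv`, `survival.csv`, `fits.csv`, `partition_prevalence.csv`,
#' `partition_ibm.csv`, `contributions.csv`, `phases.csv`, `manifest.yaml`,
#' and figures `fig_incidence_fit`, `fig_survival_fit`, `fig_levels`,
#' `fig_derivatives` (PNG).
#'
#' @param config A [sim_config()]; ignored when `input_dir` is given except
#'   for the analysis window and ages.
#' @param out_dir Output directory (created if needed).
#' @param input_dir Optional directory with `persons.csv` / `claims.csv` to
#'   analyze instead of simulating.
#' @param weights Standard weights (default uniform over the analysis ages);
#'   a data frame or CSV path, see [standard_weights()].
#' @param series_source `"smoothed"` or `"raw"` series for partitioning.
#' @param df Spline degrees of freedom for smoothing.
#' @return Invisibly, a list of class `pipeline_result` with every intermediate
#'   object (`cohort`, `persons`, `onsets`, `table`, `rates`, `survival`,
#'   `fits`, `partition_prev`, `partition_ibm`, `contributions`, `phases`) and
#'   the output paths.
#' @export
run_pipeline <- function(config, out_dir, input_dir = NULL,
                         weights = NULL,
                         series_source = c("smoothed", "raw"), df = 4) {
  series_source <- match.arg(series_source)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  years <- c(config$year_start, ceiling(config$year_end) - 1)
  ages <- c(config$age_min, config$age_max)
  w <- standard_weights(ages[1]:ages[2], weights)

  if (is.null(input_dir)) {
    cohort <- simulate_cohort(config)
  } else {
    raw <- read_cohort(input_dir)
    cohort <- structure(list(persons = raw$persons, claims = raw$claims,
                             config = config), class = "sim_cohort")
  }
  write_cohort(cohort, out_dir)

  persons <- apply_coverage_filter(cohort$persons)
  hf_claims <- dplyr::filter(
    dplyr::semi_join(cohort$claims, persons, by = "person_id"),
    grepl("^(428|I50)", .data$dx_code)
  )
  onsets <- identify_onset(hf_claims, persons) |>
    classify_onset(persons, boundary_year = config$year_start)
  table <- build_person_year_table(persons, onsets, years, ages)
  write_person_year_table(table, file.path(out_dir, "person_year_table.csv"),
                          file.path(out_dir, "person_year_lag.csv"))

  prev <- prevalence_series(table, w)
  inc <- incidence_series(table, w)
  ibm <- ibm_series(table, w)
  rates <- prev |>
    dplyr::left_join(inc, by = "year") |>
    dplyr::left_join(ibm, by = "year")
  readr::write_csv(rates, file.path(out_dir, "rates.csv"))

  surv <- km_survival(persons, onsets, last_year = years[2]) |>
    relative_survival(table, persons, onsets)
  surv_wide <- surv |>
    tidyr::pivot_wider(id_cols = "diag_year", names_from = "horizon",
                       values_from = c("observed", "relative"),
                       names_glue = "{ifelse(.value == 'observed', 'S', 'R')}{horizon}")
  readr::write_csv(surv_wide, file.path(out_dir, "survival.csv"))

  # the boundary year has no ascertainable incidence (its onsets are folded
  # into the pre-boundary pool), so the trend is fitted on positive years
  fits <- list(
    incidence = fit_trend(dplyr::filter(
      dplyr::transmute(inc, .data$year, value = .data$incidence),
      .data$value > 0), "rate", df = df),
    prevalence = fit_trend(dplyr::transmute(prev, .data$year, value = .data$P),
                           "rate", df = df),
    IBM = fit_trend(dplyr::transmute(ibm, .data$year, value = .data$M),
                    "rate", df = df)
  )
  for (k in sort(unique(surv$horizon))) {
    sk <- surv |>
      dplyr::filter(.data$horizon == k, .data$observed > 0, .data$observed < 1) |>
      dplyr::transmute(year = .data$diag_year, value = .data$observed)
    if (nrow(sk) >= df + 2) {
      fits[[paste0("S", k)]] <- fit_trend(sk, "proportion", df = df)
    }
  }
  fits_tbl <- purrr::imap(fits, function(f, nm) {
    dplyr::transmute(f$series, target = nm, .data$year,
                     observed = .data$value, .data$fitted)
  }) |> purrr::list_rbind()
  readr::write_csv(fits_tbl, file.path(out_dir, "fits.csv"))

  part_prev <- partition_prevalence(table, w, series_source, df)
  part_ibm <- partition_ibm(table, w, series_source, df)
  readr::write_csv(tibble::as_tibble(part_prev),
                   file.path(out_dir, "partition_prevalence.csv"))
  readr::write_csv(tibble::as_tibble(part_ibm),
                   file.path(out_dir, "partition_ibm.csv"))

  contrib <- dplyr::bind_rows(
    prevalence = tibble::as_tibble(relative_contributions(part_prev)),
    IBM = tibble::as_tibble(relative_contributions(part_ibm)),
    .id = "outcome"
  )
  readr::write_csv(contrib, file.path(out_dir, "contributions.csv"))

  phases <- dplyr::bind_rows(
    prevalence = classify_phases(part_prev),
    IBM = classify_phases(part_ibm),
    .id = "outcome"
  )
  readr::write_csv(phases, file.path(out_dir, "phases.csv"))

  res <- structure(
    list(cohort = cohort, persons = persons, onsets = onsets, table = table,
         rates = rates, survival = surv, fits = fits,
         partition_prev = part_prev, partition_ibm = part_ibm,
         contributions = contrib, phases = phases, out_dir = out_dir),
    class = "pipeline_result"
  )

  plot_pipeline(res, out_dir)

  manifest <- list(
    config = config_as_list(config),
    weights = "uniform-or-user-supplied",
    series_source = series_source, df = df,
    input_dir = if (is.null(input_dir)) NA else input_dir,
    file_md5 = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    ))
  )
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d persons -> %d analysis years, outputs in %s\n",
              nrow(x$persons), nrow(x$rates), x$out_dir))
  invisible(x)
}

#' Figures for a pipeline run
#'
#' Writes the four standard figures (empirical dots vs model lines for
#' incidence and survival; levels with components; derivatives with
#' partitioned determinants) to `dir` as PNG.
#'
#' @param res A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Invisibly, the named list of ggplot objects.
#' @export
plot_pipeline <- function(res, dir) {
  plots <- list(
    fig_incidence_fit = autoplot(res$fits$incidence) +
      ggplot2::labs(y = "incidence per 1000 person-years"),
    fig_survival_fit = plot_survival_fit(res$survival, res$fits),
    fig_levels = plot_levels(res$partition_prev, res$partition_ibm),
    fig_derivatives = plot_derivatives(res$partition_prev, res$partition_ibm)
  )
  dev <- if (isTRUE(capabilities("png"))) "png" else "pdf"
  for (nm in names(plots)) {
    ggplot2::ggsave(file.path(dir, paste0(nm, ".", dev)), plots[[nm]],
                    width = 8, height = 5, dpi = 120)
  }
  invisible(plots)
}

#' @rdname plot_pipeline
#' @param survival Long survival tibble from [relative_survival()].
#' @param fits Named list of [fit_trend()] objects (entries `S1`, `S3`, `S5`
#'   used when present).
#' @export
plot_survival_fit <- function(survival, fits = list()) {
  p <- ggplot2::ggplot(survival,
                       ggplot2::aes(x = .data$diag_year, y = .data$observed,
                                    colour = factor(.data$horizon))) +
    ggplot2::geom_point(size = 1.6)
  lines <- purrr::imap(fits, function(f, nm) {
    if (!grepl("^S[0-9]+$", nm)) return(NULL)
    dplyr::mutate(f$series, horizon = sub("^S", "", nm))
  }) |> purrr::compact() |> purrr::list_rbind()
  if (!is.null(lines) && nrow(lines)) {
    p <- p + ggplot2::geom_line(
      data = lines,
      ggplot2::aes(x = .data$year, y = .data$fitted,
                   colour = .data$horizon),
      linewidth = 0.8, inherit.aes = FALSE
    )
  }
  p + ggplot2::labs(x = "year of diagnosis", y = "survival proportion",
                    colour = "horizon (years)",
                    title = "Observed survival (dots) and model-based trend (lines)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pipeline
#' @param part_prev,part_ibm Partition objects.
#' @export
plot_levels <- function(part_prev, part_ibm) {
  pl <- tibble::as_tibble(part_prev) |>
    tidyr::pivot_longer(c("P", "P0", "P00", "Pis"),
                        names_to = "component", values_to = "value") |>
    dplyr::mutate(outcome = "prevalence (per 100 py)")
  ml <- tibble::as_tibble(part_ibm) |>
    tidyr::pivot_longer(c("M", "Mmu", "M0", "M00", "Mis"),
                        names_to = "component", values_to = "value") |>
    dplyr::mutate(outcome = "IBM (per 100,000 py)")
  ggplot2::ggplot(dplyr::bind_rows(pl, ml),
                  ggplot2::aes(.data$year, .data$value,
                               colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "calendar year", y = NULL,
                  title = "Levels and partitioned components") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pipeline
#' @export
plot_derivatives <- function(part_prev, part_ibm) {
  d <- dplyr::bind_rows(
    prevalence = tidy(part_prev),
    IBM = tidy(part_ibm),
    .id = "outcome"
  ) |> dplyr::filter(.data$interior)
  dd <- dplyr::distinct(d, .data$outcome, .data$year, .data$D)
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$contribution,
                                  colour = .data$term)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_line(data = dd,
                       ggplot2::aes(.data$year, .data$D), colour = "black",
                       linewidth = 0.9) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "calendar year", y = "contribution (1/year)",
                  title = "Log-derivatives (black) and partitioned determinants") +
    ggplot2::theme_minimal()
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom dplyr n
NULL
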