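#' Run the full synthetic-city analysis pipeline
#'
#' Chains every stage of the analysis on self-generated data: city
#' generation, CSV export, segregation indices, the two-stage bias fit with
#' learning rates and variance decomposition, split-half noise ceiling, and
#' Granger temporal-precedence summaries on a multi-year panel.  All
#' randomness derives from \code{seed}, so the same seed reproduces a
#' byte-identical \code{report.json}.
#'
#' @param out_dir output directory for the CSV tables and
#'   \code{report.json}.
#' @param seed integer master seed.
#' @param n_cities number of cross-sectional cities.
#' @param n_panel_cities,n_years panel dimensions for the precedence stage.
#' @param params \code{\link{model_parameters}}.
#' @param measure segregation measure for the fit.
#' @param min_responses respondent filter for retained cities.
#' @param n_respondents respondents generated per city.
#' @param n_splits noise-ceiling split permutations.
#' @param n_boot precedence bootstrap replicates.
#' @param coupling panel coupling passed to \code{\link{generate_panel}}.
#' @param pop_range population range for the generator.
#' @return invisibly, the report list (also written as
#'   \code{report.json}).
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_cities = 150L,
                         n_panel_cities = 43L, n_years = 10L,
                         params = model_parameters(),
                         measure = "mean_deviance", min_responses = 500,
                         n_respondents = 1000L, n_splits = 100L,
                         n_boot = 200L,
                         coupling = list(direction = "structural_to_bias",
                                         lag = 1L, strength = 3,
                                         noise_sd = 0.05),
                         pop_range = c(5e4, 2e6)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cities <- generate_cities(n_cities, params, pop_range = pop_range,
                            seed = seed)
  seg <- segregation_values(cities, measure)
  obs <- generate_bias(cities, params, n_respondents = n_respondents,
                       measure = measure, seg = seg, seed = seed + 1L)
  respondents <- generate_individuals(obs, params, seed = seed + 2L)
  write_city_data(cities, out_dir, bias = obs, respondents = respondents)
  seg_long <- do.call(rbind, lapply(cities, segregation_measures))
  utils::write.csv(format_reals(seg_long),
                   file.path(out_dir, "segregation.csv"),
                   row.names = FALSE, quote = FALSE)

  fit <- bias_model(obs, cities, measure = measure,
                    min_responses = min_responses, delta = params$delta,
                    seg = seg)
  ceiling <- noise_ceiling(respondents, n_splits = n_splits,
                           seed = seed + 3L)
  panels <- generate_panel(n_panel_cities, n_years, coupling = coupling,
                           seed = seed + 4L)
  precedence <- precedence_summary(panels, n_boot = n_boot,
                                   seed = seed + 5L)
  utils::write.csv(format_reals(as.data.frame(precedence)),
                   file.path(out_dir, "precedence.csv"),
                   row.names = FALSE, quote = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("urbanbias")),
    seed = seed,
    config = list(n_cities = n_cities, n_panel_cities = n_panel_cities,
                  n_years = n_years, measure = measure,
                  min_responses = min_responses,
                  n_respondents = n_respondents, n_splits = n_splits,
                  n_boot = n_boot, pop_range = pop_range,
                  params = unclass(params), coupling = coupling),
    scaling = list(C = fit$scaling$C, beta1 = fit$scaling$beta1,
                   ci_beta1 = fit$scaling$ci_beta1, r2 = fit$scaling$r2,
                   n_cities = fit$scaling$n_cities),
    adjustments = list(C2 = fit$adjustments$C2,
                       beta2 = fit$adjustments$beta2,
                       ci_beta2 = fit$adjustments$ci_beta2,
                       beta3 = fit$adjustments$beta3,
                       ci_beta3 = fit$adjustments$ci_beta3),
    learning_rates = unclass(fit$learning_rates),
    decomposition = fit$decomposition,
    vif = as.list(fit$vif),
    noise_ceiling = list(lower = ceiling$lower, upper = ceiling$upper,
                         noise_corrected_r2 = noise_corrected_r2(
                           fit$decomposition$total, ceiling)),
    precedence = as.data.frame(precedence)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
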