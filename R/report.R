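#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: validates the inputs, calibrates
#' each strategy's non-indicated CS probabilities to its target CS rate,
#' runs the Monte Carlo cohort for each strategy, builds the
#' cost-effectiveness frontier, produces outcome reports and strategy
#' difference tables, and (optionally) the sensitivity analyses. All outputs
#' are written as plain CSV with fixed column order plus a JSON manifest
#' (seed, package version, input hashes) sufficient for bit-exact re-runs.
#'
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @param registry Parameter registry.
#' @param prior_tab Prior-CS probability table.
#' @inheritParams run_cohort
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param population Reference population for national extrapolation.
#' @param grid_step,tolerance Calibration controls.
#' @param sensitivity Also run the one-way and two-way analyses (slower).
#' @return Invisibly, a list: calibrations, cohort results, frontier,
#'   outcome reports, difference tables, optimal strategy and manifest.
#' @export
run_full_analysis <- function(out_dir = NULL, registry = param_registry(),
                              prior_tab = prior_cs_table(),
                              n_women = 10000L, horizon = 35L, seed = 1L,
                              wtp = WTP_DEFAULT,
                              population = POPULATION_DEFAULT,
                              grid_step = 0.001, tolerance = 0.005,
                              sensitivity = FALSE) {
  params <- baseline_params(registry)
  cal <- calibrate_strategies(NULL, params, prior_tab,
                              horizon = horizon, grid_step = grid_step,
                              tolerance = tolerance)
  strats <- cal$strategies
  results <- lapply(seq_len(nrow(strats)), function(i) {
    run_cohort(strats[i, ], params, prior_tab, n_women = n_women,
               horizon = horizon, seed = seed)
  })
  names(results) <- strats$id
  frontier <- build_frontier(results)
  optimal <- select_optimal(frontier, wtp)
  outcomes <- lapply(results, summarize_outcomes, population = population)
  diffs <- lapply(setdiff(names(outcomes), "A_national"), function(s) {
    difference_table(outcomes[["A_national"]], outcomes[[s]])
  })
  names(diffs) <- setdiff(names(outcomes), "A_national")
  sens <- NULL
  if (sensitivity) {
    sens <- list(
      one_way = one_way_sensitivity(params = params, prior_tab = prior_tab,
                                    strats = strats, horizon = horizon,
                                    wtp = wtp, registry = registry),
      two_way = two_way_sensitivity(params = params, prior_tab = prior_tab,
                                    strats = strats, horizon = horizon,
                                    wtp = wtp)
    )
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cesim")),
    seed = as.integer(seed), n_women = as.integer(n_women),
    horizon = as.integer(horizon), wtp = wtp, population = population,
    grid_step = grid_step, tolerance = tolerance,
    registry_hash = rlang::hash(registry),
    prior_cs_hash = rlang::hash(prior_tab),
    optimal = optimal
  )
  out <- list(calibrations = cal$calibrations, strategies = strats,
              results = results, frontier = frontier, outcomes = outcomes,
              differences = diffs, optimal = optimal, sensitivity = sens,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(
      dplyr::bind_rows(lapply(cal$calibrations, glance)),
      file.path(out_dir, "calibration.csv"))
    readr::write_csv(dplyr::bind_rows(lapply(results, glance)),
                     file.path(out_dir, "cohort_results.csv"))
    fr <- as_tibble(frontier)
    fr$cost <- round(fr$cost, 2)
    fr$icer <- round(fr$icer, 2)
    readr::write_csv(fr, file.path(out_dir, "frontier.csv"))
    for (s in names(outcomes)) {
      readr::write_csv(outcomes[[s]]$events,
                       file.path(out_dir, paste0("outcomes_", s, ".csv")))
    }
    for (s in names(diffs)) {
      readr::write_csv(diffs[[s]],
                       file.path(out_dir, paste0("differences_A_vs_", s, ".csv")))
    }
    if (!is.null(sens)) {
      readr::write_csv(sens$one_way, file.path(out_dir, "one_way.csv"))
      readr::write_csv(sens$two_way, file.path(out_dir, "two_way.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
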