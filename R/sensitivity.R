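#' Parameters examined in one-way sensitivity analysis
#'
#' The deterministically swept inputs: PPH probabilities (vaginal, previa,
#' accreta, rupture), TOLAC conversion, uterine rupture, ICU admission and
#' hysterectomy probabilities, the mortality probabilities (PPH, indicated
#' ante-/intrapartum CS, ICU) and the ICU, CS and vaginal-delivery costs.
#'
#' @return Character vector of parameter ids.
#' @export
one_way_parameters <- function() {
  c("p_pph_vaginal", "p_pph_previa", "p_pph_accreta", "p_pph_rupture",
    "p_intra_cs_tolac", "p_rupture_tolac", "p_icu_hysterectomy",
    "p_hyst_accreta", "p_em_hyst_cs",
    "p_mort_pph_vaginal", "p_mort_antepartum_ind", "p_mort_intrapartum_ind",
    "p_mort_icu", "cost_icu", "cost_cs", "cost_vaginal")
}

# Evaluate all strategies deterministically and return glances + optimal id.
eval_strategies <- function(strats, params, prior_tab, horizon, wtp) {
  res <- lapply(seq_len(nrow(strats)), function(i) {
    expected_value(strats[i, ], params, prior_tab, horizon = horizon)
  })
  fr <- build_frontier(res)
  list(frontier = fr, optimal = select_optimal(fr, wtp))
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates every strategy (exactly, via [expected_value()], so sweeps
#' are smooth in the swept value) while a single parameter moves over a
#' regular grid — by default ±`range` relative to baseline, clipped to the
#' legal bounds implied by the parameter's units — and records each
#' strategy's cost and QALYs plus the optimal strategy at the
#' willingness-to-pay threshold.
#'
#' @param param_ids Parameters to sweep (default [one_way_parameters()]).
#' @inheritParams run_cohort
#' @param strats Calibrated strategy tibble (default: the three strategies
#'   calibrated at baseline).
#' @param range Relative half-width of the sweep (default 0.5).
#' @param n_points Grid points per parameter (default 5).
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param registry Registry used to look up units for bound clipping.
#' @return A long tibble: `param_id`, `value`, `strategy_id`, `cost`,
#'   `qaly`, `optimal`.
#' @export
one_way_sensitivity <- function(param_ids = one_way_parameters(),
                                params = baseline_params(),
                                prior_tab = prior_cs_table(), strats = NULL,
                                range = 0.5, n_points = 5L, horizon = 35L,
                                wtp = WTP_DEFAULT,
                                registry = param_registry()) {
  strats <- strats %||% calibrate_strategies(NULL, params, prior_tab)$strategies
  units <- setNames(registry$units, registry$id)
  purrr::map_dfr(param_ids, function(id) {
    base <- pget(params, id)
    lo <- base * (1 - range)
    hi <- base * (1 + range)
    if (units[[id]] %in% c("probability", "utility")) {
      clipped <- hi > 1
      hi <- min(hi, 1)
      if (clipped) warn(sprintf("sweep range for %s clipped to [%g, 1]", id, lo))
    }
    vals <- if (hi > lo) seq(lo, hi, length.out = n_points) else base
    purrr::map_dfr(vals, function(v) {
      ps <- params
      ps$values[[id]] <- v
      ev <- eval_strategies(strats, ps, prior_tab, horizon, wtp)
      fr <- as_tibble(ev$frontier)
      tibble(param_id = id, value = v, strategy_id = fr$strategy_id,
             cost = fr$cost, qaly = fr$qaly, optimal = ev$optimal)
    })
  })
}

#' Two-way sensitivity analysis over CEmOC access and CS rate
#'
#' Builds a custom strategy for every cell of a regular
#' (access, target CS rate) grid, calibrates its non-indicated CS
#' probabilities to the cell's target (cells whose target lies at or below
#' the indicated-only floor are flagged `floor_constrained`, not dropped),
#' evaluates it exactly, and labels each cell with the optimal strategy at
#' the willingness-to-pay threshold among the three base strategies plus the
#' cell's own.
#'
#' @param access_range,cs_rate_range Numeric length-2 ranges in \[0, 1\].
#' @param n_points Grid points per axis.
#' @inheritParams one_way_sensitivity
#' @param grid_step Calibration grid step used per cell.
#' @return A tibble: `access`, `cs_rate`, `achieved_cs_rate`,
#'   `floor_constrained`, `cost`, `qaly`, `nmb` (net monetary benefit at
#'   `wtp`) and `optimal`.
#' @export
two_way_sensitivity <- function(access_range = c(0.3, 0.8),
                                cs_rate_range = c(0.05, 0.45),
                                n_points = 5L, params = baseline_params(),
                                prior_tab = prior_cs_table(), strats = NULL,
                                horizon = 35L, wtp = WTP_DEFAULT,
                                grid_step = 0.002) {
  stopifnot(all(access_range >= 0 & access_range <= 1),
            all(cs_rate_range >= 0 & cs_rate_range <= 1))
  strats <- strats %||% calibrate_strategies(NULL, params, prior_tab)$strategies
  base_ev <- lapply(seq_len(nrow(strats)), function(i) {
    expected_value(strats[i, ], params, prior_tab, horizon = horizon)
  })
  base_gl <- dplyr::bind_rows(lapply(base_ev, glance))
  grid <- tidyr::expand_grid(
    access = seq(access_range[1], access_range[2], length.out = n_points),
    cs_rate = seq(cs_rate_range[1], cs_rate_range[2], length.out = n_points)
  )
  purrr::pmap_dfr(grid, function(access, cs_rate) {
    cell <- strategy("cell", access, cs_rate,
                     p_hist_cs = pget(params, "p_hist_cs_national"))
    cal <- calibrate(cell, params, prior_tab, horizon = horizon,
                     grid_step = grid_step)
    ev <- expected_value(cal$strategy, params, prior_tab, horizon = horizon)
    all_gl <- dplyr::bind_rows(base_gl, glance(ev))
    fr <- build_frontier(all_gl)
    tibble(access = access, cs_rate = cs_rate,
           achieved_cs_rate = cal$achieved,
           floor_constrained = cal$floor_constrained,
           converged = cal$converged,
           cost = ev$mean_cost, qaly = ev$mean_qaly,
           nmb = ev$mean_qaly * wtp - ev$mean_cost,
           optimal = select_optimal(fr, wtp))
  })
}

#' Plot the two-way sensitivity surface
#'
#' @param surface Output of [two_way_sensitivity()].
#' @param fill Column to map to fill (default `"optimal"`).
#' @return A ggplot heatmap over the (access, CS rate) plane.
#' @export
plot_two_way <- function(surface, fill = "optimal") {
  ggplot2::ggplot(surface, ggplot2::aes(x = .data$access, y = .data$cs_rate)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::labs(x = "Access to CEmOC", y = "Target CS rate", fill = fill) +
    ggplot2::theme_minimal()
}

#' Probabilistic sensitivity analysis
#'
#' Redraws every registry parameter from its distribution `n_draws` times;
#' for each draw the three strategies are rebuilt from the sampled set (so
#' sampled access and prior-CS prevalences propagate), evaluated by Monte
#' Carlo with common random numbers across strategies within the draw, and
#' the optimal strategy at the willingness-to-pay threshold is recorded by
#' net monetary benefit. Calibrated non-indicated CS probabilities are
#' strategy attributes estimated at baseline and are held fixed across draws.
#'
#' @param n_draws Number of parameter draws (default 1000; the published
#'   analysis scale. Scale down for quick runs).
#' @param registry Parameter registry to sample from.
#' @inheritParams run_cohort
#' @param strats Calibrated strategy tibble; its non-indicated probabilities
#'   are reused for every draw.
#' @param n_women Women per cohort evaluation (default 2000, a desk-scale
#'   cohort; increase for publication-scale runs).
#' @param wtp Willingness-to-pay threshold.
#' @return A `cesim_psa`: per-draw `(draw, strategy_id, cost, qaly)` tibble
#'   and the optimal-strategy frequency table.
#' @export
run_psa <- function(n_draws = 1000L, registry = param_registry(),
                    prior_tab = prior_cs_table(), strats = NULL,
                    n_women = 2000L, horizon = 35L, seed = 1L,
                    wtp = WTP_DEFAULT) {
  stopifnot(n_draws >= 1L)
  base_params <- baseline_params(registry)
  strats <- strats %||% calibrate_strategies(NULL, base_params, prior_tab)$strategies
  set.seed(as.integer(seed))
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  rows <- vector("list", n_draws)
  optimal <- character(n_draws)
  for (d in seq_len(n_draws)) {
    ps <- sample_params(registry, seed = draw_seeds[d])
    sd_ <- strategies(ps)
    sd_$p_nonind_antepartum <- strats$p_nonind_antepartum
    sd_$p_nonind_intrapartum <- strats$p_nonind_intrapartum
    sd_$calibrated <- TRUE
    res <- lapply(seq_len(nrow(sd_)), function(i) {
      run_cohort(sd_[i, ], ps, prior_tab, n_women = n_women,
                 horizon = horizon, seed = draw_seeds[d])
    })
    gl <- dplyr::bind_rows(lapply(res, glance))
    rows[[d]] <- tibble(draw = d, strategy_id = gl$strategy_id,
                        cost = gl$mean_cost, qaly = gl$mean_qaly)
    nmb <- gl$mean_qaly * wtp - gl$mean_cost
    optimal[d] <- gl$strategy_id[which.max(nmb)]
  }
  draws <- dplyr::bind_rows(rows)
  freq <- draws %>%
    dplyr::distinct(.data$strategy_id) %>%
    mutate(frequency = vapply(.data$strategy_id,
                              function(s) mean(optimal == s), numeric(1)))
  structure(list(draws = draws, optimal = optimal, frequency = freq,
                 n_draws = n_draws, n_women = n_women, seed = as.integer(seed),
                 wtp = wtp),
            class = "cesim_psa")
}

#' @export
print.cesim_psa <- function(x, ...) {
  cat(sprintf("<cesim_psa> %d draws x %d women, WTP %.2f\n",
              x$n_draws, x$n_women, x$wtp))
  print(x$frequency)
  invisible(x)
}

#' @method tidy cesim_psa
#' @export
tidy.cesim_psa <- function(x, ...) x$draws

#' @method glance cesim_psa
#' @export
glance.cesim_psa <- function(x, ...) {
  tidyr::pivot_wider(x$frequency, names_from = "strategy_id",
                     values_from = "frequency") %>%
    mutate(n_draws = x$n_draws, wtp = x$wtp)
}

#' Plot the PSA cost-effectiveness plane
#'
#' @param psa A `cesim_psa`.
#' @return A ggplot scatter of per-draw (QALY, cost) pairs by strategy.
#' @export
plot_psa <- function(psa) {
  ggplot2::ggplot(psa$draws,
                  ggplot2::aes(x = .data$qaly, y = .data$cost,
                               colour = .data$strategy_id)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Mean QALYs per woman", y = "Mean cost per woman (2016 USD)",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}
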