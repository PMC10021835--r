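#' Overall CS rate achieved in a cohort result
#'
#' @param result A `cesim_cohort`.
#' @return Cesarean sections per full-term pregnancy.
#' @examples
#' achieved_cs_rate(expected_value(strategies()[1, ], horizon = 3))
#' @export
achieved_cs_rate <- function(result) {
  preg <- result$tally[["pregnancies_to_term"]]
  if (!isTRUE(preg > 0)) {
    abort("CS rate undefined: no full-term pregnancies in result")
  }
  unname(result$tally[["cesarean_sections"]] / preg)
}

#' Calibrate non-indicated CS probabilities to a target CS rate
#'
#' The probabilities of a non-indicated antepartum and intrapartum CS are not
#' observable and are estimated by grid search: both are varied at regular
#' intervals — jointly, holding their published baseline ratio
#' (0.0094 : 0.018) — while all other parameters stay fixed, until the
#' simulated overall CS rate (cesareans per full-term pregnancy) matches the
#' strategy's target. The objective is evaluated with the exact
#' expected-value recursion ([expected_value()]), so the search is free of
#' Monte Carlo jitter and idempotent; a coarse pass at ten times `grid_step`
#' brackets the optimum and a fine pass at `grid_step` resolves it, which
#' selects the same point as the full regular grid because the achieved rate
#' is monotone in the sweep scale. A Monte Carlo engine is available for
#' cross-checks.
#'
#' If the target lies at or below the indicated-only floor (the rate achieved
#' with both non-indicated probabilities at zero), no non-indicated CS are
#' performed: both probabilities are set to zero and the result is flagged
#' `floor_constrained`, with the floor reported.
#'
#' @param strategy One-row strategy tibble.
#' @inheritParams run_cohort
#' @param grid_step Fine grid step on the antepartum probability (default
#'   0.001).
#' @param tolerance Acceptable |achieved - target| (default 0.005).
#' @param ratio Intrapartum:antepartum ratio held during the sweep; defaults
#'   to the published baselines' ratio.
#' @param engine `"expected"` (exact, default) or `"monte_carlo"`.
#' @return A `cesim_calibration`: the calibrated strategy, the evaluated
#'   grid, the selected point, achieved rate, floor, and convergence flags.
#' @examples
#' \donttest{
#' cal <- calibrate(strategies()[1, ], grid_step = 0.005)
#' cal$achieved
#' }
#' @export
calibrate <- function(strategy, params = baseline_params(),
                      prior_tab = prior_cs_table(), horizon = 35L,
                      grid_step = 0.001, tolerance = 0.005, ratio = NULL,
                      engine = c("expected", "monte_carlo"),
                      n_women = 10000L, seed = 1L) {
  engine <- match.arg(engine)
  strat_df <- if (is.data.frame(strategy)) strategy else as_tibble(as_strategy_row(strategy))
  strat <- as_strategy_row(strat_df)
  stopifnot(grid_step > 0, tolerance > 0)
  ratio <- ratio %||% (pget(params, "p_nonind_intrapartum") /
                         pget(params, "p_nonind_antepartum"))
  target <- strat$target_cs_rate

  rate_at <- function(p_na) {
    s2 <- strat_df
    s2$p_nonind_antepartum <- p_na
    s2$p_nonind_intrapartum <- min(p_na * ratio, 1)
    res <- if (engine == "expected") {
      expected_value(s2, params, prior_tab, horizon = horizon)
    } else {
      run_cohort(s2, params, prior_tab, n_women = n_women,
                 horizon = horizon, seed = seed)
    }
    achieved_cs_rate(res)
  }

  floor_rate <- rate_at(0)
  grid <- tibble(p_nonind_antepartum = 0,
                 p_nonind_intrapartum = 0, achieved = floor_rate)
  if (target <= floor_rate + 1e-12) {
    sel <- 0
    achieved <- floor_rate
    floor_constrained <- TRUE
  } else {
    floor_constrained <- FALSE
    s_max <- min(1, 1 / ratio)
    coarse <- seq(0, s_max, by = grid_step * 10)
    if (coarse[length(coarse)] < s_max) coarse <- c(coarse, s_max)
    r_coarse <- vapply(coarse, rate_at, numeric(1))
    i <- which.min(abs(r_coarse - target))
    lo <- coarse[max(1L, i - 1L)]
    hi <- coarse[min(length(coarse), i + 1L)]
    fine <- seq(lo, hi, by = grid_step)
    r_fine <- vapply(fine, rate_at, numeric(1))
    grid <- tibble(
      p_nonind_antepartum = c(coarse, fine),
      p_nonind_intrapartum = pmin(c(coarse, fine) * ratio, 1),
      achieved = c(r_coarse, r_fine)
    )
    j <- which.min(abs(r_fine - target))
    sel <- fine[j]
    achieved <- r_fine[j]
  }

  strat_df$p_nonind_antepartum <- sel
  strat_df$p_nonind_intrapartum <- min(sel * ratio, 1)
  strat_df$calibrated <- TRUE
  structure(list(
    strategy = strat_df,
    grid = grid,
    selected = c(p_nonind_antepartum = sel,
                 p_nonind_intrapartum = min(sel * ratio, 1)),
    achieved = achieved, target = target, floor = floor_rate,
    floor_constrained = floor_constrained,
    converged = abs(achieved - target) <= tolerance,
    tolerance = tolerance, grid_step = grid_step, engine = engine,
    seed = if (engine == "monte_carlo") as.integer(seed) else NA_integer_
  ), class = "cesim_calibration")
}

#' @export
print.cesim_calibration <- function(x, ...) {
  cat(sprintf("<cesim_calibration> %s\n", x$strategy$id))
  cat(sprintf("  target %.4f, achieved %.4f (floor %.4f)%s\n",
              x$target, x$achieved, x$floor,
              if (x$floor_constrained) " [floor-constrained: no non-indicated CS]" else ""))
  cat(sprintf("  selected p_nonind antepartum %.4f / intrapartum %.4f; converged: %s\n",
              x$selected[1], x$selected[2], x$converged))
  invisible(x)
}

#' @method tidy cesim_calibration
#' @export
tidy.cesim_calibration <- function(x, ...) x$grid

#' @method glance cesim_calibration
#' @export
glance.cesim_calibration <- function(x, ...) {
  tibble(strategy_id = x$strategy$id, target = x$target, achieved = x$achieved,
         floor = x$floor, floor_constrained = x$floor_constrained,
         converged = x$converged,
         p_nonind_antepartum = unname(x$selected[1]),
         p_nonind_intrapartum = unname(x$selected[2]))
}

#' Calibrate every strategy in a table
#'
#' @param strats Strategy tibble (default the three modelled strategies).
#' @inheritParams calibrate
#' @return A list with `strategies` (calibrated tibble) and `calibrations`
#'   (list of `cesim_calibration` objects, named by strategy id).
#' @export
calibrate_strategies <- function(strats = NULL, params = baseline_params(),
                                 prior_tab = prior_cs_table(), ...) {
  strats <- strats %||% strategies(params)
  cals <- lapply(seq_len(nrow(strats)), function(i) {
    calibrate(strats[i, ], params, prior_tab, ...)
  })
  names(cals) <- strats$id
  list(strategies = dplyr::bind_rows(lapply(cals, `[[`, "strategy")),
       calibrations = cals)
}
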