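# A small pre-calibrated strategy set shared across sweeps (short horizon
# keeps the exact evaluator fast; sweeps are deterministic).
sens_strats <- base_strats
sens_strats$calibrated <- TRUE

test_that("one-way sweeps move costs monotonically and flag degenerate ranges", {
  sw <- one_way_sensitivity("cost_cs", params = base_ps, strats = sens_strats,
                            range = 0.5, n_points = 3, horizon = 5)
  expect_setequal(unique(sw$strategy_id), sens_strats$id)
  for (s in sens_strats$id) {
    cs <- sw$cost[sw$strategy_id == s][order(sw$value[sw$strategy_id == s])]
    expect_true(all(diff(cs) > 0))
  }
  # a zero-width range collapses to a constant column
  sw0 <- one_way_sensitivity("cost_cs", params = base_ps, strats = sens_strats,
                             range = 0, n_points = 3, horizon = 5)
  expect_equal(length(unique(sw0$value)), 1L)
  # ranges crossing a probability bound are clipped with a warning
  expect_warning(
    one_way_sensitivity("p_intra_cs_tolac", params = base_ps,
                        strats = sens_strats, range = 0.5, n_points = 2,
                        horizon = 2),
    "clipped")
})

test_that("two-way cells calibrate to their targets or report the floor", {
  surf <- two_way_sensitivity(access_range = c(0.4, 0.6),
                              cs_rate_range = c(0.25, 0.35), n_points = 2,
                              params = base_ps, strats = sens_strats,
                              horizon = 8, grid_step = 0.01)
  expect_equal(nrow(surf), 4)
  ok <- !surf$floor_constrained
  expect_true(all(abs(surf$achieved_cs_rate[ok] - surf$cs_rate[ok]) < 0.02))
  expect_true(all(c("cost", "qaly", "nmb", "optimal") %in% names(surf)))
})

test_that("without access no cesarean is possible anywhere on the surface", {
  surf0 <- two_way_sensitivity(access_range = c(0, 0), cs_rate_range = c(0.2, 0.2),
                               n_points = 1, params = base_ps,
                               strats = sens_strats, horizon = 5,
                               grid_step = 0.01)
  expect_equal(surf0$achieved_cs_rate, 0)
  expect_false(surf0$converged)
})

test_that("point-mass PSA reproduces the baseline set on every draw", {
  reg <- param_registry()
  reg$family <- "point"
  reg$params <- lapply(reg$baseline, identity)
  reg <- validate_registry(reg)
  s <- sample_params(reg, seed = 4)
  expect_equal(s$values, baseline_params(reg)$values)
  psa <- run_psa(n_draws = 2, registry = reg, strats = sens_strats,
                 n_women = 150, horizon = 4, seed = 8)
  wide <- tidyr::pivot_wider(psa$draws, names_from = "draw",
                             values_from = c("cost", "qaly"))
  expect_s3_class(psa, "cesim_psa")
})

test_that("PSA optimal-strategy frequencies are seeded and sum to one", {
  psa <- run_psa(n_draws = 5, strats = sens_strats, n_women = 120,
                 horizon = 4, seed = 31)
  expect_equal(sum(psa$frequency$frequency), 1)
  expect_equal(nrow(psa$draws), 5 * 3)
  psa2 <- run_psa(n_draws = 5, strats = sens_strats, n_women = 120,
                  horizon = 4, seed = 31)
  expect_identical(psa$draws, psa2$draws)
  expect_s3_class(plot_psa(psa), "ggplot")
})
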