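test_that("cohort runs are bitwise reproducible under a fixed seed", {
  r1 <- run_cohort(base_strats[1, ], base_ps, n_women = 300, horizon = 5, seed = 9)
  r2 <- run_cohort(base_strats[1, ], base_ps, n_women = 300, horizon = 5, seed = 9)
  expect_identical(r1$tally, r2$tally)
  expect_identical(r1$mean_cost, r2$mean_cost)
  expect_identical(r1$mean_qaly, r2$mean_qaly)
})

test_that("a never-pregnant cohort collects exactly one QALY per cycle", {
  ps <- set_params(base_ps, p_pregnancy = 0, p_hist_hysterectomy = 0)
  r <- run_cohort(base_strats[1, ], ps, n_women = 50, horizon = 35, seed = 1)
  expect_equal(r$mean_qaly, 35)
  expect_equal(r$mean_cost, 0)
  expect_equal(unname(r$tally[["pregnancies_to_term"]]), 0)
})

test_that("QALYs never exceed the horizon and tallies conserve deliveries", {
  for (seed in 1:8) {
    ps <- baseline_params(random_parameter_table(seed))
    st <- quick_strategy(access = runif(1))
    r <- run_cohort(st, ps, n_women = 200, horizon = 4, seed = seed)
    expect_lte(r$mean_qaly, 4 + 1e-12)
    t <- r$tally
    expect_equal(t[["vaginal_deliveries"]] + t[["cesarean_sections"]],
                 t[["pregnancies_to_term"]])
    expect_equal(t[["live_births"]] + t[["neonatal_deaths"]],
                 t[["pregnancies_to_term"]])
    expect_lte(t[["maternal_deaths"]], 200)
    expect_true(all(t >= 0))
  }
})

test_that("Monte Carlo means agree with the exact evaluator within 4 SE", {
  for (seed in 1:6) {
    ps <- baseline_params(random_parameter_table(seed + 100))
    st <- quick_strategy(access = runif(1, 0.2, 0.9))
    for (h in 1:3) {
      ev <- expected_value(st, ps, horizon = h)
      mc <- run_cohort(st, ps, n_women = 5000, horizon = h, seed = seed)
      expect_lt(abs(mc$mean_cost - ev$mean_cost), 4 * mc$se_cost + 1e-9,
                label = sprintf("cost, table %d horizon %d", seed, h))
      expect_lt(abs(mc$mean_qaly - ev$mean_qaly), 4 * mc$se_qaly + 1e-9,
                label = sprintf("qaly, table %d horizon %d", seed, h))
    }
  }
})

test_that("entry prevalences are honoured", {
  # prior-CS prevalence: with certain pregnancy, certain elective repeat and
  # nothing else, first-cycle cesareans are exactly the women with a prior CS
  ps <- set_params(zero_complications(base_ps), p_pregnancy = 1)
  st <- strategy("c_like", access = 1, target_cs_rate = 0.282,
                 p_hist_cs = 0.282, p_nonind_antepartum = 0,
                 p_nonind_intrapartum = 0)
  r <- run_cohort(st, ps, flat_prior_tab(p_er = 1), n_women = 10000,
                  horizon = 1, seed = 2)
  frac <- r$tally[["cesarean_sections"]] / 10000
  expect_lt(abs(frac - 0.282), 0.013)

  # hysterectomy-history prevalence read off the utility stream (0.94/cycle)
  ps2 <- set_params(base_ps, p_pregnancy = 0)
  r2 <- run_cohort(base_strats[1, ], ps2, n_women = 10000, horizon = 35, seed = 3)
  f_hat <- (35 - r2$mean_qaly) / (0.06 * 35)
  expect_lt(abs(f_hat - 0.017), 4 * sqrt(0.017 * 0.983 / 10000))
})

test_that("death is absorbing and forfeits utility from mid-cycle", {
  ps <- set_params(zero_complications(base_ps), p_pregnancy = 1,
                   p_antepartum_indication = 1, p_mort_antepartum_ind = 1)
  st <- quick_strategy(access = 1, na = 0, ni = 0, hist = 0)
  r <- run_cohort(st, ps, n_women = 100, horizon = 10, seed = 1)
  # every woman dies at her first delivery: half the pregnant-state utility,
  # one CS cost, and nothing afterwards
  expect_equal(r$mean_qaly, 0.99 / 2)
  expect_equal(r$mean_cost, 745.66)
  expect_equal(unname(r$tally[["maternal_deaths"]]), 100)
  expect_equal(unname(r$tally[["pregnancies_to_term"]]), 100)
  ev <- expected_value(st, ps, horizon = 10)
  expect_equal(ev$mean_qaly, 0.99 / 2)
  expect_equal(ev$mean_cost, 745.66)
  # without the half-cycle correction the full pregnant-state utility accrues
  r_nohc <- run_cohort(st, ps, n_women = 50, horizon = 3, seed = 1,
                       half_cycle = FALSE)
  expect_equal(r_nohc$mean_qaly, 0.99)
})

test_that("post-hysterectomy women accrue 0.94 per cycle and never get pregnant", {
  ps <- set_params(base_ps, p_hist_hysterectomy = 1)
  r <- run_cohort(base_strats[1, ], ps, n_women = 40, horizon = 20, seed = 1)
  expect_equal(r$mean_qaly, 20 * 0.94)
  expect_equal(unname(r$tally[["pregnancies_to_term"]]), 0)
})

test_that("exact evaluator is monotone in cost and access where it must be", {
  st <- base_strats[1, ]
  ev_lo <- expected_value(st, set_params(base_ps, cost_cs = 500), horizon = 6)
  ev_hi <- expected_value(st, set_params(base_ps, cost_cs = 900), horizon = 6)
  expect_gt(ev_hi$mean_cost, ev_lo$mean_cost)

  s_lo <- quick_strategy(access = 0.3)
  s_hi <- quick_strategy(access = 0.9)
  f_lo <- expected_value(s_lo, base_ps, horizon = 6)$tally[["fistula"]]
  f_hi <- expected_value(s_hi, base_ps, horizon = 6)$tally[["fistula"]]
  expect_gte(f_lo, f_hi)
})

test_that("discounting reduces accumulated cost and QALYs", {
  st <- base_strats[1, ]
  ev0 <- expected_value(st, base_ps, horizon = 10)
  ev3 <- expected_value(st, base_ps, horizon = 10,
                        discount_cost = 0.03, discount_qaly = 0.03)
  expect_lt(ev3$mean_cost, ev0$mean_cost)
  expect_lt(ev3$mean_qaly, ev0$mean_qaly)
})
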