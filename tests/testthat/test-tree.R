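test_that("leaf-path probabilities sum to one across random parameter tables", {
  for (seed in 1:20) {
    ps <- baseline_params(random_parameter_table(seed))
    st <- quick_strategy(access = runif(1))
    for (c in c(0L, 2L)) {
      lv <- episode_leaves(c, ps, st)
      expect_equal(sum(lv$.p), 1, tolerance = 1e-9)
      expect_true(all(lv$.p > 0))
    }
  }
  # and at baseline for every prior-CS count
  for (c in 0:3) {
    lv <- episode_leaves(c, base_ps, base_strats[1, ])
    expect_equal(sum(lv$.p), 1, tolerance = 1e-12)
  }
})

test_that("the forced accreta path accumulates every cost component", {
  lv <- episode_leaves(2, base_ps, base_strats[1, ])
  worst <- lv[lv$access & lv$accreta & lv$pph & lv$hyst & lv$icu, ]
  expect_gt(nrow(worst), 0)
  # CS + transfusion + hysterectomy + ICU
  expect_equal(unique(worst$cost), 745.66 + 79.89 + 2241.42 + 1172.50)
  expect_true(all(worst$mode_cs))
})

test_that("with no complications the episode cost is exactly one delivery", {
  ps <- zero_complications(base_ps)
  st_acc <- quick_strategy(access = 1, na = 0, ni = 0)
  lv <- episode_leaves(0, ps, st_acc, flat_prior_tab())
  expect_equal(nrow(lv), 1)
  expect_equal(lv$cost, 153.70)
  expect_false(lv$mode_cs)
  # with a prior CS and certain elective repeat the only cost is one CS
  lv2 <- episode_leaves(1, ps, st_acc, flat_prior_tab(p_er = 1))
  expect_equal(lv2$cost, 745.66)
  expect_true(lv2$mode_cs)
  # mixed access: costs stay in the two-delivery set
  lv3 <- episode_leaves(1, ps, quick_strategy(access = 0.5, na = 0, ni = 0),
                        flat_prior_tab())
  expect_true(all(lv3$cost %in% c(153.70, 745.66)))
})

test_that("without access an absolute indication kills the neonate and no surgery happens", {
  lv <- episode_leaves(1, base_ps, quick_strategy(access = 0))
  expect_true(all(!lv$access))
  expect_true(all(!lv$mode_cs))
  expect_true(all(!lv$hyst), info = "no hysterectomy without access")
  expect_true(all(!lv$icu))
  ind <- lv$accreta | lv$previa | lv$rupture | lv$neonate_died
  expect_true(all(lv$neonate_died[lv$accreta | lv$previa | lv$rupture]))
  # fistula only reachable on unmet-indication paths
  expect_true(all(lv$neonate_died[lv$fistula]))
  # cost never exceeds a vaginal delivery
  expect_true(all(lv$cost == 153.70))
})

test_that("with access the neonate always survives", {
  for (c in 0:2) {
    lv <- episode_leaves(c, base_ps, quick_strategy(access = 1))
    expect_true(all(!lv$neonate_died))
  }
})

test_that("simulated episodes agree with the enumerated leaf expectations", {
  st <- base_strats[1, ]
  n <- 20000
  for (c in c(0L, 2L)) {
    lv <- episode_leaves(c, base_ps, st)
    ep <- delivery_episode(n, c, base_ps, st, seed = 42)
    for (ev in c("mode_cs", "pph", "hyst", "neonate_died")) {
      p_exp <- sum(lv$.p * lv[[ev]])
      se <- sqrt(p_exp * (1 - p_exp) / n)
      expect_lt(abs(mean(ep[[ev]]) - p_exp), 4 * se + 1e-12,
                label = sprintf("count %d, event %s", c, ev))
    }
    expect_lt(abs(mean(ep$cost) - sum(lv$.p * lv$cost)),
              4 * stats::sd(ep$cost) / sqrt(n))
  }
})

test_that("forced TOLAC conversion yields a cesarean", {
  ps <- set_params(zero_complications(base_ps), p_intra_cs_tolac = 1)
  st <- quick_strategy(access = 1, na = 0, ni = 0)
  ep <- delivery_episode(500, 1, ps, st, prior_tab = flat_prior_tab(p_er = 0),
                         seed = 3)
  expect_true(all(ep$tolac))
  expect_true(all(ep$mode_cs))
  expect_false(any(ep$vbac))
})
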