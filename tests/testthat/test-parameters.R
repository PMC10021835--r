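test_that("shipped registry carries the published baselines", {
  reg <- param_registry()
  expect_equal(nrow(reg), 40)
  expect_false(any(duplicated(reg$id)))
  get <- function(id) reg$baseline[reg$id == id]
  expect_equal(get("p_pregnancy"), 0.0654)
  expect_equal(get("cost_cs"), 745.66)
  expect_equal(get("cost_vaginal"), 153.70)
  expect_equal(get("u_hysterectomy"), 0.94)
  expect_equal(get("p_access_national"), 0.502)
  expect_equal(get("p_intra_cs_tolac"), 0.739)
  ps <- baseline_params(reg)
  expect_equal(ps$values[["cost_cs"]], 745.66)
  expect_identical(ps$provenance, "baseline")
})

test_that("malformed registries are rejected by row id", {
  reg <- param_registry()
  bad <- reg
  bad$baseline[bad$id == "p_pregnancy"] <- 1.3
  expect_error(validate_registry(bad), "p_pregnancy")
  dup <- rbind(reg, reg[1, ])
  expect_error(validate_registry(dup), "duplicate")
  neg <- reg
  neg$params[[which(neg$id == "cost_cs")]] <- c(-1, 5)
  expect_error(validate_registry(neg), "cost_cs")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,baseline,family", tmp)
  expect_error(load_registry(tmp), "missing columns")
})

test_that("seeded sampling is reproducible and point masses are fixed", {
  s1 <- sample_params(seed = 11)
  s2 <- sample_params(seed = 11)
  expect_identical(s1$values, s2$values)
  s3 <- sample_params(seed = 12)
  expect_false(identical(s1$values, s3$values))
  # point-distribution parameters never move
  expect_equal(s1$values[["u_nonpregnant"]], 1)
  expect_equal(s1$values[["u_dead"]], 0)
  expect_identical(s1$provenance, "psa_sample")
})

test_that("sampled values respect their units-implied ranges", {
  reg <- param_registry()
  units <- setNames(reg$units, reg$id)
  for (seed in 1:20) {
    v <- sample_params(reg, seed = seed)$values
    expect_true(all(v[units == "probability"] >= 0 & v[units == "probability"] <= 1))
    expect_true(all(v[units == "utility"] >= 0 & v[units == "utility"] <= 1))
    expect_true(all(v[units == "usd_2016"] >= 0))
  }
})

test_that("empirical moments of sampled sets match analytic beta means", {
  reg <- param_registry()
  n <- 2000
  draws <- vapply(seq_len(n), function(s) {
    v <- sample_params(reg, seed = s)$values
    c(v[["p_pph_accreta"]], v[["p_pregnancy"]])
  }, numeric(2))
  # beta(18, 12) has mean 0.6; beta(14.882, 212.76) has mean ~0.0654
  expect_equal(mean(draws[1, ]), 18 / 30, tolerance = 0.02 / 0.6)
  expect_lt(abs(mean(draws[2, ]) - 14.882 / (14.882 + 212.76)), 0.005)
})

test_that("set_params overrides values and rejects unknown ids", {
  ps <- set_params(baseline_params(), p_pregnancy = 1, cost_cs = 100)
  expect_equal(ps$values[["p_pregnancy"]], 1)
  expect_equal(ps$values[["cost_cs"]], 100)
  expect_error(set_params(ps, not_a_param = 1), "unknown parameter")
})

test_that("prior-CS table validates monotone previa/accreta risks", {
  tab <- prior_cs_table()
  expect_named(tab, c("prior_cs_count", "p_previa", "p_accreta", "p_elective_repeat"))
  expect_false(is.unsorted(tab$p_previa))
  expect_false(is.unsorted(tab$p_accreta))
  bad <- tab
  bad$p_previa <- rev(bad$p_previa)
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, tmp)
  expect_error(prior_cs_table(tmp), "non-decreasing")
})
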