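test_that("icer is incremental cost over incremental QALYs", {
  expect_equal(icer(list(cost = 0, qaly = 0), list(cost = 100, qaly = 10)), 10)
  expect_equal(icer(list(cost = 50, qaly = 1), list(cost = 50, qaly = 2)), 0)
  expect_equal(icer(list(mean_cost = 0, mean_qaly = 0),
                    list(mean_cost = 5, mean_qaly = 2)), 2.5)
  expect_error(icer(list(cost = 0, qaly = 1), list(cost = 10, qaly = 1)),
               "dominated")
})

test_that("strict and extended dominance are identified and certified", {
  fr <- build_frontier(data.frame(strategy_id = c("X", "Y"),
                                  cost = c(100, 200), qaly = c(10, 9)))
  expect_equal(fr$status[fr$strategy_id == "Y"], "dominated_strict")
  expect_equal(fr$status[fr$strategy_id == "X"], "frontier")

  fr2 <- build_frontier(data.frame(strategy_id = c("X", "Y", "Z"),
                                   cost = c(0, 10, 11), qaly = c(0, 1, 3)))
  expect_equal(fr2$status[fr2$strategy_id == "Y"], "dominated_extended")
  expect_equal(sort(fr2$strategy_id[fr2$status == "frontier"]), c("X", "Z"))
  expect_equal(fr2$icer[fr2$strategy_id == "Z"], 11 / 3)
  # certification: Y is beaten on ICER by the costlier Z
  expect_gt(icer(fr2[fr2$strategy_id == "X", ], fr2[fr2$strategy_id == "Y", ]),
            icer(fr2[fr2$strategy_id == "X", ], fr2[fr2$strategy_id == "Z", ]))
})

test_that("frontier matches the convex-hull oracle on random strategy sets", {
  set.seed(77)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    df <- data.frame(strategy_id = paste0("s", seq_len(k)),
                     cost = runif(k, 0, 1000), qaly = runif(k, 20, 35))
    fr <- build_frontier(df)
    expect_equal(sort(fr$strategy_id[fr$status == "frontier"]),
                 hull_frontier(df), label = paste("rep", rep))
    # ICERs strictly increase along the frontier
    ic <- fr$icer[fr$status == "frontier"]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
  }
})

test_that("frontier output is invariant to input ordering and handles ties", {
  df <- data.frame(strategy_id = c("a", "b", "c", "d"),
                   cost = c(5, 1, 3, 3), qaly = c(30, 21, 25, 28))
  fr1 <- build_frontier(df)
  fr2 <- build_frontier(df[c(3, 1, 4, 2), ])
  expect_equal(fr1, fr2)
  # exact cost tie: the lower-QALY twin is strictly dominated
  tie <- build_frontier(data.frame(strategy_id = c("p", "q"),
                                   cost = c(10, 10), qaly = c(5, 7)))
  expect_equal(tie$status[tie$strategy_id == "p"], "dominated_strict")
})

test_that("optimal strategy is the best affordable frontier entry", {
  fr <- build_frontier(data.frame(strategy_id = c("B", "C"),
                                  cost = c(100, 200), qaly = c(10, 10.5)))
  # ICER(C) = 200 per QALY
  expect_equal(select_optimal(fr, wtp = 1939.61), "C")
  expect_equal(select_optimal(fr, wtp = 100), "B")
  single <- build_frontier(data.frame(strategy_id = "only",
                                      cost = 5, qaly = 1))
  expect_equal(select_optimal(single, wtp = 1), "only")
})

test_that("frontier accepts cohort-result lists and draws a plot", {
  ps <- zero_complications(base_ps)
  res <- list(expected_value(quick_strategy(access = 0, id = "lo"), ps, horizon = 3),
              expected_value(quick_strategy(access = 1, id = "hi"), ps, horizon = 3))
  fr <- build_frontier(res)
  expect_s3_class(fr, "cesim_frontier")
  p <- plot_frontier(fr)
  expect_s3_class(p, "ggplot")
})
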