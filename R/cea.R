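#' Incremental cost-effectiveness ratio
#'
#' The additional cost of a strategy divided by its additional benefit in
#' quality-adjusted life-years, relative to the next-least-expensive
#' non-dominated strategy.
#'
#' @param lower,upper Rows/lists with `cost` and `qaly` (or `mean_cost` /
#'   `mean_qaly`) fields; `upper` must cost at least as much and be strictly
#'   more effective.
#' @return ICER in USD per QALY.
#' @examples
#' icer(list(cost = 0, qaly = 0), list(cost = 100, qaly = 10))
#' @export
icer <- function(lower, upper) {
  gx <- function(x, a, b) {
    x <- as.list(x)
    v <- x[[a]] %||% x[[b]]
    if (is.null(v)) abort(sprintf("missing '%s' field", a))
    v
  }
  dc <- gx(upper, "cost", "mean_cost") - gx(lower, "cost", "mean_cost")
  dq <- gx(upper, "qaly", "mean_qaly") - gx(lower, "qaly", "mean_qaly")
  if (dq <= 0) {
    abort("ICER undefined: upper strategy is not more effective (dominated pair)")
  }
  dc / dq
}

#' Build the cost-effectiveness frontier
#'
#' Sorts strategies by mean cost, removes strictly dominated entries
#' (costlier and no more effective than another strategy), then iteratively
#' removes entries under extended (weak) dominance — a higher ICER than a
#' costlier alternative — until ICERs strictly increase along the frontier.
#' Exact cost ties are ordered by QALY descending and the lower-QALY twin is
#' marked strictly dominated.
#'
#' @param results Data frame with columns `strategy_id`, `cost`, `qaly`
#'   (or `mean_cost`/`mean_qaly`), one row per strategy; or a list of
#'   `cesim_cohort` objects.
#' @return A tibble sorted by cost with columns `strategy_id`, `cost`,
#'   `qaly`, `icer` (NA for the cheapest frontier entry and for dominated
#'   entries) and `status` (`"frontier"`, `"dominated_strict"`,
#'   `"dominated_extended"`), classed `cesim_frontier`.
#' @examples
#' build_frontier(data.frame(strategy_id = c("X", "Y", "Z"),
#'                           cost = c(0, 10, 11), qaly = c(0, 1, 3)))
#' @export
build_frontier <- function(results) {
  if (!is.data.frame(results) && is.list(results)) {
    results <- dplyr::bind_rows(lapply(results, glance))
  }
  df <- as_tibble(results)
  if ("mean_cost" %in% names(df) && !"cost" %in% names(df)) {
    df <- dplyr::rename(df, cost = "mean_cost", qaly = "mean_qaly")
  }
  stopifnot(all(c("strategy_id", "cost", "qaly") %in% names(df)))
  if (!all(is.finite(df$cost)) || !all(is.finite(df$qaly))) {
    abort("costs and QALYs must be finite")
  }
  df <- df[order(df$cost, -df$qaly), c("strategy_id", "cost", "qaly")]
  n <- nrow(df)
  status <- rep("frontier", n)
  # strict dominance: a cheaper-or-equal, at-least-as-effective witness that
  # is better on at least one axis
  for (i in seq_len(n)) {
    witness <- df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
      (df$cost < df$cost[i] | df$qaly > df$qaly[i])
    if (any(witness)) status[i] <- "dominated_strict"
  }
  # extended dominance: enforce strictly increasing ICERs among survivors
  repeat {
    keep <- which(status == "frontier")
    if (length(keep) < 3L) break
    ic <- vapply(seq_along(keep)[-1], function(k) {
      icer(df[keep[k - 1L], ], df[keep[k], ])
    }, numeric(1))
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    status[keep[bad[1L] + 1L]] <- "dominated_extended"
  }
  keep <- which(status == "frontier")
  df$icer <- NA_real_
  if (length(keep) > 1L) {
    for (k in seq_along(keep)[-1]) {
      df$icer[keep[k]] <- icer(df[keep[k - 1L], ], df[keep[k], ])
    }
  }
  df$status <- status
  class(df) <- c("cesim_frontier", class(df))
  df
}

#' Select the optimal strategy at a willingness-to-pay threshold
#'
#' Returns the highest-QALY frontier strategy whose ICER does not exceed the
#' willingness-to-pay threshold; the cheapest frontier entry qualifies
#' unconditionally.
#'
#' @param frontier Output of [build_frontier()].
#' @param wtp Willingness-to-pay threshold in USD/QALY (default 1939.61,
#'   India's 2017 GDP per capita).
#' @return The selected `strategy_id`.
#' @examples
#' fr <- build_frontier(data.frame(strategy_id = c("X", "Y"),
#'                                 cost = c(0, 10), qaly = c(0, 1)))
#' select_optimal(fr, wtp = 100)
#' @export
select_optimal <- function(frontier, wtp = WTP_DEFAULT) {
  fr <- frontier[frontier$status == "frontier", ]
  if (!nrow(fr)) abort("empty frontier")
  ok <- is.na(fr$icer) | fr$icer <= wtp
  cand <- fr[ok, ]
  cand$strategy_id[which.max(cand$qaly)]
}

#' Plot a cost-effectiveness frontier
#'
#' @param frontier A `cesim_frontier`.
#' @param wtp Willingness-to-pay threshold annotated on the subtitle.
#' @return A ggplot: QALYs against cost, frontier strategies joined.
#' @export
plot_frontier <- function(frontier, wtp = WTP_DEFAULT) {
  fr <- as_tibble(frontier)
  on <- fr[fr$status == "frontier", ]
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = on, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy_id),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "Mean QALYs per woman", y = "Mean cost per woman (2016 USD)",
                  colour = NULL,
                  subtitle = sprintf("WTP threshold %.2f USD/QALY", wtp)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot cesim_frontier
#' @export
autoplot.cesim_frontier <- function(object, ...) plot_frontier(object, ...)
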