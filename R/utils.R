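`%||%` <- function(x, y) if (is.null(x)) y else x

# Willingness-to-pay default: India's 2017 GDP per capita in USD.
WTP_DEFAULT <- 1939.61

# Female population of reproductive age used for national extrapolation,
# recovered from the printed (per-10k, national) reporting pair.
POPULATION_DEFAULT <- 3.25e8

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

# Coerce a one-row data frame / list describing a strategy into a plain list.
as_strategy_row <- function(strategy) {
  if (is.data.frame(strategy)) {
    if (nrow(strategy) != 1L) {
      abort("`strategy` must be a single strategy (one row)")
    }
    strategy <- as.list(strategy)
  }
  needed <- c("id", "access", "target_cs_rate", "p_hist_cs",
              "p_nonind_antepartum", "p_nonind_intrapartum")
  missing <- setdiff(needed, names(strategy))
  if (length(missing)) {
    abort(paste0("strategy is missing fields: ", paste(missing, collapse = ", ")))
  }
  for (f in setdiff(needed, "id")) {
    assert_scalar_number(strategy[[f]], f, 0, 1)
  }
  strategy$calibrated <- isTRUE(strategy$calibrated)
  strategy
}
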