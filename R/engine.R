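new_cohort_result <- function(strategy_id, mean_cost, mean_qaly, se_cost,
                              se_qaly, tally, n_women, horizon, seed,
                              provenance) {
  structure(list(strategy_id = strategy_id, mean_cost = mean_cost,
                 mean_qaly = mean_qaly, se_cost = se_cost, se_qaly = se_qaly,
                 tally = tally, n_women = n_women, horizon = horizon,
                 seed = seed, provenance = provenance),
            class = "cesim_cohort")
}

#' @export
print.cesim_cohort <- function(x, ...) {
  cat(sprintf("<cesim_cohort> %s (%s)\n", x$strategy_id, x$provenance))
  cat(sprintf("  n_women %s, horizon %d cycles\n", format(x$n_women), x$horizon))
  cat(sprintf("  mean cost  %10.2f USD  (se %.3f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean QALY  %10.4f       (se %.5f)\n", x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' @method tidy cesim_cohort
#' @export
tidy.cesim_cohort <- function(x, ...) {
  tibble(event = names(x$tally), count = as.numeric(x$tally))
}

#' @method glance cesim_cohort
#' @export
glance.cesim_cohort <- function(x, ...) {
  tibble(strategy_id = x$strategy_id, mean_cost = x$mean_cost,
         mean_qaly = x$mean_qaly, se_cost = x$se_cost, se_qaly = x$se_qaly,
         n_women = x$n_women, horizon = x$horizon, provenance = x$provenance)
}

utilities_from <- function(pars) {
  c(np = pars$u_nonpregnant, preg = pars$u_pregnant,
    ph = pars$u_hysterectomy, dead = pars$u_dead)
}

#' Run the first-order Monte Carlo cohort simulation
#'
#' Simulates `n_women` independent reproductive lifetimes under one strategy.
#' Each woman enters at age 14, possibly with a history of hysterectomy or of
#' cesarean section, and cycles annually for `horizon` years: non-pregnant
#' women face the annual pregnancy probability; a pregnancy resolves within
#' the cycle through the delivery-episode tree ([episode_leaves()] documents
#' the wiring); death is absorbing and post-hysterectomy women do not become
#' pregnant again. Utilities use a half-cycle convention (the cycle credit is
#' the mean of the within-cycle and exit-state utilities), so a woman dying in
#' childbirth collects half of the pregnant-state utility that year.
#'
#' All randomness comes from a single uniform-draw array indexed by
#' (woman, cycle, slot) generated from `seed`, so results are bitwise
#' reproducible and two strategies run with the same seed share their random
#' numbers (common random numbers for paired comparisons).
#'
#' @param strategy One-row strategy tibble (see [strategy()], [strategies()]).
#' @param params A `cesim_params`, by default the published baselines.
#' @param prior_tab Prior-CS probability table.
#' @param n_women Cohort size (default 10,000 first-order simulations).
#' @param horizon Number of one-year cycles (default 35: ages 14 to 49).
#' @param seed RNG seed.
#' @param half_cycle Apply the half-cycle utility correction (default TRUE).
#' @param discount_cost,discount_qaly Annual discount rates (default 0).
#' @return A `cesim_cohort`: mean cost and QALYs per woman with Monte Carlo
#'   standard errors, and cohort-total event tallies.
#' @examples
#' \donttest{
#' res <- run_cohort(strategies()[1, ], n_women = 500, seed = 1)
#' glance(res)
#' }
#' @export
run_cohort <- function(strategy, params = baseline_params(),
                       prior_tab = prior_cs_table(), n_women = 10000L,
                       horizon = 35L, seed = 1L, half_cycle = TRUE,
                       discount_cost = 0, discount_qaly = 0) {
  strat <- as_strategy_row(strategy)
  pars <- as.list(params$values)
  n <- as.integer(n_women)
  horizon <- as.integer(horizon)
  stopifnot(n >= 1L, horizon >= 1L)
  u_st <- utilities_from(pars)

  set.seed(as.integer(seed))
  u_init <- matrix(runif(n * 2L), n, 2L)
  # one pregnancy slot + the episode slots per woman-cycle
  K <- N_EP_SLOTS + 1L
  U <- array(runif(as.double(n) * horizon * K), dim = c(n, horizon, K))

  # states: 1 non-pregnant, 2 post-hysterectomy, 3 dead
  state <- ifelse(u_init[, 1] < pars$p_hist_hysterectomy, 2L, 1L)
  cs_count <- as.integer(state == 1L & u_init[, 2] < strat$p_hist_cs)

  cost_i <- numeric(n)
  qaly_i <- numeric(n)
  ev_names <- tally_events()
  totals <- setNames(numeric(length(ev_names)), ev_names)

  for (t in seq_len(horizon)) {
    dfc <- 1 / (1 + discount_cost)^(t - 1)
    dfq <- 1 / (1 + discount_qaly)^(t - 1)
    np <- state == 1L
    preg <- np & U[, t, 1L] < pars$p_pregnancy
    u_mid <- c(u_st[["np"]], u_st[["ph"]], u_st[["dead"]])[state]
    u_mid[preg] <- u_st[["preg"]]
    idx <- which(preg)
    if (length(idx)) {
      uu <- U[idx, t, -1L, drop = FALSE]
      dim(uu) <- c(length(idx), K - 1L)
      ep <- sim_episode(cs_count[idx], uu, pars, strat, prior_tab)
      cost_i[idx] <- cost_i[idx] + dfc * ep$cost
      cs_count[idx] <- cs_count[idx] + as.integer(ep$mode_cs)
      state[idx] <- ifelse(ep$died, 3L, ifelse(ep$hyst, 2L, 1L))
      totals["pregnancies_to_term"] <- totals["pregnancies_to_term"] + length(idx)
      totals["cesarean_sections"] <- totals["cesarean_sections"] + sum(ep$mode_cs)
      totals["vaginal_deliveries"] <- totals["vaginal_deliveries"] + sum(!ep$mode_cs)
      totals["tolac"] <- totals["tolac"] + sum(ep$tolac)
      totals["vbac"] <- totals["vbac"] + sum(ep$vbac)
      totals["previa"] <- totals["previa"] + sum(ep$previa)
      totals["accreta"] <- totals["accreta"] + sum(ep$accreta)
      totals["uterine_rupture"] <- totals["uterine_rupture"] + sum(ep$rupture)
      totals["pph_transfusion"] <- totals["pph_transfusion"] + sum(ep$pph)
      totals["peripartum_hysterectomy"] <- totals["peripartum_hysterectomy"] + sum(ep$hyst)
      totals["icu_admissions"] <- totals["icu_admissions"] + sum(ep$icu)
      totals["fistula"] <- totals["fistula"] + sum(ep$fistula)
      totals["incontinence"] <- totals["incontinence"] + sum(ep$incontinence)
      totals["stroke"] <- totals["stroke"] + sum(ep$stroke)
      totals["live_births"] <- totals["live_births"] + sum(!ep$neonate_died)
      totals["neonatal_deaths"] <- totals["neonatal_deaths"] + sum(ep$neonate_died)
      totals["maternal_deaths"] <- totals["maternal_deaths"] + sum(ep$died)
    }
    u_exit <- c(u_st[["np"]], u_st[["ph"]], u_st[["dead"]])[state]
    u_cycle <- if (half_cycle) 0.5 * (u_mid + u_exit) else u_mid
    qaly_i <- qaly_i + dfq * u_cycle
  }

  new_cohort_result(
    strategy_id = strat$id,
    mean_cost = mean(cost_i), mean_qaly = mean(qaly_i),
    se_cost = stats::sd(cost_i) / sqrt(n), se_qaly = stats::sd(qaly_i) / sqrt(n),
    tally = totals, n_women = n, horizon = horizon, seed = as.integer(seed),
    provenance = "monte_carlo"
  )
}

#' Exact expected-value evaluation of a strategy
#'
#' Computes the exact expectation of cost, QALYs and every event tally by a
#' per-cycle recursion over the model's Markov state space: non-pregnant
#' crossed with the prior-CS count (capped at the prior-CS table's top row,
#' above which episode dynamics are constant, so the recursion is exact at
#' any horizon), post-hysterectomy and dead. Delivery episodes enter through
#' their exhaustively enumerated leaves ([episode_leaves()]). The evaluator
#' is deterministic — standard errors are zero — and serves both as the
#' verification oracle for the Monte Carlo engine and as the jitter-free
#' objective for calibration and deterministic sensitivity sweeps.
#'
#' @inheritParams run_cohort
#' @param n_women Nominal cohort size used to scale the expected tallies
#'   (results are expectations; `n_women` only sets the reporting scale).
#' @return A `cesim_cohort` with provenance `"expected_value"`.
#' @examples
#' ev <- expected_value(strategies()[1, ], horizon = 5)
#' ev$mean_qaly
#' @export
expected_value <- function(strategy, params = baseline_params(),
                           prior_tab = prior_cs_table(), n_women = 10000L,
                           horizon = 35L, half_cycle = TRUE,
                           discount_cost = 0, discount_qaly = 0) {
  strat <- as_strategy_row(strategy)
  pars <- as.list(params$values)
  horizon <- as.integer(horizon)
  u_st <- utilities_from(pars)
  cmax <- max(prior_tab$prior_cs_count)
  counts <- 0:cmax
  ev_names <- tally_events()

  # per-count episode summaries from the leaf enumeration
  leaf_ev <- function(lv) {
    c(pregnancies_to_term = 1,
      vaginal_deliveries = sum(lv$.p * !lv$mode_cs),
      cesarean_sections = sum(lv$.p * lv$mode_cs),
      tolac = sum(lv$.p * lv$tolac), vbac = sum(lv$.p * lv$vbac),
      previa = sum(lv$.p * lv$previa), accreta = sum(lv$.p * lv$accreta),
      uterine_rupture = sum(lv$.p * lv$rupture),
      pph_transfusion = sum(lv$.p * lv$pph),
      peripartum_hysterectomy = sum(lv$.p * lv$hyst),
      icu_admissions = sum(lv$.p * lv$icu),
      fistula = sum(lv$.p * lv$fistula),
      incontinence = sum(lv$.p * lv$incontinence),
      stroke = sum(lv$.p * lv$stroke),
      live_births = sum(lv$.p * !lv$neonate_died),
      neonatal_deaths = sum(lv$.p * lv$neonate_died),
      maternal_deaths = sum(lv$.p * lv$died))[ev_names]
  }
  nC <- length(counts)
  e_cost <- numeric(nC)
  e_uexit <- numeric(nC)
  p_die <- numeric(nC)
  p_hys <- numeric(nC)
  trans_np <- matrix(0, nC, nC)
  e_events <- matrix(0, nC, length(ev_names),
                     dimnames = list(NULL, ev_names))
  for (i in seq_len(nC)) {
    lv <- episode_leaves(counts[i], params, strategy, prior_tab)
    e_cost[i] <- sum(lv$.p * lv$cost)
    p_die[i] <- sum(lv$.p * lv$died)
    surv <- !lv$died
    p_hys[i] <- sum(lv$.p * (lv$hyst & surv))
    stay <- surv & !lv$hyst
    cprime <- pmin(counts[i] + lv$cs_inc, cmax)
    for (j in seq_len(nC)) {
      trans_np[i, j] <- sum(lv$.p * (stay & cprime == counts[j]))
    }
    e_uexit[i] <- sum(lv$.p * ifelse(lv$died, u_st[["dead"]],
                                     ifelse(lv$hyst, u_st[["ph"]], u_st[["np"]])))
    e_events[i, ] <- leaf_ev(lv)
  }
  u_epi <- if (half_cycle) 0.5 * u_st[["preg"]] + 0.5 * e_uexit
           else rep(u_st[["preg"]], nC)

  # initial distribution: (NP_0..NP_cmax, PH, DEAD)
  ph0 <- pars$p_hist_hysterectomy
  s_np <- numeric(nC)
  s_np[1] <- (1 - ph0) * (1 - strat$p_hist_cs)
  s_np[2] <- (1 - ph0) * strat$p_hist_cs
  s_ph <- ph0
  s_dead <- 0

  pp <- pars$p_pregnancy
  cost <- 0
  qaly <- 0
  events <- setNames(numeric(length(ev_names)), ev_names)
  for (t in seq_len(horizon)) {
    dfc <- 1 / (1 + discount_cost)^(t - 1)
    dfq <- 1 / (1 + discount_qaly)^(t - 1)
    m <- s_np * pp
    cost <- cost + dfc * sum(m * e_cost)
    events <- events + colSums(m * e_events)
    qaly <- qaly + dfq * (sum(s_np * ((1 - pp) * u_st[["np"]] + pp * u_epi)) +
                            s_ph * u_st[["ph"]] + s_dead * u_st[["dead"]])
    new_np <- s_np * (1 - pp) + as.numeric(m %*% trans_np)
    s_ph <- s_ph + sum(m * p_hys)
    s_dead <- s_dead + sum(m * p_die)
    s_np <- new_np
  }

  new_cohort_result(
    strategy_id = strat$id, mean_cost = cost, mean_qaly = qaly,
    se_cost = 0, se_qaly = 0, tally = events * n_women,
    n_women = as.integer(n_women), horizon = horizon, seed = NA_integer_,
    provenance = "expected_value"
  )
}
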