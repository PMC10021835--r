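#' Event counters tracked per woman
#'
#' @return Character vector of tally names. `pph_transfusion` counts every
#'   post-partum hemorrhage; the transfusion cost is applied only when the
#'   woman delivered with CEmOC access (without access no transfusion is
#'   available, the event is tallied but uncosted).
#' @export
tally_events <- function() {
  c("pregnancies_to_term", "vaginal_deliveries", "cesarean_sections",
    "tolac", "vbac", "previa", "accreta", "uterine_rupture",
    "pph_transfusion", "peripartum_hysterectomy", "icu_admissions",
    "fistula", "incontinence", "stroke",
    "live_births", "neonatal_deaths", "maternal_deaths")
}

leaf_flag_cols <- c("mode_cs", "tolac", "vbac", "accreta", "previa", "rupture",
                    "pph", "hyst", "icu", "d_ind", "d_pph", "d_icu",
                    "fistula", "incontinence", "stroke", "neonate_died")

mk_branch <- function(p, ...) {
  row <- as.list(setNames(rep(FALSE, length(leaf_flag_cols)), leaf_flag_cols))
  on <- c(...)
  if (length(on)) row[on] <- TRUE
  row <- c(list(.p = p), row)
  as.data.frame(row)
}

# Split every row of `df` on a Bernoulli flag `name` with probability `p`
# (scalar or function of the rows, for conditional draws); zero-probability
# branches are pruned.
branch_expand <- function(df, name, p) {
  if (!nrow(df)) return(df)
  pv <- if (is.function(p)) p(df) else rep(p, nrow(df))
  pv <- pmin(pmax(pv, 0), 1)
  t <- df
  t[[name]] <- TRUE
  t$.p <- t$.p * pv
  f <- df
  f$.p <- f$.p * (1 - pv)
  out <- rbind(t, f)
  out[out$.p > 0, , drop = FALSE]
}

chain_icu <- function(df, pars) {
  df <- branch_expand(df, "icu", function(d) ifelse(d$hyst, pars$p_icu_hysterectomy, 0))
  branch_expand(df, "d_icu", function(d) ifelse(d$icu, pars$p_mort_icu, 0))
}

# Cesarean with facility access: optional context-specific PPH, a
# hysterectomy draw (context-specific or the emergency-during-CS rate), the
# ICU chain, and any indication-specific mortality.
chain_cs_access <- function(df, p_pph, p_hyst, p_mort_ind, pars) {
  if (p_pph > 0) df <- branch_expand(df, "pph", p_pph)
  df <- branch_expand(df, "hyst", p_hyst)
  df <- chain_icu(df, pars)
  if (p_mort_ind > 0) df <- branch_expand(df, "d_ind", p_mort_ind)
  df
}

# Vaginal delivery with access: PPH (with its with-access mortality),
# peripartum hysterectomy, ICU chain.
chain_vag_access <- function(df, pars) {
  df <- branch_expand(df, "pph", pars$p_pph_vaginal)
  df <- branch_expand(df, "d_pph", function(d) ifelse(d$pph, pars$p_mort_pph_vaginal, 0))
  df <- branch_expand(df, "hyst", pars$p_hyst_vaginal)
  chain_icu(df, pars)
}

# Any delivery without access: vaginal, no transfusion/hysterectomy/ICU;
# PPH carries the without-access mortality; unmet absolute indications add
# obstructed-labor sequelae draws.
chain_noaccess <- function(df, p_pph, p_mort_ind, sequelae, pars) {
  df <- branch_expand(df, "pph", p_pph)
  df <- branch_expand(df, "d_pph", function(d) ifelse(d$pph, pars$p_mort_pph_no_access, 0))
  if (p_mort_ind > 0) df <- branch_expand(df, "d_ind", p_mort_ind)
  if (sequelae) {
    df <- branch_expand(df, "fistula", pars$p_fistula)
    df <- branch_expand(df, "incontinence", pars$p_incontinence)
    df <- branch_expand(df, "stroke", pars$p_stroke)
  }
  df
}

#' Exhaustively enumerate the delivery-episode tree
#'
#' Lists every leaf of the delivery decision tree for a woman with a given
#' number of prior cesareans: the access draw, the antepartum branch
#' (placenta accreta, placenta previa, other absolute antepartum indication,
#' non-indicated antepartum CS), the labor branch (TOLAC versus elective
#' repeat CS for women with prior CS; intrapartum indication or non-indicated
#' intrapartum CS otherwise) and all downstream complication, mortality and
#' neonatal outcomes, each with its exact path probability. The enumeration
#' is the audit surface for the tree wiring and the basis of the exact
#' expected-value evaluator; leaf probabilities sum to one.
#'
#' @param prior_cs Number of prior cesarean sections (scalar; values above
#'   the prior-CS table's top row use the top row).
#' @param params A `cesim_params` parameter set.
#' @param strategy A one-row strategy (see [strategy()]).
#' @param prior_tab Prior-CS probability table, see [prior_cs_table()].
#' @return A tibble of leaves: path probability `.p`, `access`, outcome flags
#'   (mode, complications, deaths), `cost` (2016 USD) and `cs_inc` (whether
#'   the episode increments the prior-CS count).
#' @examples
#' lv <- episode_leaves(0, baseline_params(), strategies()[1, ])
#' sum(lv$.p)
#' @export
episode_leaves <- function(prior_cs, params, strategy,
                           prior_tab = prior_cs_table()) {
  strat <- as_strategy_row(strategy)
  pars <- as.list(params$values)
  ri <- prior_cs_row(prior_cs, prior_tab)
  p_a <- prior_tab$p_accreta[ri]
  p_v <- prior_tab$p_previa[ri]
  p_er <- prior_tab$p_elective_repeat[ri]
  p_g <- pars$p_antepartum_indication
  p_na <- strat$p_nonind_antepartum
  p_ni <- strat$p_nonind_intrapartum
  p_ii <- pars$p_intrapartum_indication
  p_rupt <- pars$p_rupture_tolac
  has_prior <- prior_cs > 0

  ## --- with access -------------------------------------------------------
  acc <- list()
  acc$accreta <- chain_cs_access(
    mk_branch(p_a, "accreta", "mode_cs"),
    pars$p_pph_accreta, pars$p_hyst_accreta, pars$p_mort_antepartum_ind, pars)
  acc$previa <- chain_cs_access(
    mk_branch((1 - p_a) * p_v, "previa", "mode_cs"),
    pars$p_pph_previa, pars$p_em_hyst_cs, pars$p_mort_antepartum_ind, pars)
  acc$ante_ind <- chain_cs_access(
    mk_branch((1 - p_a) * (1 - p_v) * p_g, "mode_cs"),
    0, pars$p_em_hyst_cs, pars$p_mort_antepartum_ind, pars)
  rem <- (1 - p_a) * (1 - p_v) * (1 - p_g)
  acc$nonind_ante <- chain_cs_access(
    mk_branch(rem * p_na, "mode_cs"), 0, pars$p_em_hyst_cs, 0, pars)
  rem <- rem * (1 - p_na)
  if (has_prior) {
    acc$elective_repeat <- chain_cs_access(
      mk_branch(rem * p_er, "mode_cs"), 0, pars$p_em_hyst_cs, 0, pars)
    tol <- rem * (1 - p_er)
    acc$tolac_rupture <- chain_cs_access(
      mk_branch(tol * p_rupt, "mode_cs", "tolac", "rupture"),
      pars$p_pph_rupture, pars$p_hyst_rupture, pars$p_mort_intrapartum_ind, pars)
    tol <- tol * (1 - p_rupt)
    acc$tolac_conversion <- chain_cs_access(
      mk_branch(tol * pars$p_intra_cs_tolac, "mode_cs", "tolac"),
      0, pars$p_em_hyst_cs, 0, pars)
    tol <- tol * (1 - pars$p_intra_cs_tolac)
    acc$tolac_nonind <- chain_cs_access(
      mk_branch(tol * p_ni, "mode_cs", "tolac"), 0, pars$p_em_hyst_cs, 0, pars)
    acc$vbac <- chain_vag_access(
      mk_branch(tol * (1 - p_ni), "tolac", "vbac"), pars)
  } else {
    acc$intra_ind <- chain_cs_access(
      mk_branch(rem * p_ii, "mode_cs"), 0, pars$p_em_hyst_cs,
      pars$p_mort_intrapartum_ind, pars)
    acc$nonind_intra <- chain_cs_access(
      mk_branch(rem * (1 - p_ii) * p_ni, "mode_cs"),
      0, pars$p_em_hyst_cs, 0, pars)
    acc$vaginal <- chain_vag_access(
      mk_branch(rem * (1 - p_ii) * (1 - p_ni)), pars)
  }
  acc <- do.call(rbind, acc)
  acc$access <- TRUE
  acc$.p <- acc$.p * strat$access

  ## --- without access ----------------------------------------------------
  noa <- list()
  noa$accreta <- chain_noaccess(
    mk_branch(p_a, "accreta", "neonate_died"),
    pars$p_pph_accreta, pars$p_mort_antepartum_ind, TRUE, pars)
  noa$previa <- chain_noaccess(
    mk_branch((1 - p_a) * p_v, "previa", "neonate_died"),
    pars$p_pph_previa, pars$p_mort_antepartum_ind, TRUE, pars)
  noa$ante_ind <- chain_noaccess(
    mk_branch((1 - p_a) * (1 - p_v) * p_g, "neonate_died"),
    pars$p_pph_vaginal, pars$p_mort_antepartum_ind, TRUE, pars)
  remn <- (1 - p_a) * (1 - p_v) * (1 - p_g)
  if (has_prior) {
    noa$rupture <- chain_noaccess(
      mk_branch(remn * p_rupt, "rupture", "neonate_died"),
      pars$p_pph_rupture, pars$p_mort_intrapartum_ind, TRUE, pars)
    remn <- remn * (1 - p_rupt)
  }
  noa$intra_ind <- chain_noaccess(
    mk_branch(remn * p_ii, "neonate_died"),
    pars$p_pph_vaginal, pars$p_mort_intrapartum_ind, TRUE, pars)
  noa$uncomplicated <- chain_noaccess(
    mk_branch(remn * (1 - p_ii)), pars$p_pph_vaginal, 0, FALSE, pars)
  noa <- do.call(rbind, noa)
  noa$access <- FALSE
  noa$.p <- noa$.p * (1 - strat$access)

  lv <- rbind(acc, noa)
  lv <- lv[lv$.p > 0, , drop = FALSE]
  lv$died <- lv$d_ind | lv$d_pph | lv$d_icu
  lv$cs_inc <- lv$mode_cs
  lv$cost <- ifelse(lv$mode_cs, pars$cost_cs, pars$cost_vaginal) +
    ifelse(lv$pph & lv$access, pars$cost_pph, 0) +
    ifelse(lv$hyst, pars$cost_hysterectomy, 0) +
    ifelse(lv$icu, pars$cost_icu, 0)
  rownames(lv) <- NULL
  as_tibble(lv)
}

# Uniform-draw slot layout for one delivery episode (columns of `u`).
EP_SLOTS <- c(access = 1L, accreta = 2L, previa = 3L, ante_ind = 4L,
              nonind_ante = 5L, er = 6L, rupture = 7L, intra = 8L,
              nonind_intra = 9L, pph = 10L, hyst = 11L, icu = 12L,
              mort_ind = 13L, mort_pph = 14L, mort_icu = 15L,
              fistula = 16L, incontinence = 17L, stroke = 18L)
N_EP_SLOTS <- length(EP_SLOTS)

# Vectorised delivery episode: one row of `u` (uniforms in fixed slot order)
# per pregnant woman. Returns outcome vectors. Must mirror episode_leaves().
sim_episode <- function(cs_count, u, pars, strat, prior_tab) {
  n <- length(cs_count)
  ri <- prior_cs_row(cs_count, prior_tab)
  p_acc_c <- prior_tab$p_accreta[ri]
  p_prev_c <- prior_tab$p_previa[ri]
  p_er_c <- prior_tab$p_elective_repeat[ri]

  acc_ok <- u[, EP_SLOTS["access"]] < strat$access
  accreta <- u[, EP_SLOTS["accreta"]] < p_acc_c
  previa <- !accreta & u[, EP_SLOTS["previa"]] < p_prev_c
  gen_ante <- !accreta & !previa &
    u[, EP_SLOTS["ante_ind"]] < pars$p_antepartum_indication
  ante_ind <- accreta | previa | gen_ante
  has_prior <- cs_count > 0

  # with access
  na_cs <- acc_ok & !ante_ind & u[, EP_SLOTS["nonind_ante"]] < strat$p_nonind_antepartum
  labor_a <- acc_ok & !ante_ind & !na_cs
  er <- labor_a & has_prior & u[, EP_SLOTS["er"]] < p_er_c
  tolac <- labor_a & has_prior & !er
  rupt_a <- tolac & u[, EP_SLOTS["rupture"]] < pars$p_rupture_tolac
  conv <- tolac & !rupt_a & u[, EP_SLOTS["intra"]] < pars$p_intra_cs_tolac
  ni_t <- tolac & !rupt_a & !conv &
    u[, EP_SLOTS["nonind_intra"]] < strat$p_nonind_intrapartum
  vbac <- tolac & !rupt_a & !conv & !ni_t
  labor0 <- labor_a & !has_prior
  ii <- labor0 & u[, EP_SLOTS["intra"]] < pars$p_intrapartum_indication
  ni0 <- labor0 & !ii & u[, EP_SLOTS["nonind_intra"]] < strat$p_nonind_intrapartum
  vag0 <- labor0 & !ii & !ni0

  # without access (all vaginal)
  noa <- !acc_ok
  rupt_n <- noa & !ante_ind & has_prior &
    u[, EP_SLOTS["rupture"]] < pars$p_rupture_tolac
  ii_n <- noa & !ante_ind & !rupt_n &
    u[, EP_SLOTS["intra"]] < pars$p_intrapartum_indication
  abs_ind_n <- noa & (ante_ind | rupt_n | ii_n)

  mode_cs <- acc_ok & (ante_ind | na_cs | er | rupt_a | conv | ni_t | ii | ni0)
  rupture <- rupt_a | rupt_n
  vaginal_access <- acc_ok & (vbac | vag0)

  p_pph <- rep(0, n)
  p_pph[accreta] <- pars$p_pph_accreta
  p_pph[previa] <- pars$p_pph_previa
  p_pph[rupture] <- pars$p_pph_rupture
  p_pph[vaginal_access] <- pars$p_pph_vaginal
  p_pph[noa & !accreta & !previa & !rupt_n] <- pars$p_pph_vaginal
  pph <- u[, EP_SLOTS["pph"]] < p_pph

  p_h <- rep(0, n)
  p_h[mode_cs] <- pars$p_em_hyst_cs
  p_h[acc_ok & accreta] <- pars$p_hyst_accreta
  p_h[rupt_a] <- pars$p_hyst_rupture
  p_h[vaginal_access] <- pars$p_hyst_vaginal
  hyst <- u[, EP_SLOTS["hyst"]] < p_h
  icu <- hyst & u[, EP_SLOTS["icu"]] < pars$p_icu_hysterectomy

  p_mi <- rep(0, n)
  p_mi[ante_ind] <- pars$p_mort_antepartum_ind
  p_mi[rupture | ii | ii_n] <- pars$p_mort_intrapartum_ind
  d_ind <- u[, EP_SLOTS["mort_ind"]] < p_mi

  p_mp <- rep(0, n)
  p_mp[pph & vaginal_access] <- pars$p_mort_pph_vaginal
  p_mp[pph & noa] <- pars$p_mort_pph_no_access
  d_pph <- u[, EP_SLOTS["mort_pph"]] < p_mp
  d_icu <- icu & u[, EP_SLOTS["mort_icu"]] < pars$p_mort_icu
  died <- d_ind | d_pph | d_icu

  fistula <- abs_ind_n & u[, EP_SLOTS["fistula"]] < pars$p_fistula
  incontinence <- abs_ind_n & u[, EP_SLOTS["incontinence"]] < pars$p_incontinence
  stroke <- abs_ind_n & u[, EP_SLOTS["stroke"]] < pars$p_stroke

  cost <- ifelse(mode_cs, pars$cost_cs, pars$cost_vaginal) +
    (pph & acc_ok) * pars$cost_pph + hyst * pars$cost_hysterectomy +
    icu * pars$cost_icu

  list(mode_cs = mode_cs, tolac = tolac, vbac = vbac, accreta = accreta,
       previa = previa, rupture = rupture, pph = pph, hyst = hyst, icu = icu,
       fistula = fistula, incontinence = incontinence, stroke = stroke,
       neonate_died = abs_ind_n, died = died, cost = cost)
}

#' Simulate standalone delivery episodes
#'
#' Runs `n` independent delivery episodes for women with a fixed number of
#' prior cesareans, outside the Markov cycle — useful for inspecting the
#' episode-level event distribution directly.
#'
#' @param n Number of episodes.
#' @inheritParams episode_leaves
#' @param seed RNG seed.
#' @return A tibble with one row per episode (mode, events, mortality, cost).
#' @export
delivery_episode <- function(n, prior_cs, params, strategy,
                             prior_tab = prior_cs_table(), seed = 1L) {
  strat <- as_strategy_row(strategy)
  pars <- as.list(params$values)
  set.seed(as.integer(seed))
  u <- matrix(runif(n * N_EP_SLOTS), nrow = n)
  out <- sim_episode(rep(as.integer(prior_cs), n), u, pars, strat, prior_tab)
  as_tibble(out)
}
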