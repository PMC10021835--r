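# Shared fixtures and an independent frontier oracle.

base_ps <- baseline_params()
base_strats <- strategies()

quick_strategy <- function(access = 0.5, target = 0.2, hist = 0.1,
                           na = 0.01, ni = 0.02, id = "q") {
  strategy(id, access, target, p_hist_cs = hist,
           p_nonind_antepartum = na, p_nonind_intrapartum = ni)
}

# Zero out every complication, indication and mortality probability so only
# pregnancy, access and delivery mode remain.
zero_complications <- function(ps) {
  set_params(ps,
    p_hist_hysterectomy = 0, p_antepartum_indication = 0, p_pph_vaginal = 0,
    p_hyst_vaginal = 0, p_rupture_tolac = 0, p_pph_accreta = 0,
    p_hyst_accreta = 0, p_pph_previa = 0, p_hyst_rupture = 0,
    p_icu_hysterectomy = 0, p_mort_icu = 0, p_intrapartum_indication = 0,
    p_mort_antepartum_ind = 0, p_mort_intrapartum_ind = 0,
    p_mort_pph_vaginal = 0, p_em_hyst_cs = 0, p_pph_rupture = 0,
    p_mort_pph_no_access = 0, p_fistula = 0, p_incontinence = 0,
    p_stroke = 0)
}

# A prior-CS table with no previa/accreta risk and full elective repeat,
# handy for pinning delivery modes.
flat_prior_tab <- function(p_er = 1) {
  tibble::tibble(prior_cs_count = 0:3, p_previa = 0, p_accreta = 0,
                 p_elective_repeat = c(0, rep(p_er, 3)))
}

# Independent frontier oracle: greedy lower-convex-hull construction on the
# (qaly, cost) plane, built without reference to build_frontier()'s
# dominance bookkeeping.
hull_frontier <- function(df) {
  df <- df[order(df$cost, -df$qaly), ]
  sel <- 1L
  repeat {
    last <- sel[length(sel)]
    cand <- which(df$qaly > df$qaly[last] + 1e-12)
    if (!length(cand)) break
    ic <- (df$cost[cand] - df$cost[last]) / (df$qaly[cand] - df$qaly[last])
    sel <- c(sel, cand[which.min(ic)])
  }
  sort(df$strategy_id[sel])
}
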