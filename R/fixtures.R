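#' Generate a randomized, valid parameter table
#'
#' Produces a registry-format table with the same ids and units as the
#' shipped registry but randomized values: probabilities uniform on a
#' moderate range (every decision node is binary, so any value in (0, 1) is
#' feasible), costs log-uniform on \[10, 5000\] USD, utilities uniform on
#' \[0.5, 1\] (the dead-state utility stays 0). Distribution parameters are
#' rebuilt around the new baselines so the table passes [validate_registry()]
#' unchanged. Used by the property-style test harness to exercise every
#' invariant on inputs the analysis has never seen.
#'
#' @param seed Integer seed.
#' @return A validated `cesim_registry` tibble.
#' @examples
#' r <- random_parameter_table(seed = 3)
#' r$baseline[r$id == "cost_cs"]
#' @export
random_parameter_table <- function(seed) {
  reg <- param_registry()
  set.seed(as.integer(seed))
  for (i in seq_len(nrow(reg))) {
    if (reg$id[i] == "u_dead") next
    u <- reg$units[i]
    if (u == "probability") {
      m <- runif(1, 0.001, 0.6)
      reg$baseline[i] <- m
      reg$family[i] <- "beta"
      reg$params[[i]] <- c(m * 200, (1 - m) * 200)
    } else if (u == "usd_2016") {
      m <- exp(runif(1, log(10), log(5000)))
      reg$baseline[i] <- m
      reg$family[i] <- "gamma"
      reg$params[[i]] <- c(16, m / 16)
    } else if (u == "utility") {
      m <- runif(1, 0.5, 1)
      reg$baseline[i] <- m
      reg$family[i] <- "uniform"
      reg$params[[i]] <- c(max(0, m - 0.05), min(1, m + 0.05))
    }
  }
  validate_registry(reg)
}

#' Degenerate scenarios with closed-form expected outcomes
#'
#' A fixed battery of boundary scenarios whose outcomes are known exactly,
#' used to pin the engine's arithmetic:
#' \describe{
#'   \item{zero_fertility}{No pregnancies ever: mean QALYs equal the horizon
#'     exactly, mean cost 0.}
#'   \item{certain_pregnancy_no_complications}{Pregnancy every cycle, full
#'     access, all complication/indication/non-indicated probabilities 0:
#'     every cycle is one vaginal facility delivery (cost 153.70) and the
#'     cycle utility is (0.99 + 1)/2 under the half-cycle rule.}
#'   \item{no_access_certain_indication}{No access and a certain absolute
#'     antepartum indication with all mortality off: every pregnancy ends in
#'     a neonatal death, live births are 0 and the mortality rates are
#'     undefined.}
#'   \item{certain_death_first_delivery}{Pregnancy, absolute indication and
#'     indication mortality all certain with full access: the woman dies in
#'     her first cycle, collecting half the pregnant-state utility
#'     (0.495 QALYs) and one CS cost (745.66).}
#' }
#'
#' @param horizon Cycles used for the expected values (default 35).
#' @return A list of scenarios: each has `name`, `params`, `strategy`,
#'   `prior_tab` (a zero-risk prior-CS table so placental risks are off),
#'   `expected` (named list of metric values), `tolerance` and `provenance`.
#' @export
degenerate_scenarios <- function(horizon = 35L) {
  base <- baseline_params()
  flat_tab <- tibble(prior_cs_count = 0:3, p_previa = 0, p_accreta = 0,
                     p_elective_repeat = c(0, 1, 1, 1))
  zero_compl <- function(ps) {
    set_params(ps,
      p_hist_hysterectomy = 0, p_antepartum_indication = 0,
      p_pph_vaginal = 0, p_hyst_vaginal = 0, p_rupture_tolac = 0,
      p_pph_accreta = 0, p_hyst_accreta = 0, p_pph_previa = 0,
      p_hyst_rupture = 0, p_icu_hysterectomy = 0, p_mort_icu = 0,
      p_intrapartum_indication = 0, p_mort_antepartum_ind = 0,
      p_mort_intrapartum_ind = 0, p_mort_pph_vaginal = 0, p_em_hyst_cs = 0,
      p_pph_rupture = 0, p_mort_pph_no_access = 0, p_fistula = 0,
      p_incontinence = 0, p_stroke = 0)
  }
  full_access <- strategy("full_access", 1, 0.5, p_hist_cs = 0,
                          p_nonind_antepartum = 0, p_nonind_intrapartum = 0)
  no_access <- strategy("no_access", 0, 0, p_hist_cs = 0,
                        p_nonind_antepartum = 0, p_nonind_intrapartum = 0)
  cv <- pget(base, "cost_vaginal")
  list(
    list(
      name = "zero_fertility",
      params = set_params(base, p_pregnancy = 0, p_hist_hysterectomy = 0),
      strategy = full_access, prior_tab = flat_tab,
      expected = list(mean_qaly = as.numeric(horizon), mean_cost = 0),
      tolerance = 1e-9, provenance = "closed_form"
    ),
    list(
      name = "certain_pregnancy_no_complications",
      params = zero_compl(set_params(base, p_pregnancy = 1)),
      strategy = full_access, prior_tab = flat_tab,
      expected = list(
        mean_cost = horizon * cv,
        mean_qaly = horizon * (0.99 + 1) / 2,
        cs_rate = 0,
        pregnancies_per_woman = as.numeric(horizon)
      ),
      tolerance = 1e-9, provenance = "closed_form"
    ),
    list(
      name = "no_access_certain_indication",
      params = set_params(zero_compl(base), p_pregnancy = 1,
                          p_antepartum_indication = 1),
      strategy = no_access, prior_tab = flat_tab,
      expected = list(live_births = 0, neonatal_deaths_equal_pregnancies = TRUE,
                      nmr_undefined = TRUE),
      tolerance = 1e-9, provenance = "closed_form"
    ),
    list(
      name = "certain_death_first_delivery",
      params = set_params(zero_compl(base), p_pregnancy = 1,
                          p_antepartum_indication = 1,
                          p_mort_antepartum_ind = 1),
      strategy = full_access, prior_tab = flat_tab,
      expected = list(mean_qaly = 0.99 / 2,
                      mean_cost = pget(base, "cost_cs"),
                      maternal_deaths_per_woman = 1),
      tolerance = 1e-9, provenance = "closed_form"
    )
  )
}

#' Write fixture files in the package's CSV dialects
#'
#' Emits a randomized parameter table and the default prior-CS table as CSV
#' files, so tests and examples can exercise the real file-reading path.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the randomized table.
#' @return Invisibly, the written paths.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- random_parameter_table(seed)
  reg$params <- vapply(reg$params, paste, character(1), collapse = ";")
  p1 <- file.path(dir, "parameters_random.csv")
  readr::write_csv(reg, p1)
  p2 <- file.path(dir, "prior_cs_table.csv")
  readr::write_csv(prior_cs_table(), p2)
  invisible(c(registry = p1, prior_cs = p2))
}
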