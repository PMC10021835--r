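#' Define an access/CS-rate strategy
#'
#' A strategy couples a probability of access to comprehensive emergency
#' obstetric care (CEmOC) with a target overall CS rate and the prevalence of
#' prior CS among entering women. The non-indicated CS probabilities start at
#' their published baselines and are normally replaced by [calibrate()] so the
#' simulated CS-per-pregnancy rate matches the target.
#'
#' @param id Strategy identifier.
#' @param access Probability that a pregnant woman has access to CEmOC.
#' @param target_cs_rate Target overall CS rate (cesareans per full-term
#'   pregnancy).
#' @param p_hist_cs Probability that a woman enters the model with a prior CS.
#' @param p_nonind_antepartum,p_nonind_intrapartum Non-indicated CS
#'   probabilities (antepartum; intrapartum).
#' @param calibrated Whether the non-indicated probabilities have been
#'   calibrated to the target.
#' @return A one-row tibble.
#' @export
strategy <- function(id, access, target_cs_rate, p_hist_cs,
                     p_nonind_antepartum = 0.0094,
                     p_nonind_intrapartum = 0.018,
                     calibrated = FALSE) {
  out <- tibble(
    id = as.character(id), access = access, target_cs_rate = target_cs_rate,
    p_hist_cs = p_hist_cs, p_nonind_antepartum = p_nonind_antepartum,
    p_nonind_intrapartum = p_nonind_intrapartum, calibrated = calibrated
  )
  as_strategy_row(out) # validation side effect
  out
}

#' The three modelled strategies
#'
#' Strategy A extends the national-average access and CS rate to the whole
#' population, B the rural values, C the urban values. Access and prior-CS
#' prevalences are read from the supplied parameter set so that
#' probabilistic-sensitivity draws propagate into the strategies.
#'
#' @param params A `cesim_params`; defaults to the published baselines.
#' @param access_source `"table"` (default) uses the canonical input-table
#'   access probabilities (0.502/0.472/0.557); `"text"` uses the slightly
#'   different values quoted in the model description (0.4958/0.4719/0.5574).
#' @return A three-row strategy tibble (A_national, B_rural, C_urban).
#' @examples
#' strategies()
#' @export
strategies <- function(params = baseline_params(),
                       access_source = c("table", "text")) {
  access_source <- match.arg(access_source)
  acc <- if (access_source == "table") {
    c(pget(params, "p_access_national"),
      pget(params, "p_access_rural"),
      pget(params, "p_access_urban"))
  } else {
    c(0.4958, 0.4719, 0.5574)
  }
  dplyr::bind_rows(
    strategy("A_national", acc[1], 0.172, pget(params, "p_hist_cs_national"),
             pget(params, "p_nonind_antepartum"), pget(params, "p_nonind_intrapartum")),
    strategy("B_rural", acc[2], 0.128, pget(params, "p_hist_cs_rural"),
             pget(params, "p_nonind_antepartum"), pget(params, "p_nonind_intrapartum")),
    strategy("C_urban", acc[3], 0.282, pget(params, "p_hist_cs_urban"),
             pget(params, "p_nonind_antepartum"), pget(params, "p_nonind_intrapartum"))
  )
}
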