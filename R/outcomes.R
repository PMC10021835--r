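#' Convert cohort tallies into reporting units
#'
#' Expresses the simulated event tallies as events per 10,000 women per year
#' (the published reporting convention: lifetime tallies divided by the
#' horizon), as lifetime events per 10,000 women, and extrapolated to a
#' reference female population of reproductive age. Also computes the
#' maternal mortality ratio (maternal deaths per 100,000 live births) and the
#' neonatal mortality rate (neonatal deaths per 1,000 live births); with zero
#' live births these rates are undefined and reported as `NA`, not zero.
#'
#' @param result A `cesim_cohort`.
#' @param population Reference female population of reproductive age used
#'   for the national extrapolation (default 3.25e8, recovered from the
#'   published per-10k/national reporting pair for India 2018).
#' @return A `cesim_outcomes` object: `events` tibble (`event`,
#'   `per_10k_year`, `per_10k_lifetime`, `national_annual`), scalar
#'   `mmr_per_100k` and `nmr_per_1000`, and run metadata.
#' @examples
#' \donttest{
#' res <- run_cohort(strategies()[1, ], n_women = 500, seed = 1)
#' summarize_outcomes(res)
#' }
#' @export
summarize_outcomes <- function(result, population = POPULATION_DEFAULT) {
  stopifnot(result$n_women > 0)
  t <- result$tally
  per_life <- t * 10000 / result$n_women
  per_year <- per_life / result$horizon
  events <- tibble(
    event = names(t),
    per_10k_year = as.numeric(per_year),
    per_10k_lifetime = as.numeric(per_life),
    national_annual = as.numeric(per_year) * population / 10000
  )
  lb <- t[["live_births"]]
  mmr <- if (lb > 0) t[["maternal_deaths"]] * 1e5 / lb else NA_real_
  nmr <- if (lb > 0) t[["neonatal_deaths"]] * 1e3 / lb else NA_real_
  if (lb == 0) {
    warn("zero live births: MMR and NMR are undefined (reported as NA)")
  }
  structure(list(events = events, mmr_per_100k = unname(mmr),
                 nmr_per_1000 = unname(nmr), population = population,
                 n_women = result$n_women, horizon = result$horizon,
                 strategy_id = result$strategy_id),
            class = "cesim_outcomes")
}

#' @export
print.cesim_outcomes <- function(x, ...) {
  cat(sprintf("<cesim_outcomes> %s (n = %s women, %d-year horizon)\n",
              x$strategy_id, format(x$n_women), x$horizon))
  print(x$events, n = nrow(x$events))
  cat(sprintf("Maternal mortality: %s per 100,000 live births\n",
              format(x$mmr_per_100k, digits = 3)))
  cat(sprintf("Neonatal mortality: %s per 1,000 live births\n",
              format(x$nmr_per_1000, digits = 3)))
  invisible(x)
}

#' @method tidy cesim_outcomes
#' @export
tidy.cesim_outcomes <- function(x, ...) x$events

#' Signed differences between two outcome reports
#'
#' Computes alternative-minus-base differences per event, in per-10,000-women
#' -per-year and national-annual units; a positive number is an increase in
#' events under the alternative strategy.
#'
#' @param base,alt `cesim_outcomes` objects sharing the same reference
#'   population.
#' @return A tibble: `event`, `delta_per_10k_year`, `delta_national_annual`.
#' @export
difference_table <- function(base, alt) {
  if (!isTRUE(all.equal(base$population, alt$population))) {
    abort("outcome reports use different reference populations")
  }
  missing <- c(setdiff(base$events$event, alt$events$event),
               setdiff(alt$events$event, base$events$event))
  if (length(missing)) {
    abort(paste0("mismatched event keys: ", paste(unique(missing), collapse = ", ")))
  }
  dplyr::left_join(base$events, alt$events, by = "event",
                   suffix = c("_base", "_alt")) %>%
    mutate(delta_per_10k_year = .data$per_10k_year_alt - .data$per_10k_year_base,
           delta_national_annual = .data$national_annual_alt - .data$national_annual_base) %>%
    select("event", "delta_per_10k_year", "delta_national_annual")
}
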