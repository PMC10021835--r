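#' Load a parameter registry from CSV
#'
#' The registry is the single source of every model input: probabilities,
#' costs (2016 USD) and health-state utilities, each with a baseline value
#' and a sampling distribution for probabilistic sensitivity analysis. The
#' CSV dialect has columns `id, baseline, family, params, units, description,
#' source`, where `params` is a semicolon-separated numeric list. The file
#' shipped with the package (`param_registry()`) reproduces the published
#' input table for the India model verbatim.
#'
#' @param path Path to a registry CSV file.
#' @return A tibble with class `cesim_registry`: one row per parameter with
#'   parsed distribution parameters (`params` as a list column).
#' @examples
#' reg <- param_registry()
#' reg[reg$id == "cost_cs", ]
#' @export
load_registry <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("id", "baseline", "family", "params", "units")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(paste0("registry is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"description" %in% names(raw)) raw$description <- ""
  if (!"source" %in% names(raw)) raw$source <- ""
  raw$params <- lapply(strsplit(as.character(raw$params), ";", fixed = TRUE),
                       function(x) as.numeric(trimws(x)))
  validate_registry(raw)
}

#' Validate a registry table
#'
#' Checks ids for uniqueness, baselines against the range implied by their
#' units (probabilities and utilities in \[0, 1\], costs non-negative) and
#' every distribution specification for well-formedness. Problems are
#' reported by row id; any problem is a hard error.
#'
#' @param tbl A data frame in registry layout (with `params` either a list
#'   column or semicolon-separated strings).
#' @return The validated registry tibble, classed `cesim_registry`.
#' @export
validate_registry <- function(tbl) {
  tbl <- as_tibble(tbl)
  if (!is.list(tbl$params)) {
    tbl$params <- lapply(strsplit(as.character(tbl$params), ";", fixed = TRUE),
                         function(x) as.numeric(trimws(x)))
  }
  dup <- unique(tbl$id[duplicated(tbl$id)])
  if (length(dup)) {
    abort(paste0("duplicate parameter id(s): ", paste(dup, collapse = ", ")))
  }
  problems <- character()
  for (i in seq_len(nrow(tbl))) {
    id <- tbl$id[i]
    b <- tbl$baseline[i]
    units <- tbl$units[i]
    if (!units %in% c("probability", "usd_2016", "utility")) {
      problems <- c(problems, sprintf("%s: unknown units '%s'", id, units))
      next
    }
    ok <- switch(units,
      probability = is.finite(b) && b >= 0 && b <= 1,
      utility = is.finite(b) && b >= 0 && b <= 1,
      usd_2016 = is.finite(b) && b >= 0
    )
    if (!ok) {
      problems <- c(problems,
                    sprintf("%s: baseline %g outside range for units '%s'", id, b, units))
    }
    err <- dist_validate(tbl$family[i], tbl$params[[i]])
    if (!is.null(err)) problems <- c(problems, sprintf("%s: %s", id, err))
  }
  if (length(problems)) {
    abort(paste0("invalid registry rows:\n", paste("-", problems, collapse = "\n")))
  }
  class(tbl) <- c("cesim_registry", class(tbl))
  tbl
}

#' Default parameter registry
#'
#' @return The registry shipped with the package (published baseline values
#'   and distributions for the India model).
#' @export
param_registry <- function() {
  load_registry(system.file("extdata", "parameters.csv", package = "cesim"))
}

new_param_set <- function(values, provenance, seed = NA_integer_) {
  structure(list(values = values, provenance = provenance, seed = seed),
            class = "cesim_params")
}

#' Baseline parameter set
#'
#' Realises every registry parameter at its printed baseline value.
#' Complement branch probabilities are implicit: every decision node in the
#' delivery trees is binary, so each complement is `1 - p` by construction
#' and branch probabilities sum to one identically.
#'
#' @param registry A `cesim_registry`, by default the shipped one.
#' @return A `cesim_params` object (named values plus provenance).
#' @examples
#' ps <- baseline_params()
#' ps$values[["cost_cs"]]
#' @export
baseline_params <- function(registry = param_registry()) {
  new_param_set(setNames(registry$baseline, registry$id), "baseline")
}

#' @rdname baseline_params
#' @export
baseline_set <- baseline_params

#' Sample a parameter set for probabilistic sensitivity analysis
#'
#' Draws every parameter independently from its registered distribution.
#' Beta draws keep probabilities in \[0, 1\] and gamma draws keep costs
#' non-negative, so every sampled model is well-formed without clipping;
#' the same seed always yields the identical set.
#'
#' @inheritParams baseline_params
#' @param seed Integer seed for the draw.
#' @return A `cesim_params` object with provenance `"psa_sample"`.
#' @examples
#' s1 <- sample_params(seed = 7)
#' s2 <- sample_params(seed = 7)
#' identical(s1$values, s2$values)
#' @export
sample_params <- function(registry = param_registry(), seed) {
  if (missing(seed)) abort("`seed` is required for sample_params()")
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(nrow(registry)), function(i) {
    dist_draw(registry$family[i], registry$params[[i]], 1L)
  }, numeric(1))
  new_param_set(setNames(vals, registry$id), "psa_sample", as.integer(seed))
}

#' @rdname sample_params
#' @export
sample_set <- sample_params

#' Override individual parameter values
#'
#' Convenience for degenerate scenarios and one-way sweeps: returns a copy of
#' the set with the named values replaced. Unknown names are an error.
#'
#' @param params A `cesim_params` object.
#' @param ... Named scalar overrides, e.g. `p_pregnancy = 1`.
#' @return The modified `cesim_params`.
#' @examples
#' ps <- set_params(baseline_params(), p_pregnancy = 0)
#' @export
set_params <- function(params, ...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(params$values))
  if (length(unknown)) {
    abort(paste0("unknown parameter id(s): ", paste(unknown, collapse = ", ")))
  }
  params$values[names(over)] <- unlist(over)
  params
}

pget <- function(params, id) {
  v <- params$values[[id]]
  if (is.null(v)) abort(sprintf("parameter '%s' not in set", id))
  v
}

#' @export
print.cesim_params <- function(x, ...) {
  cat(sprintf("<cesim_params> %d parameters, provenance: %s%s\n",
              length(x$values), x$provenance,
              if (!is.na(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  invisible(x)
}

#' Probabilities conditional on the number of prior cesarean sections
#'
#' Placenta previa, placenta accreta and the elective-repeat-CS (versus trial
#' of labor) share all depend on how many cesareans a woman has had. The
#' shipped default table is a documented synthetic stand-in (the source model's
#' exact per-count values are unpublished): previa/accreta risks rise with CS
#' count and are anchored so their cohort-weighted marginals match the
#' published per-10,000-women event scale. Rows are keyed 0, 1, 2, 3+ and
#' counts above the top row use the top row.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `prior_cs_count, p_previa, p_accreta, p_elective_repeat`.
#' @return A validated tibble.
#' @export
prior_cs_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "prior_cs_table_synthetic.csv",
                                package = "cesim")
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("prior_cs_count", "p_previa", "p_accreta", "p_elective_repeat")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    abort(paste0("prior-CS table missing columns: ", paste(missing, collapse = ", ")))
  }
  tbl <- dplyr::arrange(tbl, .data$prior_cs_count)
  probs <- as.matrix(tbl[, c("p_previa", "p_accreta", "p_elective_repeat")])
  if (any(probs < 0) || any(probs > 1)) {
    abort("prior-CS table entries must be probabilities in [0, 1]")
  }
  if (is.unsorted(tbl$p_previa) || is.unsorted(tbl$p_accreta)) {
    abort("previa and accreta probabilities must be non-decreasing in prior CS count")
  }
  tbl
}

# Row index into the prior-CS table for a vector of counts (top row reused
# above the table's maximum count).
prior_cs_row <- function(count, tbl) {
  pmin(count, max(tbl$prior_cs_count)) + 1L
}
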