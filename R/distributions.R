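#' Distribution specifications for model parameters
#'
#' Each registry row carries a distribution family and its parameters, used
#' for probabilistic sensitivity analysis. Supported families:
#' \describe{
#'   \item{beta}{`params = c(alpha, beta)`, both strictly positive; used for
#'     probabilities.}
#'   \item{gamma}{`params = c(shape, scale)`, both strictly positive; used for
#'     costs.}
#'   \item{dirichlet}{`params` is a concentration vector of length >= 2, all
#'     positive. A draw returns the first normalised component, which for a
#'     length-2 vector is exactly a beta draw; provided for nodes whose
#'     branch probabilities are standardised jointly.}
#'   \item{uniform}{`params = c(low, high)` with `low <= high`; used for
#'     health utilities.}
#'   \item{point}{`params = value`; a degenerate distribution that always
#'     returns its value.}
#' }
#'
#' @param family Distribution family name.
#' @param params Numeric vector of distribution parameters.
#' @return `dist_validate()` returns `NULL` invisibly or a character error
#'   message; `dist_draw()` a numeric vector of draws; `dist_mean()` the
#'   analytic mean.
#' @keywords internal
#' @name distributions
NULL

dist_families <- c("beta", "gamma", "dirichlet", "uniform", "point")

#' @rdname distributions
dist_validate <- function(family, params) {
  if (!family %in% dist_families) {
    return(sprintf("unknown distribution family '%s'", family))
  }
  if (any(is.na(params)) || any(params < 0)) {
    return("distribution parameters must be non-negative and non-missing")
  }
  switch(family,
    beta = if (length(params) != 2L || any(params <= 0)) {
      "beta requires two strictly positive parameters"
    },
    gamma = if (length(params) != 2L || any(params <= 0)) {
      "gamma requires two strictly positive parameters (shape, scale)"
    },
    dirichlet = if (length(params) < 2L || any(params <= 0)) {
      "dirichlet requires a concentration vector of length >= 2, all positive"
    },
    uniform = if (length(params) != 2L || params[1] > params[2]) {
      "uniform requires low <= high"
    },
    point = if (length(params) != 1L) "point requires a single value"
  )
}

#' @param n Number of draws.
#' @rdname distributions
dist_draw <- function(family, params, n = 1L) {
  switch(family,
    beta = rbeta(n, params[1], params[2]),
    gamma = rgamma(n, shape = params[1], scale = params[2]),
    dirichlet = {
      g <- matrix(rgamma(n * length(params), shape = rep(params, each = n)),
                  nrow = n)
      g[, 1] / rowSums(g)
    },
    uniform = runif(n, params[1], params[2]),
    point = rep(params[1], n)
  )
}

#' @rdname distributions
dist_mean <- function(family, params) {
  switch(family,
    beta = params[1] / (params[1] + params[2]),
    gamma = params[1] * params[2],
    dirichlet = params[1] / sum(params),
    uniform = mean(params),
    point = params[1]
  )
}
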