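#' Model parameters for the clonality mixture
#'
#' Bundles the three parameters of the random-effects clonality model:
#' the population proportion of clonal cases `pi`, and the location and
#' scale (`mu`, `sigma`) of the clonality-signal distribution.  For a
#' clonal case the signal \eqn{\xi \in [0,1)} is the anticipated fraction
#' of its observed mutations that are matches; the model assumes
#' \eqn{-\log(1-\xi)} is lognormal, equivalently that
#' \eqn{u = \log(-\log(1-\xi))} is normal with mean `mu` and standard
#' deviation `sigma`.
#'
#' @param pi Proportion of clonal cases in the population, in `[0, 1]`.
#' @param mu Location of the signal distribution on the u scale (real).
#' @param sigma Scale of the signal distribution on the u scale
#'   (strictly positive).
#' @return An object of class `clonal_params`: a named list with
#'   elements `pi`, `mu`, `sigma`.
#' @examples
#' clonal_params(pi = 0.25, mu = -1, sigma = 1)
#' @export
clonal_params <- function(pi, mu, sigma) {
  stopifnot(is.numeric(pi), length(pi) == 1L, is.finite(pi),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (pi < 0 || pi > 1) stop("`pi` must lie in [0, 1], got ", pi)
  if (sigma <= 0) stop("`sigma` must be > 0, got ", sigma)
  structure(list(pi = pi, mu = mu, sigma = sigma), class = "clonal_params")
}

#' @export
print.clonal_params <- function(x, ...) {
  cat(sprintf("<clonal_params> pi = %.4g, mu = %.4g, sigma = %.4g\n",
              x$pi, x$mu, x$sigma))
  invisible(x)
}

as_clonal_params <- function(x) {
  if (inherits(x, "clonal_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (all(c("pi", "mu", "sigma") %in% names(x))) {
      return(clonal_params(x$pi, x$mu, x$sigma))
    }
  }
  stop("cannot interpret `params`: supply clonal_params() or a named ",
       "list with pi, mu, sigma")
}

#' Signal-distribution scenarios used in the estimator-comparison study
#'
#' Three reference shapes for the clonality-signal distribution, indexed
#' 1 to 3.  Scenario 1 (`mu = -2`, `sigma = 1.5`) concentrates the signal
#' at small values (median \eqn{\xi \approx 0.13}: few matches even in
#' clonal cases, the hardest setting for estimation); scenario 3
#' (`mu = 0.7`, `sigma = 0.3`) concentrates it near 0.87 (most mutations
#' of a clonal case are matched); scenario 2 (`mu = -1`, `sigma = 1`) is
#' intermediate.
#'
#' @param scenario Integer 1, 2 or 3.
#' @return A named list with elements `scenario`, `mu`, `sigma`.
#' @examples
#' scenario_params(3)
#' @export
scenario_params <- function(scenario) {
  stopifnot(length(scenario) == 1L, scenario %in% 1:3)
  ms <- list(c(-2, 1.5), c(-1, 1.0), c(0.7, 0.3))[[scenario]]
  list(scenario = as.integer(scenario), mu = ms[1], sigma = ms[2])
}
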