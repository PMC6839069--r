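# Internal E-step on a compiled dataset: posterior clonality weight and
# posterior moments of the transformed signal u given clonal, for every
# case, by quadrature on the grid of the current parameters.
estep_comp <- function(comp, pi, mu, sigma, grid_k) {
  q <- aghq_quantities(comp, mu, sigma, grid_k)
  lM <- q$lM
  m1 <- q$m1
  m2 <- q$m2
  if (pi <= 0) {
    w <- rep(0, comp$n)
  } else if (pi >= 1) {
    w <- rep(1, comp$n)
  } else {
    m <- pmax(lM, comp$lI)
    num <- pi * exp(lM - m)
    w <- num / (num + (1 - pi) * exp(comp$lI - m))
  }
  list(w = w, m1 = m1, m2 = m2, lM = lM)
}

#' E-step: posterior clonality weights and signal moments
#'
#' For each case computes, at the supplied parameters, the posterior
#' probability of clonality
#' \eqn{w_j = \pi M_j / \{\pi M_j + (1-\pi) I_j\}} (with
#' \eqn{M_j} the signal-marginalized clonal likelihood and \eqn{I_j}
#' the independent likelihood) and the posterior first and second
#' moments `m1`, `m2` of the transformed signal \eqn{u} given the case
#' is clonal.  At `pi = 0` or `pi = 1` the weights are the forced
#' constants 0 or 1.  An empty case has `w = pi` exactly: its data
#' carry no information.
#'
#' @inheritParams fit_em
#' @param params Model parameters ([clonal_params()] or named list).
#' @return A tibble with columns `case_id`, `w`, `m1`, `m2`.
#' @export
e_step <- function(data, params, grid_k = 64, case_ids = NULL) {
  params <- as_clonal_params(params)
  comp <- compile_case_data(data, case_ids)
  e <- estep_comp(comp, params$pi, params$mu, params$sigma, grid_k)
  tibble::tibble(case_id = comp$case_ids, w = e$w, m1 = e$m1, m2 = e$m2)
}

#' M-step: closed-form update of the mixture parameters
#'
#' Maximizes the expected complete-data log-likelihood given the E-step
#' quantities: \eqn{\hat\pi = \sum_j w_j / n},
#' \eqn{\hat\mu = \sum_j w_j m_{1j} / \sum_j w_j}, and
#' \eqn{\hat\sigma^2 = \sum_j w_j (m_{2j} - 2\hat\mu m_{1j} +
#' \hat\mu^2) / \sum_j w_j}, with \eqn{\hat\sigma} floored at
#' `sigma_min`.  If every weight is zero the clonal component carries no
#' mass: the update returns `pi = 0` and leaves `mu`, `sigma` at their
#' current values (a message notes the degenerate branch).
#'
#' @param posteriors Tibble from [e_step()] (columns `w`, `m1`, `m2`).
#' @param params Current parameters, used only by the degenerate
#'   all-zero-weight branch.
#' @param sigma_min Lower bound for `sigma` (default 0.05); prevents a
#'   point-mass signal distribution when few cases carry weight.
#' @return A [clonal_params()] object.
#' @export
m_step <- function(posteriors, params = NULL, sigma_min = 0.05) {
  stopifnot(is.data.frame(posteriors), nrow(posteriors) >= 1L,
            all(c("w", "m1", "m2") %in% names(posteriors)))
  w <- posteriors$w
  sw <- sum(w)
  pi_new <- sw / length(w)
  if (sw <= 0) {
    if (is.null(params)) {
      stop("all posterior weights are zero and no current `params` ",
           "were supplied to fall back on")
    }
    params <- as_clonal_params(params)
    message("m_step: all posterior weights zero; pi set to 0, ",
            "mu and sigma kept at current values")
    return(clonal_params(0, params$mu, params$sigma))
  }
  mu_new <- sum(w * posteriors$m1) / sw
  s2 <- sum(w * (posteriors$m2 - 2 * mu_new * posteriors$m1 +
                   mu_new^2)) / sw
  clonal_params(pi_new, mu_new, max(sqrt(max(s2, 0)), sigma_min))
}

new_clonal_fit <- function(method, params, loglik, loglik_trace, n_iter,
                           converged, boundary, posteriors, n_cases,
                           settings) {
  structure(list(method = method, params = params, loglik = loglik,
                 loglik_trace = loglik_trace, n_iter = n_iter,
                 converged = converged, boundary = boundary,
                 posteriors = posteriors, n_cases = n_cases,
                 settings = settings),
            class = "clonal_fit")
}

# Posteriors reported with a fitted object.  A boundary estimate of pi
# forces every case posterior to the same constant (the pathology that
# motivates the EM estimator); evaluate them at the snapped value so
# the forced constants are exact.
final_posteriors <- function(comp, pi, mu, sigma, grid_k, boundary) {
  if (boundary) pi <- round(pi)
  e <- estep_comp(comp, pi, mu, sigma, grid_k)
  tibble::tibble(case_id = comp$case_ids, w = e$w)
}

multistart_grid <- function(init) {
  lapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
         function(p0) clonal_params(p0, init$mu, init$sigma))
}

#' Fit the clonality mixture model by EM
#'
#' Maximizes the observed-data likelihood of the random-effects
#' clonality model by alternating [e_step()] and [m_step()].  The
#' latent variables are the per-case clonality indicator and, for
#' clonal cases, the clonality signal; because the fitted proportion
#' of clonal cases is a mean of per-case posterior weights it reaches
#' the boundary values 0 or 1 only when every individual posterior
#' does, which is what protects the EM estimator from the spurious
#' boundary estimates the one-step maximizer can produce.
#'
#' @param data A per-locus case table (see [as_case_table()]).
#' @param init Starting parameters (default
#'   `clonal_params(0.5, -1, 1)`).
#' @param grid_k Number of Gauss-Hermite nodes used to marginalize over
#'   the clonality signal (default 64).
#' @param tol Convergence tolerance: the fit stops when the
#'   observed-data log-likelihood changes by less than `tol` between
#'   iterations (default `1e-6`).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param sigma_min Floor for `sigma` in the M-step (default 0.05).
#' @param multistart If `TRUE`, the fit is repeated from five starting
#'   values of `pi` (0.1 to 0.9) with `mu`, `sigma` taken from `init`,
#'   and the fit with the best final log-likelihood is returned.
#' @param case_ids Optional vector of all case labels, including cases
#'   with no observed mutations (which cannot appear in a per-locus
#'   table but still count toward the denominator of `pi`).  Defaults
#'   to the cases present in `data`.
#' @return An object of class `clonal_fit` with elements `params`
#'   (the estimates), `loglik`, `loglik_trace` (observed-data
#'   log-likelihood per iteration, nondecreasing), `n_iter`,
#'   `converged`, `boundary` (`TRUE` when the estimated proportion is
#'   within `1e-8` of 0 or 1), `posteriors` (per-case posterior
#'   clonality probabilities at the estimates), `n_cases`, `settings`.
#' @seealso [fit_onestep()], [fit_clonality()], [posterior_clonality()]
#' @examples
#' sim <- simulate_cases(60, pi_true = 0.5, scenario = 3, seed = 1)
#' fit <- fit_em(sim$cases)
#' tidy(fit)
#' @export
fit_em <- function(data, init = clonal_params(0.5, -1, 1), grid_k = 64,
                   tol = 1e-6, max_iter = 1000,
                   sigma_min = 0.05, multistart = FALSE,
                   case_ids = NULL) {
  init <- as_clonal_params(init)
  comp <- compile_case_data(data, case_ids)
  if (comp$n == 0L) stop("no cases")
  settings <- list(init = init, grid_k = grid_k, tol = tol,
                   max_iter = max_iter,
                   sigma_min = sigma_min, multistart = multistart)
  if (length(comp$p) == 0L) {
    return(flat_likelihood_fit("em", init, comp, grid_k, settings))
  }
  if (multistart) {
    fits <- lapply(multistart_grid(init), function(st) {
      fit_em(data, init = st, grid_k = grid_k, tol = tol,
             max_iter = max_iter,
             sigma_min = sigma_min, multistart = FALSE,
             case_ids = case_ids)
    })
    best <- fits[[which.max(vapply(fits, function(f) f$loglik, 0))]]
    best$settings <- settings
    return(best)
  }

  pars <- init
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- NA_real_
  e <- NULL
  for (it in seq_len(max_iter + 1L)) {
    e <- estep_comp(comp, pars$pi, pars$mu, pars$sigma, grid_k)
    ll <- sum(mix_loglik(e$lM, comp$lI, pars$pi))
    trace[it] <- ll
    if (it > 1L && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (it == max_iter + 1L) break
    pars <- m_step(tibble::tibble(w = e$w, m1 = e$m1, m2 = e$m2),
                   params = pars, sigma_min = sigma_min)
    ll_prev <- ll
  }
  boundary <- pars$pi <= .boundary_tol || pars$pi >= 1 - .boundary_tol
  post <- final_posteriors(comp, pars$pi, pars$mu, pars$sigma, grid_k,
                           boundary)
  new_clonal_fit("em", pars, trace[length(trace)], trace,
                 n_iter = length(trace) - 1L, converged = converged,
                 boundary = boundary, posteriors = post,
                 n_cases = comp$n, settings = settings)
}

# Degenerate flat-likelihood branch (dataset with no loci at all): any
# parameter value maximizes the likelihood; return the starting values
# for determinism.
flat_likelihood_fit <- function(method, init, comp, grid_k, settings) {
  warning("dataset has no observed loci: likelihood is flat; ",
          "returning the starting values")
  boundary <- init$pi <= .boundary_tol || init$pi >= 1 - .boundary_tol
  post <- final_posteriors(comp, init$pi, init$mu, init$sigma, grid_k,
                           boundary)
  new_clonal_fit(method, init, 0, 0, n_iter = 0L, converged = TRUE,
                 boundary = boundary, posteriors = post,
                 n_cases = comp$n, settings = settings)
}

#' Fit the clonality mixture model by one-step constrained maximization
#'
#' Directly maximizes the signal-marginalized mixture log-likelihood
#' (the sum over cases of [case_marginal_loglik()]) with a
#' box-constrained quasi-Newton algorithm (`optim(method =
#' "L-BFGS-B")`) over \eqn{\pi \in [0,1]}, \eqn{\mu \in} `mu_bounds`,
#' \eqn{\sigma \in} `sigma_bounds`.  Unlike the EM fit, the estimate of
#' \eqn{\pi} can land exactly on the boundary 0 or 1, which forces all
#' per-case posterior clonality probabilities to that constant.
#'
#' @inheritParams fit_em
#' @param mu_bounds,sigma_bounds Box constraints for `mu` and `sigma`.
#' @return A `clonal_fit` object (see [fit_em()]); `n_iter` is the
#'   number of objective evaluations used by the optimizer and
#'   `loglik_trace` is empty.
#' @examples
#' sim <- simulate_cases(60, pi_true = 0.5, scenario = 3, seed = 1)
#' fit_onestep(sim$cases)
#' @export
fit_onestep <- function(data, init = clonal_params(0.5, -1, 1),
                        grid_k = 64, mu_bounds = c(-10, 10),
                        sigma_bounds = c(0.05, 10), multistart = FALSE,
                        case_ids = NULL) {
  init <- as_clonal_params(init)
  comp <- compile_case_data(data, case_ids)
  if (comp$n == 0L) stop("no cases")
  settings <- list(init = init, grid_k = grid_k, mu_bounds = mu_bounds,
                   sigma_bounds = sigma_bounds, multistart = multistart)
  if (length(comp$p) == 0L) {
    return(flat_likelihood_fit("onestep", init, comp, grid_k, settings))
  }
  if (multistart) {
    fits <- lapply(multistart_grid(init), function(st) {
      fit_onestep(data, init = st, grid_k = grid_k,
                  mu_bounds = mu_bounds, sigma_bounds = sigma_bounds,
                  multistart = FALSE, case_ids = case_ids)
    })
    best <- fits[[which.max(vapply(fits, function(f) f$loglik, 0))]]
    best$settings <- settings
    return(best)
  }

  negll <- function(par) -obs_loglik(comp, par[1], par[2], par[3], grid_k)
  opt <- tryCatch(
    optim(c(init$pi, init$mu, init$sigma), negll, method = "L-BFGS-B",
          lower = c(0, mu_bounds[1], sigma_bounds[1]),
          upper = c(1, mu_bounds[2], sigma_bounds[2])),
    error = function(e) {
      stop("one-step optimizer failed: ", conditionMessage(e),
           " [init pi=", init$pi, ", mu=", init$mu, ", sigma=",
           init$sigma, "]", call. = FALSE)
    })
  pars <- clonal_params(opt$par[1], opt$par[2], opt$par[3])
  boundary <- pars$pi <= .boundary_tol || pars$pi >= 1 - .boundary_tol
  post <- final_posteriors(comp, pars$pi, pars$mu, pars$sigma, grid_k,
                           boundary)
  new_clonal_fit("onestep", pars, -opt$value, numeric(0),
                 n_iter = unname(opt$counts["function"]),
                 converged = opt$convergence == 0, boundary = boundary,
                 posteriors = post, n_cases = comp$n,
                 settings = settings)
}

#' Fit the clonality model by one or both estimators
#'
#' Convenience wrapper around [fit_em()] and [fit_onestep()].  The
#' default enables the five-point multistart on the starting value of
#' `pi`, which is cheap at this scale and guards against local optima
#' of the mixture likelihood.
#'
#' @inheritParams fit_em
#' @param method `"em"`, `"onestep"`, or `"both"`.
#' @param ... Passed on to [fit_em()] and/or [fit_onestep()].
#' @return A `clonal_fit` for a single method; for `"both"`, a named
#'   list with elements `em` and `onestep`.
#' @examples
#' sim <- simulate_cases(60, pi_true = 0.5, scenario = 3, seed = 1)
#' fits <- fit_clonality(sim$cases, method = "both")
#' glance(fits$em)
#' @export
fit_clonality <- function(data, method = c("em", "onestep", "both"),
                          multistart = TRUE, ...) {
  method <- match.arg(method)
  dots <- list(...)
  known <- union(names(formals(fit_em)), names(formals(fit_onestep)))
  if (length(dots) && !all(names(dots) %in% known)) {
    stop("unknown argument(s): ",
         paste(setdiff(names(dots), known), collapse = ", "))
  }
  run <- function(fitter) {
    args <- dots[names(dots) %in% names(formals(fitter))]
    do.call(fitter, c(list(data, multistart = multistart), args))
  }
  switch(method,
         em = run(fit_em),
         onestep = run(fit_onestep),
         both = list(em = run(fit_em), onestep = run(fit_onestep)))
}

#' Per-case posterior probabilities of clonality
#'
#' The model's per-case diagnostic output: the posterior probability
#' that each tumor pair is clonally related, evaluated at the supplied
#' (typically fitted) parameters.  A case with no observed mutations
#' has posterior equal to `pi`; at a boundary value of `pi` every
#' posterior is the forced constant 0 or 1.
#'
#' @inheritParams e_step
#' @return A tibble with columns `case_id` and `w`.
#' @examples
#' tbl <- contralateral_breast_cases()
#' posterior_clonality(tbl, clonal_params(0.059, 0, 0.51))
#' @export
posterior_clonality <- function(data, params, grid_k = 64,
                                case_ids = NULL) {
  params <- as_clonal_params(params)
  comp <- compile_case_data(data, case_ids)
  boundary <- params$pi <= .boundary_tol || params$pi >= 1 - .boundary_tol
  final_posteriors(comp, params$pi, params$mu, params$sigma, grid_k,
                   boundary)
}

#' @export
print.clonal_fit <- function(x, ...) {
  cat(sprintf("<clonal_fit: %s>\n", x$method))
  cat(sprintf("  pi = %.4f, mu = %.4f, sigma = %.4f\n",
              x$params$pi, x$params$mu, x$params$sigma))
  cat(sprintf("  loglik = %.6f after %d iteration(s); converged: %s%s\n",
              x$loglik, x$n_iter, x$converged,
              if (x$boundary) "; pi on boundary" else ""))
  cat(sprintf("  %d cases; mean posterior clonality %.4f\n",
              x$n_cases, mean(x$posteriors$w)))
  invisible(x)
}
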