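#' Per-locus match probabilities under the clonal and independent models
#'
#' For a locus with occurrence probability `p`, conditional on the locus
#' being mutated in at least one tumor of the pair:
#'
#' * clonal case with signal \eqn{\xi}: the probability the locus is
#'   shared is \eqn{\{\xi + (1-\xi)p\} / \{\xi + (1-\xi)(2-p)\}} and
#'   private \eqn{2(1-\xi)(1-p) / \{\xi + (1-\xi)(2-p)\}};
#' * independent case: shared \eqn{p/(2-p)}, private \eqn{2(1-p)/(2-p)}.
#'
#' The two statuses partition the event, so for fixed \eqn{(\xi, p)} the
#' shared and private probabilities sum to one, and at \eqn{\xi = 0} the
#' clonal probabilities reduce exactly to the independent ones.
#'
#' @param xi Clonality signal in `[0, 1)`.  Vectorized.
#' @param p Occurrence probability in (0, 1).  Vectorized.
#' @param status `"shared"` or `"private"` (recycled).
#' @return Probability (vector).
#' @examples
#' locus_prob_clonal(0, p = 0.137, status = "shared")   # = 0.137/1.863
#' locus_prob_independent(p = 0.137, status = "shared")
#' @export
locus_prob_clonal <- function(xi, p, status = c("shared", "private")) {
  status <- match.arg(status)
  if (any(!is.finite(xi) | xi < 0 | xi >= 1)) {
    stop("`xi` must lie in [0, 1)")
  }
  if (any(!is.finite(p) | p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)")
  z <- log1p(-xi) + log1p(-p)       # log a, a = (1-xi)(1-p)
  # shared numerator 1 - a via expm1: exact even when xi and p are tiny
  if (status == "shared") -expm1(z) / (1 + exp(z)) else
    2 * exp(z) / (1 + exp(z))
}

#' @rdname locus_prob_clonal
#' @export
locus_prob_independent <- function(p, status = c("shared", "private")) {
  status <- match.arg(status)
  if (any(!is.finite(p) | p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)")
  if (status == "shared") p / (2 - p) else 2 * (1 - p) / (2 - p)
}

# Locus-level log-probabilities on the log(1-xi) scale, vectorized over
# loci x signal values.  `l1mxi` is log(1 - xi), which the quadrature
# path supplies as -exp(u) so that xi values indistinguishable from 1 in
# double precision keep an exact log(1 - xi).  Returns an L x K matrix.
locus_logprob_matrix <- function(p, shared, l1mxi) {
  Z <- outer(log1p(-p), rep(1, length(l1mxi))) +
    matrix(l1mxi, length(p), length(l1mxi), byrow = TRUE)
  denom <- log1p(exp(Z))            # log{1 + (1-xi)(1-p)}
  out <- matrix(0, length(p), length(l1mxi))
  if (any(shared)) {
    # log{1 - (1-xi)(1-p)} via expm1: stays accurate when xi and p are
    # both tiny (the numerator is then ~ xi + p)
    out[shared, ] <- log(-expm1(Z[shared, , drop = FALSE])) -
      denom[shared, , drop = FALSE]
  }
  if (any(!shared)) {
    out[!shared, ] <- log(2) + Z[!shared, , drop = FALSE] -
      denom[!shared, , drop = FALSE]
  }
  out
}

# Case-level clonal log-likelihood matrix (n_cases x K) from a compiled
# dataset; empty cases contribute 0.
case_loglik_clonal_matrix <- function(comp, l1mxi) {
  out <- matrix(0, comp$n, length(l1mxi))
  if (length(comp$p)) {
    loc <- locus_logprob_matrix(comp$p, comp$shared, l1mxi)
    out <- as.matrix(comp$G %*% loc)
  }
  out
}

#' Case-level log-likelihoods at a fixed signal value
#'
#' `case_loglik_clonal()` evaluates, for every case in the table, the
#' log-probability of its shared/private pattern under the clonal model
#' at signal `xi`; `case_loglik_independent()` the same under the
#' independent model.  Cases listed in `case_ids` but absent from the
#' table are empty and contribute 0.  `case_loglik_clonal(x, 0)` equals
#' `case_loglik_independent(x)` exactly.
#'
#' @inheritParams fit_em
#' @param xi Scalar clonality signal in `[0, 1)`.
#' @return A tibble with columns `case_id` and `loglik`.
#' @examples
#' tbl <- tibble::tibble(case_id = "a", locus_id = "l1",
#'                       gene_label = NA, p = 0.137,
#'                       in_tumor1 = 1, in_tumor2 = 1)
#' case_loglik_clonal(tbl, xi = 0.5)
#' case_loglik_independent(tbl)
#' @export
case_loglik_clonal <- function(data, xi, case_ids = NULL) {
  stopifnot(length(xi) == 1L)
  if (!is.finite(xi) || xi < 0 || xi >= 1) stop("`xi` must lie in [0, 1)")
  comp <- compile_case_data(data, case_ids)
  tibble::tibble(case_id = comp$case_ids,
                 loglik = drop(case_loglik_clonal_matrix(comp, log1p(-xi))))
}

#' @rdname case_loglik_clonal
#' @export
case_loglik_independent <- function(data, case_ids = NULL) {
  comp <- compile_case_data(data, case_ids)
  tibble::tibble(case_id = comp$case_ids, loglik = comp$lI)
}

#' Log-density of the transformed clonality signal
#'
#' The clonality signal \eqn{\xi} of a clonal case satisfies
#' \eqn{-\log(1-\xi) \sim} lognormal(`mu`, `sigma`), i.e. the
#' transformed signal \eqn{u = \log(-\log(1-\xi))} is normal with mean
#' `mu` and standard deviation `sigma`.  This returns the normal
#' log-density of `u`.
#'
#' @param u Transformed signal (real, vectorized).
#' @param mu,sigma Signal-distribution parameters; `sigma > 0`.
#' @return Log-density values.
#' @export
signal_logdensity <- function(u, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  dnorm(u, mean = mu, sd = sigma, log = TRUE)
}

#' Quadrature grid for marginalizing over the clonality signal
#'
#' Gauss-Hermite nodes and weights on the u scale, where the signal is
#' exactly normal, located at `mu + sqrt(2) * sigma * x_k`.  Weights are
#' renormalized to sum to one, so the grid integrates the signal density
#' to unity by construction and `sum(weight * f(xi))` approximates the
#' expectation of a smooth `f` under the signal law.
#'
#' @inheritParams signal_logdensity
#' @param k Number of nodes (default 64).
#' @return A tibble with columns `u` (node), `xi` (back-transformed
#'   signal \eqn{1 - e^{-e^u}}), `log1mxi` (\eqn{\log(1-\xi) = -e^u},
#'   kept exact for nodes where `xi` rounds to 1) and `weight`.
#' @examples
#' g <- signal_grid(mu = 0.7, sigma = 0.3)
#' sum(g$weight)            # 1
#' sum(g$weight * g$xi)     # E[xi] under scenario 3
#' @export
signal_grid <- function(mu, sigma, k = 64) {
  stopifnot(k >= 2)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  gh <- pracma::gaussHermite(k)
  u <- mu + sqrt(2) * sigma * gh$x
  w <- gh$w / sum(gh$w)
  tibble::tibble(u = u, xi = -expm1(-exp(u)), log1mxi = -exp(u),
                 weight = w)
}

# Fast row maxima with a -Inf guard (all--Inf rows keep 0 so that the
# subsequent log-sum-exp yields -Inf without NaN).
row_max_guarded <- function(V) {
  mx <- V[cbind(seq_len(nrow(V)), max.col(V, ties.method = "first"))]
  mx[!is.finite(mx)] <- 0
  mx
}

# Cache of Gauss-Hermite rules by node count.
.gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(k) {
  key <- as.character(k)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(k)
  .gh_cache[[key]]
}

# Per-case clonal log-likelihood at one u value per case (u: length n).
# Z = log{(1-xi)(1-p)} <= 0; the shared numerator 1 - e^Z is kept as
# -expm1(Z) for accuracy at tiny xi and p, and the denominator
# 1 + e^Z = 2 + expm1(Z) reuses the same transcendental.
case_loglik_clonal_at <- function(comp, u) {
  out <- numeric(comp$n)
  if (length(comp$p)) {
    z <- log1p(-comp$p) - exp(u[comp$idx])
    e1 <- expm1(z)
    den <- log(2 + e1)
    sh <- comp$shared
    val <- log(2) + z - den
    val[sh] <- log(-e1[sh]) - den[sh]
    out <- as.vector(comp$G %*% val)
  }
  out
}

# Clonal log-likelihood matrix at per-case node sets (U: n x K).
case_loglik_clonal_at_matrix <- function(comp, U) {
  out <- matrix(0, comp$n, ncol(U))
  if (length(comp$p)) {
    Z <- log1p(-comp$p) + (-exp(U))[comp$idx, , drop = FALSE]
    E1 <- expm1(Z)
    den <- log(2 + E1)
    sh <- comp$shared
    val <- log(2) + Z - den
    if (any(sh)) {
      val[sh, ] <- log(-E1[sh, , drop = FALSE]) - den[sh, , drop = FALSE]
    }
    out <- as.matrix(comp$G %*% val)
  }
  out
}

# Posterior-mode location and curvature scale for each case's signal
# integrand f_j(u) = log P(Y_j | xi(u), C=1) + log phi(u; mu, sigma).
# Vectorized golden-section search; the upper bracket accounts for the
# exponential tilt that k shared loci induce (mode <= mu + k sigma^2
# plus slack before saturation).
aghq_locate <- function(comp, mu, sigma) {
  c0 <- -log(sigma) - 0.5 * log(2 * base::pi)
  f <- function(u) {
    case_loglik_clonal_at(comp, u) - 0.5 * ((u - mu) / sigma)^2 + c0
  }
  lo <- rep(mu - 9 * sigma, comp$n)
  hi <- mu + comp$n_shared * sigma^2 + 9 * sigma
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  # AGHQ is insensitive to mode offsets well below the curvature scale,
  # so ~20 golden-section contractions (factor 0.618 each) are ample
  for (it in 1:22) {
    left <- f1 >= f2                # maximum lies in [lo, x2]
    hi[left] <- x2[left]
    lo[!left] <- x1[!left]
    x2[left] <- x1[left];  f2[left] <- f1[left]
    x1[!left] <- x2[!left]; f1[!left] <- f2[!left]
    d <- gr * (hi - lo)
    newx <- hi - d
    newx[!left] <- (lo + d)[!left]
    fn <- f(newx)
    x1[left] <- newx[left];   f1[left] <- fn[left]
    x2[!left] <- newx[!left]; f2[!left] <- fn[!left]
  }
  mode <- (lo + hi) / 2
  h <- 1e-3 * sigma
  curv <- (f(mode + h) - 2 * f(mode) + f(mode - h)) / h^2
  s <- 1 / sqrt(pmax(-curv, 1e-8))
  list(mode = mode, s = pmin(s, 10 * sigma))
}

# Adaptive Gauss-Hermite quantities per case: the marginal clonal
# log-likelihood lM_j = log int P(Y_j | xi(u), C=1) phi(u; mu, sigma) du
# and the posterior moments m1, m2 of u given C_j = 1, with each case's
# nodes centred at its own integrand mode.
aghq_quantities <- function(comp, mu, sigma, grid_k) {
  gh <- gh_rule(grid_k)
  loc <- aghq_locate(comp, mu, sigma)
  U <- loc$mode + sqrt(2) * outer(loc$s, gh$x)
  c0 <- -log(sigma) - 0.5 * log(2 * base::pi)
  FF <- case_loglik_clonal_at_matrix(comp, U) -
    0.5 * ((U - mu) / sigma)^2 + c0
  V <- sweep(FF, 2L, log(gh$w) + gh$x^2, "+")
  mx <- row_max_guarded(V)
  A <- exp(V - mx)
  sA <- rowSums(A)
  lM <- log(sqrt(2) * loc$s) + mx + log(sA)
  m1 <- rowSums(A * U) / sA
  m2 <- rowSums(A * U^2) / sA
  list(lM = lM, m1 = m1, m2 = m2)
}

# Marginal clonal log-likelihood per case.
case_logM <- function(comp, mu, sigma, grid_k) {
  aghq_quantities(comp, mu, sigma, grid_k)$lM
}

# Mixture of the marginal clonal and independent components on the log
# scale; handles pi = 0 and pi = 1 without -Inf arithmetic.
mix_loglik <- function(lM, lI, pi) {
  if (pi <= 0) return(lI)
  if (pi >= 1) return(lM)
  m <- pmax(lM, lI)
  m + log(pi * exp(lM - m) + (1 - pi) * exp(lI - m))
}

#' Marginal log-likelihood of each case under the mixture model
#'
#' Computes, per case, \eqn{\log\{\pi M_j + (1-\pi) I_j\}} where
#' \eqn{M_j = \int_0^1 P(Y_j \mid \xi, C=1)\, g(\xi)\, d\xi} is
#' evaluated by adaptive Gauss-Hermite quadrature on the u scale (each
#' case's nodes centred at the mode of its integrand, with
#' curvature-based scaling, as in mixed-model marginal likelihoods) and
#' \eqn{I_j = P(Y_j \mid C=0)}.  All accumulation is in log space
#' (log-sum-exp), so cases with many loci and very small `p` do not
#' underflow.  At `pi = 0` the result equals
#' [case_loglik_independent()] exactly.
#'
#' @inheritParams fit_em
#' @param params Model parameters ([clonal_params()] or a named list).
#' @return A tibble with columns `case_id` and `loglik`; the dataset
#'   log-likelihood is `sum(loglik)`.
#' @export
case_marginal_loglik <- function(data, params, grid_k = 64,
                                 case_ids = NULL) {
  params <- as_clonal_params(params)
  comp <- compile_case_data(data, case_ids)
  lM <- case_logM(comp, params$mu, params$sigma, grid_k)
  tibble::tibble(case_id = comp$case_ids,
                 loglik = mix_loglik(lM, comp$lI, params$pi))
}

# Dataset-level observed-data log-likelihood on a compiled dataset.
obs_loglik <- function(comp, pi, mu, sigma, grid_k) {
  sum(mix_loglik(case_logM(comp, mu, sigma, grid_k), comp$lI, pi))
}
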