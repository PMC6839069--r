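# Shared fixtures and independent oracles for the test suite.

# Build a one-case table from vectors of shared and private p values.
make_case <- function(p_shared = numeric(0), p_private = numeric(0),
                      case_id = "c1") {
  n_s <- length(p_shared)
  n_p <- length(p_private)
  tibble::tibble(
    case_id = case_id,
    locus_id = paste0("x", seq_len(n_s + n_p)),
    gene_label = NA_character_,
    p = c(p_shared, p_private),
    in_tumor1 = 1L,
    in_tumor2 = rep(c(1L, 0L), c(n_s, n_p))
  )
}

# Random single-case table: counts and p values drawn from wide ranges,
# including very small p.
random_case <- function(case_id = "c1", max_loci = 12) {
  n <- sample.int(max_loci, 1)
  p <- exp(runif(n, log(1e-6), log(0.3)))
  shared <- runif(n) < 0.3
  make_case(p[shared], p[!shared], case_id = case_id)
}

# Direct (scalar, formula-level) clonal log-likelihood of one case at
# signal xi; intentionally naive -- no shared code with the package
# internals beyond base arithmetic.
naive_case_loglik <- function(p_shared, p_private, xi) {
  sh <- (xi + (1 - xi) * p_shared) / (xi + (1 - xi) * (2 - p_shared))
  pr <- (2 * (1 - xi) * (1 - p_private)) /
    (xi + (1 - xi) * (2 - p_private))
  sum(log(sh)) + sum(log(pr))
}

# Adaptive-integration oracle for the marginal clonal likelihood
# M = int P(Y | xi, C=1) g(xi) dxi, integrating over u = log(-log(1-xi))
# with stats::integrate (no fixed grid).  Returns M on the linear scale.
oracle_marginal_clonal <- function(p_shared, p_private, mu, sigma) {
  f <- Vectorize(function(u) {
    xi <- -expm1(-exp(u))
    exp(naive_case_loglik(p_shared, p_private, xi)) *
      stats::dnorm(u, mu, sigma)
  })
  stats::integrate(f, mu - 9 * sigma, mu + 9 * sigma,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

# Oracle mixture log-likelihood of one case.
oracle_case_marginal_loglik <- function(p_shared, p_private, pi, mu,
                                        sigma) {
  M <- oracle_marginal_clonal(p_shared, p_private, mu, sigma)
  I <- exp(naive_case_loglik(p_shared, p_private, 0))
  log(pi * M + (1 - pi) * I)
}

# Oracle posterior clonality weight for one case (Bayes with adaptive
# integration).
oracle_posterior_w <- function(p_shared, p_private, pi, mu, sigma) {
  M <- oracle_marginal_clonal(p_shared, p_private, mu, sigma)
  I <- exp(naive_case_loglik(p_shared, p_private, 0))
  pi * M / (pi * M + (1 - pi) * I)
}

# Brute-force maximizer of the expected complete-data log-likelihood
# surface given E-step quantities (w, m1, m2): the function the M-step
# maximizes in closed form.  Parameter-dependent part only.
oracle_m_step <- function(w, m1, m2, sigma_min = 0.05) {
  esurf <- function(par) {
    pi <- par[1]; mu <- par[2]; sigma <- par[3]
    lp <- if (pi <= 0) ifelse(w > 0, -Inf, 0) else w * log(pi)
    lq <- if (pi >= 1) ifelse(w < 1, -Inf, 0) else (1 - w) * log(1 - pi)
    lnorm <- w * (-log(sigma) - 0.5 * log(2 * base::pi) -
                    (m2 - 2 * mu * m1 + mu^2) / (2 * sigma^2))
    sum(lp + lq + lnorm)
  }
  o <- stats::optim(c(0.5, 0, 1), function(p) -esurf(p),
                    method = "L-BFGS-B",
                    lower = c(1e-9, -20, sigma_min),
                    upper = c(1 - 1e-9, 20, 20),
                    control = list(factr = 1e3))
  list(pi = o$par[1], mu = o$par[2], sigma = o$par[3])
}

# The packaged 49-case dataset, built once per test file load.
breast_tbl <- contralateral_breast_cases()
breast_sub_tbl <- dplyr::filter(breast_tbl, !case_id %in% c("36", "48"))

# Independently frozen per-case (left, right, matches) triples for the
# 49-case contralateral breast dataset; the fixture-integrity test
# compares the packaged dataset against this copy.
contralateral_breast_counts_ref <- tibble::tribble(
  ~case_id, ~left, ~right, ~matches,
  "1", 9, 7, 0,   "2", 3, 3, 0,   "3", 2, 7, 0,   "4", 8, 10, 0,
  "6", 6, 5, 0,   "8", 6, 2, 1,   "9", 2, 3, 0,   "12", 14, 3, 0,
  "13", 3, 3, 0,  "15", 8, 5, 0,  "16", 10, 8, 0, "17", 6, 8, 0,
  "18", 8, 2, 0,  "21", 4, 3, 0,  "23", 10, 4, 0, "24", 4, 3, 0,
  "25", 4, 6, 0,  "26", 6, 5, 0,  "27", 4, 5, 0,  "29", 3, 1, 0,
  "30", 6, 5, 0,  "31", 6, 5, 0,  "32", 5, 4, 0,  "33", 6, 4, 0,
  "35", 5, 4, 0,  "36", 3, 4, 3,  "38", 8, 2, 0,  "40", 10, 1, 0,
  "41", 0, 9, 0,  "43", 4, 4, 0,  "44", 9, 21, 0, "45", 3, 4, 0,
  "48", 2, 3, 2,  "52", 5, 7, 0,  "56", 2, 5, 0,  "58", 3, 4, 0,
  "59", 2, 3, 0,  "62", 4, 4, 0,  "63", 3, 9, 1,  "64", 5, 4, 0,
  "66", 3, 33, 0, "67", 4, 1, 1,  "70", 5, 2, 0,  "71", 3, 1, 0,
  "72", 1, 3, 0,  "74", 2, 1, 0,  "75", 4, 3, 1,  "76", 7, 5, 0,
  "77", 3, 1, 0
)
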