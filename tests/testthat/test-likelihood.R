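test_that("locus probabilities partition unity and reduce at xi = 0", {
  for (p in c(1e-6, 1e-3, 0.137, 0.5, 0.99)) {
    for (xi in c(0, 1e-6, 0.127, 0.5, 0.866, 1 - 1e-9)) {
      s <- locus_prob_clonal(xi, p, "shared")
      q <- locus_prob_clonal(xi, p, "private")
      expect_gte(s, 0); expect_lte(s, 1)
      expect_equal(s + q, 1, tolerance = 1e-12)
    }
    # xi = 0 identity with the independent model, machine precision
    expect_equal(locus_prob_clonal(0, p, "shared"),
                 locus_prob_independent(p, "shared"), tolerance = 1e-14)
    expect_equal(locus_prob_independent(p, "shared") +
                   locus_prob_independent(p, "private"), 1,
                 tolerance = 1e-14)
  }
})

test_that("locus probabilities match frozen arbitrary-precision values", {
  # values frozen from an exact rational evaluation of the formulas
  expect_equal(locus_prob_independent(0.137, "shared"),
               0.07353730542136339, tolerance = 1e-14)
  expect_equal(locus_prob_clonal(0, 0.137, "shared"),
               0.07353730542136339, tolerance = 1e-14)
  expect_equal(locus_prob_clonal(0.5, 0.001, "shared"),
               0.3337779259753251, tolerance = 1e-14)
})

test_that("limits and domain errors of the locus probabilities", {
  # xi -> 1: a clonal pair with full shared evolution matches everything
  expect_equal(locus_prob_clonal(1 - 1e-12, 0.3, "shared"), 1,
               tolerance = 1e-11)
  expect_equal(locus_prob_clonal(1 - 1e-12, 0.3, "private"), 0,
               tolerance = 1e-11)
  expect_error(locus_prob_clonal(1, 0.3, "shared"), "xi")
  expect_error(locus_prob_clonal(-0.1, 0.3, "shared"), "xi")
  expect_error(locus_prob_clonal(0.5, 0, "shared"), "p")
  expect_error(locus_prob_independent(1, "shared"), "p")
})

test_that("case log-likelihoods: empty product, xi = 0 identity, frozen value", {
  one <- make_case(p_shared = 0.137)
  expect_equal(case_loglik_clonal(one, 0)$loglik, log(0.07353730542136339),
               tolerance = 1e-12)
  expect_equal(case_loglik_independent(one)$loglik,
               case_loglik_clonal(one, 0)$loglik, tolerance = 1e-14)

  # 3-locus case frozen from exact rational arithmetic
  three <- make_case(p_shared = 0.001, p_private = c(0.01, 0.137))
  expect_equal(case_loglik_clonal(three, 0.3)$loglik,
               -2.215369995847018, tolerance = 1e-12)

  # empty case contributes exactly 0 to every likelihood
  some <- make_case(p_shared = 0.01, case_id = "a")
  ll <- case_loglik_clonal(some, 0.7, case_ids = c("a", "empty"))
  expect_equal(ll$loglik[ll$case_id == "empty"], 0)
  expect_equal(case_loglik_independent(some,
                                       case_ids = c("a", "empty"))$loglik,
               c(case_loglik_independent(some)$loglik, 0))
})

test_that("xi = 0 identity holds for random cases at machine precision", {
  set.seed(401)
  for (i in 1:25) {
    cs <- random_case()
    expect_lt(abs(case_loglik_clonal(cs, 0)$loglik -
                    case_loglik_independent(cs)$loglik), 1e-12)
  }
})

test_that("clonal log-likelihood is monotone in xi by locus status", {
  xis <- seq(0, 0.999, length.out = 60)
  shared_only <- make_case(p_shared = c(0.001, 0.05, 0.3))
  private_only <- make_case(p_private = c(0.001, 0.05, 0.3))
  ll_s <- vapply(xis, function(x) case_loglik_clonal(shared_only, x)$loglik, 0)
  ll_p <- vapply(xis, function(x) case_loglik_clonal(private_only, x)$loglik, 0)
  expect_true(all(diff(ll_s) >= -1e-12))
  expect_true(all(diff(ll_p) <= 1e-12))
})

test_that("rare matches carry more clonal evidence (likelihood ratio decreasing in p)", {
  ps <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 0.3, 0.6)
  for (xi in c(0.1, 0.5, 0.9)) {
    lr <- locus_prob_clonal(xi, ps, "shared") /
      locus_prob_independent(ps, "shared")
    expect_true(all(diff(lr) < 0))
  }
})

test_that("signal density is normal on the u scale; scenario medians check out", {
  expect_equal(signal_logdensity(0.7, 0.7, 1), log(1 / sqrt(2 * pi)),
               tolerance = 1e-14)
  u <- seq(-4, 4, length.out = 11)
  expect_equal(signal_logdensity(u, -1, 1.5), dnorm(u, -1, 1.5, log = TRUE))
  expect_error(signal_logdensity(0, 0, -1), "sigma")
  # median of xi = 1 - exp(-e^mu): the three scenarios span sparse to
  # saturated matching
  med <- function(mu) -expm1(-exp(mu))
  expect_equal(med(0.7), 0.8665132033419161, tolerance = 1e-12)
  expect_equal(med(-2), 0.1265769815068834, tolerance = 1e-12)
})

test_that("quadrature grid normalizes and matches adaptive integration", {
  g <- signal_grid(0.7, 0.3, k = 64)
  expect_equal(sum(g$weight), 1, tolerance = 1e-10)
  expect_equal(g$xi, -expm1(g$log1mxi), tolerance = 1e-12)
  # E[xi] under scenario 3 against stats::integrate on the u scale
  exi <- integrate(function(u) -expm1(-exp(u)) * dnorm(u, 0.7, 0.3),
                   -10, 10, rel.tol = 1e-12)$value
  expect_equal(sum(g$weight * g$xi), exi, tolerance = 1e-6)
  expect_error(signal_grid(0, 1, k = 1))
})

test_that("grid refinement (default K vs K=256) is stable on the breast fixture", {
  for (params in list(clonal_params(0.5, -1, 1),
                      clonal_params(0.059, 0, 0.51))) {
    ldef <- case_marginal_loglik(breast_tbl, params)$loglik
    l256 <- case_marginal_loglik(breast_tbl, params, grid_k = 256)$loglik
    expect_lt(max(abs(ldef - l256)), 1e-8)
  }
})

test_that("marginal log-likelihood collapses correctly at the pi extremes", {
  cs <- make_case(p_shared = c(0.001, 0.137), p_private = c(0.01, 0.2))
  lI <- case_loglik_independent(cs)$loglik
  expect_equal(case_marginal_loglik(cs, clonal_params(0, -1, 1))$loglik,
               lI, tolerance = 1e-14)
  # pi = 1 with the signal degenerate near xi ~ 0 approaches independence
  near0 <- clonal_params(1, -18, 0.05)
  expect_equal(case_marginal_loglik(cs, near0)$loglik, lI,
               tolerance = 1e-4)
})

test_that("quadrature marginal agrees with the adaptive-integration oracle", {
  set.seed(77)
  worst <- 0
  for (i in 1:100) {
    cs <- random_case()
    pi <- runif(1, 0.05, 0.95)
    mu <- runif(1, -3, 1.5)
    sigma <- runif(1, 0.1, 2)
    got <- case_marginal_loglik(cs, clonal_params(pi, mu, sigma))$loglik
    sh <- cs$p[cs$in_tumor2 == 1]
    pr <- cs$p[cs$in_tumor2 == 0]
    want <- oracle_case_marginal_loglik(sh, pr, pi, mu, sigma)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("log-space accumulation survives 100 tiny-p loci", {
  big <- make_case(p_shared = rep(1e-6, 30), p_private = rep(1e-6, 70))
  ll <- case_marginal_loglik(big, clonal_params(0.5, -1, 1))$loglik
  expect_true(is.finite(ll))
  # and a saturating signal with private loci goes to -Inf gracefully
  llp <- case_loglik_clonal(make_case(p_private = 0.5), 1 - 1e-16)
  expect_true(llp$loglik < -30)
})
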