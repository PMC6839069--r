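test_that("e_step: empty case has w = pi; pi extremes force constants", {
  cs <- make_case(p_shared = 0.001, case_id = "a")
  e <- e_step(cs, clonal_params(0.3, -1, 1), case_ids = c("a", "b"))
  expect_equal(e$w[e$case_id == "b"], 0.3, tolerance = 1e-10)
  # empty-case posterior signal moments are the prior moments
  expect_equal(e$m1[e$case_id == "b"], -1, tolerance = 1e-8)
  expect_equal(e$m2[e$case_id == "b"], 1 + 1, tolerance = 1e-6)
  expect_equal(e_step(cs, clonal_params(0, -1, 1))$w, 0)
  expect_equal(e_step(cs, clonal_params(1, -1, 1))$w, 1)
  expect_true(all(e$m2 >= e$m1^2))
})

test_that("e_step posterior weight matches an adaptive-integration Bayes oracle", {
  cs <- make_case(p_shared = 0.001)
  got <- e_step(cs, clonal_params(0.5, 0.7, 0.3))$w
  expect_equal(got, oracle_posterior_w(0.001, numeric(0), 0.5, 0.7, 0.3),
               tolerance = 1e-6)
  set.seed(88)
  for (i in 1:10) {
    rc <- random_case()
    pi <- runif(1, 0.1, 0.9); mu <- runif(1, -2, 1); s <- runif(1, 0.2, 1.5)
    got <- e_step(rc, clonal_params(pi, mu, s))$w
    want <- oracle_posterior_w(rc$p[rc$in_tumor2 == 1],
                               rc$p[rc$in_tumor2 == 0], pi, mu, s)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("m_step closed forms match hand results and the brute-force oracle", {
  # all weights 1, identical moments: point estimates, sigma at floor
  p1 <- tibble::tibble(w = c(1, 1), m1 = 0.7, m2 = 0.7^2 + 0.09)
  out <- m_step(p1)
  expect_equal(out$pi, 1)
  expect_equal(out$mu, 0.7)
  expect_equal(out$sigma, 0.3, tolerance = 1e-12)
  # weights select case 1
  p2 <- tibble::tibble(w = c(1, 0), m1 = c(0.7, -3), m2 = c(1.49, 9.5))
  out2 <- m_step(p2)
  expect_equal(out2$pi, 0.5)
  expect_equal(out2$mu, 0.7)
  # random posteriors against brute-force maximization of the expected
  # complete-data log-likelihood surface
  set.seed(99)
  for (i in 1:5) {
    n <- 20
    w <- runif(n)
    m1 <- rnorm(n, -1, 1)
    v <- runif(n, 0.1, 2)
    post <- tibble::tibble(w = w, m1 = m1, m2 = v + m1^2)
    got <- m_step(post)
    want <- oracle_m_step(w, m1, post$m2)
    expect_equal(got$pi, want$pi, tolerance = 1e-4)
    expect_equal(got$mu, want$mu, tolerance = 1e-4)
    expect_equal(got$sigma, want$sigma, tolerance = 1e-4)
  }
})

test_that("m_step degenerate all-zero-weight branch keeps current mu, sigma", {
  post <- tibble::tibble(w = c(0, 0), m1 = c(1, 2), m2 = c(2, 5))
  expect_message(out <- m_step(post, params = clonal_params(0.5, -1, 1)),
                 "degenerate|zero")
  expect_equal(out$pi, 0)
  expect_equal(out$mu, -1)
  expect_equal(out$sigma, 1)
  expect_error(m_step(post), "params")
})

test_that("EM log-likelihood trace is nondecreasing on varied datasets", {
  datasets <- list(
    breast_tbl,
    breast_sub_tbl,
    simulate_cases(40, 0.25, 1, seed = 11)$cases,
    simulate_cases(40, 0.75, 3, seed = 12)$cases
  )
  for (d in datasets) {
    fit <- fit_em(d, max_iter = 300)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  }
})

test_that("EM and one-step recover parameters from model-faithful data", {
  sim <- simulate_cases(500, 0.5, 3, seed = 21)
  os <- fit_onestep(sim$cases, case_ids = sim$truth$case_id)
  expect_true(os$converged)
  expect_lt(abs(os$params$pi - 0.5), 0.05)

  sim2 <- simulate_cases(500, 0.25, 2, seed = 22)
  em <- fit_em(sim2$cases, case_ids = sim2$truth$case_id)
  expect_true(em$converged)
  expect_lt(abs(em$params$pi - 0.25), 0.05)
  expect_lt(abs(em$params$mu - (-1)), 0.3)
})

test_that("estimators agree when the one-step maximum is interior", {
  sim <- simulate_cases(300, 0.5, 3, seed = 23)
  os <- fit_onestep(sim$cases)
  em <- fit_em(sim$cases)
  expect_false(os$boundary)
  expect_lt(abs(os$params$pi - em$params$pi), 0.02)
  expect_gte(em$loglik, os$loglik - 1e-4)
})

test_that("flat likelihood (all cases empty) returns init with a warning", {
  empty <- tibble::tibble(case_id = character(), locus_id = character(),
                          gene_label = character(), p = numeric(),
                          in_tumor1 = integer(), in_tumor2 = integer())
  expect_warning(
    fit <- fit_em(empty, init = clonal_params(0.3, -2, 0.7),
                  case_ids = c("a", "b", "c")),
    "flat")
  expect_true(fit$converged)
  expect_equal(fit$params$pi, 0.3)
  expect_equal(fit$params$mu, -2)
  expect_equal(nrow(fit$posteriors), 3)
  expect_equal(fit$posteriors$w, rep(0.3, 3), tolerance = 1e-10)
  expect_warning(os <- fit_onestep(empty, case_ids = "a"), "flat")
  expect_true(os$converged)
  expect_error(fit_em(empty), "no cases")
})

test_that("boundary estimates force all posteriors to the same constant", {
  # a dataset with zero matches anywhere: the likelihood is maximized
  # at pi = 0 and the one-step fit lands exactly on the boundary
  no_match <- purrr::map_dfr(1:12, function(j) {
    make_case(p_private = rep(0.001, 6), case_id = paste0("c", j))
  })
  os <- fit_onestep(no_match)
  expect_true(os$boundary)
  expect_equal(os$params$pi, 0, tolerance = 1e-8)
  expect_true(all(os$posteriors$w == 0))
  pc <- posterior_clonality(no_match, clonal_params(0, -1, 1))
  expect_true(all(pc$w == 0))
})

test_that("posterior_clonality reproduces the fit posteriors and empty-case rule", {
  fit <- fit_em(breast_tbl)
  pc <- posterior_clonality(breast_tbl, fit$params)
  expect_equal(pc$w, fit$posteriors$w, tolerance = 1e-10)
  cs <- make_case(p_shared = 0.001, case_id = "a")
  pc2 <- posterior_clonality(cs, clonal_params(0.2, -1, 1),
                             case_ids = c("a", "none"))
  expect_equal(pc2$w[pc2$case_id == "none"], 0.2, tolerance = 1e-10)
})

test_that("rare matches rank above hotspot matches in the fitted posteriors", {
  fit <- fit_em(breast_tbl, multistart = TRUE)
  w <- setNames(fit$posteriors$w, fit$posteriors$case_id)
  rare <- w[c("8", "36", "48")]
  common <- w[c("63", "67", "75")]
  expect_gt(min(rare), max(common))
})
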