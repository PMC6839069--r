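#' Mutation-profile model for simulated cases
#'
#' Describes how many informative loci a simulated case carries and how
#' their occurrence probabilities are drawn.  The default mimics a
#' breast-panel mix of rare and hotspot mutations: the locus count is
#' `1 + Poisson(mean_extra_loci)`, and each locus is rare with
#' probability `rare_frac` — its `p` then log-uniform on `rare_range` —
#' or a common hotspot otherwise, with `p` uniform on `common_range`
#' (bracketing the PIK3CA H1047R frequency of about 0.14).
#'
#' @param mean_extra_loci Poisson mean for loci beyond the first
#'   (default 6, matching observed per-case totals of roughly 1-16).
#' @param rare_frac Probability a locus is rare (default 0.9).
#' @param rare_range Range of rare `p`, sampled log-uniformly
#'   (default `c(1e-4, 1e-2)`).
#' @param common_range Range of common `p`, sampled uniformly
#'   (default `c(0.05, 0.15)`).
#' @return A list of class `loci_model`.
#' @export
loci_model <- function(mean_extra_loci = 6, rare_frac = 0.9,
                       rare_range = c(1e-4, 1e-2),
                       common_range = c(0.05, 0.15)) {
  stopifnot(mean_extra_loci >= 0, rare_frac >= 0, rare_frac <= 1,
            length(rare_range) == 2L, all(rare_range > 0),
            all(rare_range < 1), length(common_range) == 2L,
            all(common_range > 0), all(common_range < 1))
  structure(list(mean_extra_loci = mean_extra_loci,
                 rare_frac = rare_frac, rare_range = rare_range,
                 common_range = common_range),
            class = "loci_model")
}

sample_loci_p <- function(model, n_loci) {
  rare <- runif(n_loci) < model$rare_frac
  p <- numeric(n_loci)
  lr <- log(model$rare_range)
  p[rare] <- exp(runif(sum(rare), lr[1], lr[2]))
  p[!rare] <- runif(sum(!rare), model$common_range[1],
                    model$common_range[2])
  p
}

#' Simulate tumor-pair mutation data from the clonality model
#'
#' Draws cases from exactly the generative model the likelihood
#' assumes: each case is clonal with probability `pi_true`; a clonal
#' case draws its transformed signal \eqn{u \sim N(\mu, \sigma)} and
#' sets \eqn{\xi = 1 - e^{-e^u}}, while an independent case has
#' \eqn{\xi = 0}.  The case's loci (count and occurrence probabilities
#' from `loci`) are then shared with the clonal-model probability
#' \eqn{\{\xi + (1-\xi)p\}/\{\xi + (1-\xi)(2-p)\}} (which reduces to
#' the independent-model \eqn{p/(2-p)} when \eqn{\xi = 0}), private
#' otherwise; a private mutation is assigned to one of the two tumors
#' at random.
#'
#' @param n_cases Number of cases to simulate.
#' @param pi_true True proportion of clonal cases, in `[0, 1]`.
#' @param scenario Signal distribution: 1, 2, 3 (see
#'   [scenario_params()]), or a list with elements `mu` and `sigma`.
#' @param loci A [loci_model()] describing the mutation profiles.
#' @param seed Integer seed; mandatory, so every dataset is
#'   reproducible with no implicit global state.
#' @return A list with two tibbles: `cases`, a per-locus case table
#'   (see [as_case_table()]), and `truth`, one row per case with the
#'   latent `clonal` indicator and signal `xi`.
#' @examples
#' sim <- simulate_cases(10, pi_true = 0.25, scenario = 2, seed = 42)
#' sim$truth
#' @export
simulate_cases <- function(n_cases, pi_true, scenario,
                           loci = loci_model(), seed) {
  stopifnot(n_cases >= 1, pi_true >= 0, pi_true <= 1,
            inherits(loci, "loci_model"))
  if (missing(seed)) stop("`seed` is required")
  if (is.numeric(scenario) && length(scenario) == 1L) {
    scenario <- scenario_params(scenario)
  }
  stopifnot(is.list(scenario), all(c("mu", "sigma") %in% names(scenario)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  clonal <- rbinom(n_cases, 1L, pi_true) == 1L
  u <- rnorm(n_cases, scenario$mu, scenario$sigma)
  xi <- ifelse(clonal, -expm1(-exp(u)), 0)
  n_loci <- 1L + rpois(n_cases, loci$mean_extra_loci)
  per_case <- lapply(seq_len(n_cases), function(j) {
    p <- sample_loci_p(loci, n_loci[j])
    pr_shared <- locus_prob_clonal(xi[j], p, "shared")
    shared <- runif(n_loci[j]) < pr_shared
    side1 <- runif(n_loci[j]) < 0.5   # which tumor a private locus hits
    tibble::tibble(
      case_id = sprintf("case%03d", j),
      locus_id = sprintf("L%d", seq_len(n_loci[j])),
      gene_label = NA_character_,
      p = p,
      in_tumor1 = as.integer(shared | side1),
      in_tumor2 = as.integer(shared | !side1)
    )
  })
  list(cases = dplyr::bind_rows(per_case),
       truth = tibble::tibble(case_id = sprintf("case%03d",
                                                seq_len(n_cases)),
                              clonal = clonal, xi = xi))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run an estimator-comparison simulation study
#'
#' For every cell of a design grid (sample size, true clonal
#' proportion, signal scenario) simulates `replicates` datasets and
#' fits each with the requested estimators, then summarizes the
#' estimates of the clonal proportion: mean, standard deviation,
#' range, and the counts of estimates exactly on the boundary
#' (within `1e-8` of 0 or 1).  When both estimators run, an
#' `em_subset` summary is added per cell: the EM estimates restricted
#' to the datasets where the one-step maximizer returned a boundary
#' value, the setting where the two estimators differ most.
#'
#' Per-replicate fits use the default single start; a fit that errors
#' is recorded and excluded from the summaries, never aborting the
#' study.  Replicate seeds are derived deterministically from `seed`
#' and the cell index, so each cell is reproducible independently of
#' execution order.
#'
#' @param cells A data frame with columns `n_cases`, `pi_true`,
#'   `scenario` (1, 2 or 3), one row per design cell.
#' @param replicates Datasets per cell (default 200).
#' @param methods Estimators to run: subset of `c("onestep", "em")`.
#' @param seed Base integer seed (required).
#' @param loci A [loci_model()].
#' @param grid_k,tol,max_iter,sigma_min Passed to the fitters.
#' @return An object of class `clonal_study`: a list with `estimates`
#'   (one row per replicate and method: `pi_hat`, `mu_hat`,
#'   `sigma_hat`, `loglik`, `converged`, `boundary`, `error`) and
#'   `summary` (one row per cell and method, including `em_subset`
#'   rows, with columns `mean`, `sd`, `min`, `max`, `n_zero`, `n_one`,
#'   `n_fit`, `n_failed`).
#' @examples
#' st <- run_study(data.frame(n_cases = 20, pi_true = 0.5, scenario = 3),
#'                 replicates = 3, seed = 7)
#' st$summary
#' @export
run_study <- function(cells, replicates = 200,
                      methods = c("onestep", "em"), seed,
                      loci = loci_model(), grid_k = 64, tol = 1e-6,
                      max_iter = 1000, sigma_min = 0.05) {
  stopifnot(is.data.frame(cells),
            all(c("n_cases", "pi_true", "scenario") %in% names(cells)),
            replicates >= 1)
  if (missing(seed)) stop("`seed` is required")
  methods <- match.arg(methods, c("onestep", "em"), several.ok = TRUE)
  cells <- tibble::as_tibble(cells)

  one_rep <- function(cell_i, rep_i) {
    cell <- cells[cell_i, ]
    rep_seed <- as.integer(seed) + (cell_i - 1L) * 1000000L + rep_i
    sim <- simulate_cases(cell$n_cases, cell$pi_true, cell$scenario,
                          loci = loci, seed = rep_seed)
    purrr::map_dfr(methods, function(m) {
      fit <- tryCatch({
        if (m == "em") {
          fit_em(sim$cases, grid_k = grid_k, tol = tol,
                 max_iter = max_iter, sigma_min = sigma_min,
                 case_ids = sim$truth$case_id)
        } else {
          fit_onestep(sim$cases, grid_k = grid_k,
                      sigma_bounds = c(sigma_min, 10),
                      case_ids = sim$truth$case_id)
        }
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        tibble::tibble(cell = cell_i, replicate = rep_i, method = m,
                       pi_hat = NA_real_, mu_hat = NA_real_,
                       sigma_hat = NA_real_, loglik = NA_real_,
                       converged = NA, boundary = NA,
                       error = conditionMessage(fit))
      } else {
        tibble::tibble(cell = cell_i, replicate = rep_i, method = m,
                       pi_hat = fit$params$pi, mu_hat = fit$params$mu,
                       sigma_hat = fit$params$sigma,
                       loglik = fit$loglik, converged = fit$converged,
                       boundary = fit$boundary, error = NA_character_)
      }
    })
  }

  grid <- tidyr::expand_grid(cell = seq_len(nrow(cells)),
                             replicate = seq_len(replicates))
  estimates <- purrr::map2_dfr(grid$cell, grid$replicate, one_rep)
  estimates <- dplyr::left_join(
    dplyr::mutate(cells, cell = dplyr::row_number()), estimates,
    by = "cell")
  structure(list(estimates = estimates,
                 summary = summarize_study(estimates)),
            class = "clonal_study")
}

#' Summarize per-replicate study estimates
#'
#' @param estimates The `estimates` tibble of a [run_study()] result.
#' @return One row per (cell, method) with `mean`, `sd`, `min`, `max`
#'   of the estimated clonal proportion, boundary counts `n_zero` /
#'   `n_one` (within `1e-8` of 0 / 1), `n_fit` and `n_failed`; plus
#'   `em_subset` rows (EM estimates on the datasets where the one-step
#'   estimate was on the boundary) when both methods are present.
#'   With a single replicate `sd` is `NA` and the range collapses to a
#'   point.
#' @export
summarize_study <- function(estimates) {
  summ_one <- function(d, label) {
    ok <- d[!is.na(d$pi_hat), ]
    tibble::tibble(
      method = label,
      n_fit = nrow(ok),
      n_failed = sum(is.na(d$pi_hat)),
      mean = if (nrow(ok)) mean(ok$pi_hat) else NA_real_,
      sd = if (nrow(ok) > 1L) sd(ok$pi_hat) else NA_real_,
      min = if (nrow(ok)) min(ok$pi_hat) else NA_real_,
      max = if (nrow(ok)) max(ok$pi_hat) else NA_real_,
      n_zero = sum(ok$pi_hat <= .boundary_tol),
      n_one = sum(ok$pi_hat >= 1 - .boundary_tol)
    )
  }
  cells <- dplyr::distinct(estimates, .data$cell, .data$n_cases,
                           .data$pi_true, .data$scenario)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    ci <- cells$cell[i]
    d <- estimates[estimates$cell == ci, ]
    out <- purrr::map_dfr(unique(d$method),
                          function(m) summ_one(d[d$method == m, ], m))
    if (all(c("onestep", "em") %in% d$method)) {
      os <- d[d$method == "onestep", c("replicate", "pi_hat")]
      bad <- os$replicate[!is.na(os$pi_hat) &
                            (os$pi_hat <= .boundary_tol |
                               os$pi_hat >= 1 - .boundary_tol)]
      sub <- d[d$method == "em" & d$replicate %in% bad, ]
      out <- dplyr::bind_rows(out, summ_one(sub, "em_subset"))
    }
    dplyr::bind_cols(cells[i, ], out)
  })
}

#' @export
print.clonal_study <- function(x, ...) {
  cat(sprintf("<clonal_study> %d cell(s), %d fitted estimate(s)\n",
              length(unique(x$estimates$cell)),
              sum(!is.na(x$estimates$pi_hat))))
  print(x$summary)
  invisible(x)
}
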