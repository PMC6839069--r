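#' Tidy a fitted clonality model
#'
#' @param x A `clonal_fit` from [fit_em()] or [fit_onestep()].
#' @param ... Unused.
#' @return One row per model parameter with columns `term` and
#'   `estimate`.
#' @method tidy clonal_fit
#' @export
tidy.clonal_fit <- function(x, ...) {
  tibble::tibble(term = c("pi", "mu", "sigma"),
                 estimate = c(x$params$pi, x$params$mu, x$params$sigma))
}

#' One-row summary of a fitted clonality model
#'
#' @inheritParams tidy.clonal_fit
#' @return A one-row tibble: `method`, `pi`, `mu`, `sigma`, `loglik`,
#'   `n_iter`, `converged`, `boundary`, `n_cases`.
#' @method glance clonal_fit
#' @export
glance.clonal_fit <- function(x, ...) {
  tibble::tibble(method = x$method, pi = x$params$pi, mu = x$params$mu,
                 sigma = x$params$sigma, loglik = x$loglik,
                 n_iter = x$n_iter, converged = x$converged,
                 boundary = x$boundary, n_cases = x$n_cases)
}

#' Per-case posterior clonality probabilities of a fit
#'
#' @inheritParams tidy.clonal_fit
#' @param data Optional case table to re-derive per-case shared and
#'   private counts for the output.
#' @return One row per case: `case_id`, `w` (posterior probability of
#'   clonality at the fitted parameters), and, when `data` is given,
#'   `n_shared` and `n_private`.
#' @method augment clonal_fit
#' @export
augment.clonal_fit <- function(x, data = NULL, ...) {
  out <- x$posteriors
  if (!is.null(data)) {
    data <- as_case_table(data)
    counts <- dplyr::summarise(
      dplyr::group_by(data, case_id = as.character(.data$case_id)),
      n_shared = sum(.data$in_tumor1 == 1 & .data$in_tumor2 == 1),
      n_private = sum(.data$in_tumor1 != .data$in_tumor2),
      .groups = "drop")
    out <- dplyr::left_join(
      dplyr::mutate(out, case_id = as.character(.data$case_id)),
      counts, by = "case_id")
    out <- dplyr::mutate(out,
                         n_shared = dplyr::coalesce(.data$n_shared, 0L),
                         n_private = dplyr::coalesce(.data$n_private, 0L))
  }
  out
}

#' Plot per-case posterior clonality probabilities
#'
#' @param object A `clonal_fit`.
#' @param ... Unused.
#' @return A ggplot: one bar per case, posterior probability of
#'   clonality on the y axis, with the fitted population proportion as
#'   a dashed reference line.
#' @method autoplot clonal_fit
#' @export
autoplot.clonal_fit <- function(object, ...) {
  d <- dplyr::mutate(object$posteriors,
                     case_id = factor(.data$case_id,
                                      levels = unique(.data$case_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$case_id, y = .data$w)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = object$params$pi,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "posterior P(clonal)",
                  title = sprintf("%s fit: pi = %.3f", object$method,
                                  object$params$pi)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot estimates of the clonal proportion across a simulation study
#'
#' @param object A `clonal_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot: boxplots of the estimated proportion by method,
#'   faceted by design cell, with the true value as a dashed line.
#' @method autoplot clonal_study
#' @export
autoplot.clonal_study <- function(object, ...) {
  d <- dplyr::filter(object$estimates, !is.na(.data$pi_hat))
  d <- dplyr::mutate(
    d, cell_label = sprintf("n=%d, pi=%.2f, sc%d", .data$n_cases,
                            .data$pi_true, .data$scenario))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$pi_hat)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$pi_true),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~cell_label) +
    ggplot2::labs(x = NULL, y = "estimated clonal proportion") +
    ggplot2::theme_minimal()
}

#' Density of the clonality signal under the three study scenarios
#'
#' @param scenarios Integer vector of scenario labels (default 1:3).
#' @return A ggplot of the signal density on the \eqn{\xi} scale for
#'   each scenario: scenario 1 concentrates near 0 (few matches in
#'   clonal cases), scenario 3 near 0.87 (most mutations matched).
#' @export
plot_signal_scenarios <- function(scenarios = 1:3) {
  xi <- seq(1e-4, 1 - 1e-4, length.out = 400)
  d <- purrr::map_dfr(scenarios, function(s) {
    sc <- scenario_params(s)
    u <- log(-log1p(-xi))
    # density of xi by change of variables from u ~ N(mu, sigma)
    dens <- exp(signal_logdensity(u, sc$mu, sc$sigma)) /
      (-log1p(-xi) * (1 - xi))
    tibble::tibble(scenario = sprintf("scenario %d (mu=%g, sigma=%g)",
                                      s, sc$mu, sc$sigma),
                   xi = xi, density = dens)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xi, y = .data$density,
                                  colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(xi), y = "density", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
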