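#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted quantal-parameter object
#'
#' @param x A `qc_fit` from [solve_moments()], [fit_transient_ls()],
#'   [eq_method()] or [fit_time_varying_refill()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (plus interval
#'   columns when the fit carries them).
#' @method tidy qc_fit
#' @export
tidy.qc_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a fitted quantal-parameter object
#'
#' @inheritParams tidy.qc_fit
#' @return A one-row tibble with the method tag, number of roots (for
#'   moment inversion), residual norm / log-likelihood and convergence.
#' @method glance qc_fit
#' @export
glance.qc_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    method = x$method,
    n_roots = if (is.null(x$roots)) NA_integer_ else nrow(x$roots),
    residual_norm = d$residual_norm %||% NA_real_,
    logLik = d$logLik %||% NA_real_,
    converged = d$converged %||% TRUE)
}

#' Tidy empirical fluctuation statistics
#'
#' @param x A `qc_stats` from [empirical_stats()].
#' @param ... Unused.
#' @return A tibble with `statistic`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy qc_stats
#' @export
tidy.qc_stats <- function(x, ...) {
  x$ci
}

#' One-row summary of empirical fluctuation statistics
#'
#' @inheritParams tidy.qc_stats
#' @return A one-row tibble with the window size, burn-in and bootstrap
#'   settings alongside the point estimates.
#' @method glance qc_stats
#' @export
glance.qc_stats <- function(x, ...) {
  tibble::tibble(mean_qc = x$mean_qc, ff = x$ff, rho = x$rho,
                 n_used = x$n_used, burn_in = x$burn_in,
                 n_boot = x$n_boot, seed = x$seed)
}
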