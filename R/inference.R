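#' Empirical steady-state fluctuation statistics of a QC trace
#'
#' Computes the steady-state mean quantal content, Fano factor
#' (variance/mean) and lag-1 Pearson autocorrelation from the stimuli
#' `burn_in..n` of a trace, with 95% bootstrap confidence intervals.
#' The Fano factor is bootstrapped by resampling single QC values; the
#' correlation by resampling consecutive `(qc_i, qc_{i+1})` pairs, which
#' preserves the lag-1 structure being estimated.
#'
#' @param trace A `qc_trace` tibble (or any data frame with a `qc` column),
#'   or a bare numeric vector of QCs.
#' @param burn_in First stimulus index included in the steady-state window
#'   (default 10, discarding the initial depression transient of a
#'   high-frequency train).
#' @param n_boot Bootstrap replicates for the confidence intervals.
#' @param seed Integer seed for the bootstrap resampling.
#' @param lags Integer lags at which to report the autocorrelation
#'   (point estimates; CIs are computed for lag 1).
#' @return A `qc_stats` object; use [generics::tidy()] for a tibble of
#'   estimates and intervals.
#' @export
empirical_stats <- function(trace, burn_in = 10, n_boot = 1000, seed = 1,
                            lags = 1) {
  qc <- if (is.numeric(trace)) trace else trace$qc
  n <- length(qc)
  if (n <= burn_in + 1)
    stop("trace must be longer than burn_in + 1", call. = FALSE)
  if (burn_in < 1) stop("`burn_in` must be >= 1", call. = FALSE)
  x <- qc[burn_in:n]
  m <- mean(x)
  if (m == 0) stop("mean QC over the window is zero; Fano factor undefined",
                   call. = FALSE)
  if (stats::var(x) == 0)
    stop("constant QC trace; correlation undefined", call. = FALSE)
  ff <- stats::var(x) / m
  rho_ell <- vapply(lags, function(l) {
    stats::cor(x[seq_len(length(x) - l)], x[-seq_len(l)])
  }, numeric(1))

  set.seed(as.integer(seed))
  nx <- length(x)
  boot_ff <- boot_rho <- boot_mean <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xs <- x[sample.int(nx, nx, replace = TRUE)]
    boot_mean[b] <- mean(xs)
    boot_ff[b] <- stats::var(xs) / mean(xs)
    idx <- sample.int(nx - 1L, nx - 1L, replace = TRUE)
    boot_rho[b] <- stats::cor(x[idx], x[idx + 1L])
  }
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  structure(
    list(mean_qc = m, ff = ff, rho = rho_ell[match(1, lags)],
         lags = lags, rho_ell = rho_ell,
         ci = tibble::tibble(
           statistic = c("mean_qc", "ff", "rho"),
           estimate  = c(m, ff, rho_ell[match(1, lags)]),
           conf.low  = c(ci(boot_mean)[1], ci(boot_ff)[1], ci(boot_rho)[1]),
           conf.high = c(ci(boot_mean)[2], ci(boot_ff)[2], ci(boot_rho)[2])),
         burn_in = burn_in, n_boot = n_boot, seed = seed,
         n_used = nx),
    class = "qc_stats")
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf("<qc_stats> window of %d stimuli (burn-in %d), %d bootstrap reps\n",
              x$n_used, x$burn_in, x$n_boot))
  print(x$ci)
  invisible(x)
}

new_qc_fit <- function(method, estimates, roots = NULL, diagnostics = list()) {
  structure(list(method = method, estimates = estimates, roots = roots,
                 diagnostics = diagnostics),
            class = "qc_fit")
}

#' @export
print.qc_fit <- function(x, ...) {
  cat("<qc_fit> method:", x$method, "\n")
  print(x$estimates)
  if (!is.null(x$roots) && nrow(x$roots) > 1) {
    cat("all roots:\n"); print(x$roots)
  }
  invisible(x)
}

#' Infer release and refilling probabilities from (FF, rho)
#'
#' Jointly solves the steady-state Fano-factor and lag-1 correlation
#' equations for `(pr, pd)` at a fixed undocking probability.  For
#' `pu = 0` the system reduces analytically: with `s = pr + pd` and
#' `q = pr pd`, the Fano-factor equation gives `s(1-FF) = q(2-FF)` and
#' substituting into the correlation equation yields
#' `q = (1 - FF) + rho FF`, so `pr` and `pd` are the two roots of
#' `z^2 - s z + q = 0` — a swap-symmetric pair.  For `pu > 0` a
#' deterministic multi-start Newton search is used.  When an observed
#' normalized depression is supplied, the root whose model-predicted
#' depression is closest is flagged `selected` (this is how the
#' physiologically relevant member of a symmetric pair is identified).
#'
#' @param ff_obs Observed steady-state Fano factor, in (0, 1).
#' @param rho_obs Observed lag-1 correlation, <= 0.
#' @param pu_fixed Undocking probability held fixed (default 0).
#' @param depression_obs Optional observed normalized synaptic depression
#'   used to disambiguate symmetric roots.
#' @return A `qc_fit` with `roots` (tibble of all solutions with their
#'   implied Fano factor, correlation and depression) and `estimates` (the
#'   selected root).
#' @examples
#' solve_moments(ff_obs = 0.5, rho_obs = -0.035, depression_obs = 0.55)
#' @export
solve_moments <- function(ff_obs, rho_obs, pu_fixed = 0,
                          depression_obs = NULL) {
  if (ff_obs <= 0 || ff_obs >= 1)
    stop("`ff_obs` must lie in (0, 1)", call. = FALSE)
  if (rho_obs > 0)
    stop("`rho_obs` must be <= 0 (the model predicts non-positive lag-1 correlation)",
         call. = FALSE)
  check_prob(pu_fixed, "pu_fixed")
  if (pu_fixed == 0 && rho_obs < -0.125)
    stop("rho below the global minimum of -0.125 attainable with pu = 0; infeasible",
         call. = FALSE)

  if (pu_fixed == 0) {
    q <- (1 - ff_obs) + rho_obs * ff_obs
    s <- q * (2 - ff_obs) / (1 - ff_obs)
    disc <- s^2 - 4 * q
    if (disc < 0 || q <= 0)
      stop("no real root: the supplied (FF, rho) pair is infeasible for pu = 0",
           call. = FALSE)
    z <- sort((s + c(-1, 1) * sqrt(disc)) / 2)
    cand <- unique(rbind(c(z[2], z[1]), c(z[1], z[2])))
    roots <- cand[cand[, 1] > 0 & cand[, 1] < 1 &
                  cand[, 2] > 0 & cand[, 2] < 1, , drop = FALSE]
  } else {
    fun <- function(x) {
      c(steady_state_fano(x[1], x[2], pu_fixed) - ff_obs,
        steady_state_corr(x[1], x[2], pu_fixed) - rho_obs)
    }
    starts <- as.matrix(expand.grid(pr = seq(0.05, 0.95, by = 0.1),
                                    pd = seq(0.05, 0.95, by = 0.1)))
    sols <- list()
    for (k in seq_len(nrow(starts))) {
      sol <- tryCatch(
        suppressWarnings(pracma::fsolve(fun, starts[k, ], tol = 1e-12)),
        error = function(e) NULL)
      if (is.null(sol)) next
      x <- sol$x
      if (any(x <= 0) || any(x >= 1)) next
      if (max(abs(fun(x))) > 1e-8) next
      sols[[length(sols) + 1L]] <- x
    }
    if (length(sols) == 0)
      stop("no root in the open unit square: the supplied statistics are infeasible",
           call. = FALSE)
    roots <- do.call(rbind, sols)
    # merge duplicates
    keep <- rep(TRUE, nrow(roots))
    for (a in seq_len(nrow(roots))) {
      if (!keep[a]) next
      for (b in seq_len(nrow(roots))) {
        if (b <= a || !keep[b]) next
        if (max(abs(roots[a, ] - roots[b, ])) < 1e-6) keep[b] <- FALSE
      }
    }
    roots <- roots[keep, , drop = FALSE]
  }
  if (nrow(roots) == 0)
    stop("no root in the open unit square: the supplied statistics are infeasible",
         call. = FALSE)

  tab <- tibble::tibble(
    pr = roots[, 1], pd = roots[, 2], pu = pu_fixed,
    ff = steady_state_fano(roots[, 1], roots[, 2], pu_fixed),
    rho = steady_state_corr(roots[, 1], roots[, 2], pu_fixed),
    depression = steady_state_occupancy(roots[, 1], roots[, 2], pu_fixed)) |>
    dplyr::arrange(dplyr::desc(.data$pr))
  if (!is.null(depression_obs)) {
    tab$selected <- seq_len(nrow(tab)) ==
      which.min(abs(tab$depression - depression_obs))
  } else {
    # default to the high-pr root, the convention used when no depression
    # measurement is available
    tab$selected <- seq_len(nrow(tab)) == 1L
  }
  sel <- tab[tab$selected, ]
  est <- tibble::tibble(term = c("pr", "pd"),
                        estimate = c(sel$pr, sel$pd))
  new_qc_fit("moments", est, roots = tab,
             diagnostics = list(ff_obs = ff_obs, rho_obs = rho_obs,
                                pu_fixed = pu_fixed,
                                depression_obs = depression_obs))
}

#' Least-squares fit of constant (pr, pd) to a normalized depression curve
#'
#' Fits the closed-form normalized mean-QC time course
#' \deqn{\frac{\langle b_i\rangle}{\langle b_1\rangle} =
#'   \frac{p_d + p_r (1-p_r)^{i-1} (1-p_d)^i}{p_d + p_r (1 - p_d)}}
#' (constant probabilities, `pu = 0`, `p1 = 1`) to a mean QC trace
#' normalized to its first stimulus, by deterministic multi-start
#' least squares over `(pr, pd)` in the open unit square.
#'
#' @param mean_trace Numeric vector of normalized mean QCs (element 1 must
#'   equal 1).
#' @return A `qc_fit` with the `(pr, pd)` estimate and residual norm.
#' @export
fit_transient_ls <- function(mean_trace) {
  y <- as.numeric(mean_trace)
  if (abs(y[1] - 1) > 1e-9)
    stop("`mean_trace` must be normalized to its first stimulus (element 1 == 1)",
         call. = FALSE)
  i <- seq_along(y)
  obj <- function(x) {
    m <- occupancy_closed_form(1, x[1], x[2], 0, i)
    sum((m - y)^2)
  }
  best <- multi_start_optim(obj, n_par = 2)
  est <- tibble::tibble(term = c("pr", "pd"), estimate = best$par)
  new_qc_fit("ls_transient", est,
             diagnostics = list(residual_norm = sqrt(best$value),
                                convergence = best$convergence))
}

# Deterministic multi-start box-constrained minimisation over [eps,1-eps]^n.
multi_start_optim <- function(obj, n_par, starts = NULL, eps = 1e-6) {
  if (is.null(starts)) {
    g <- seq(0.1, 0.9, by = 0.2)
    starts <- as.matrix(do.call(expand.grid, rep(list(g), n_par)))
  }
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[k, ], obj, method = "L-BFGS-B",
                   lower = rep(eps, n_par), upper = rep(1 - eps, n_par),
                   control = list(factr = 1e1, maxit = 500,
                                  ndeps = rep(1e-7, n_par))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)
  best
}

#' Elmqvist-Quastel pool and release-probability estimator
#'
#' The classical estimator that assumes no vesicle replenishment during the
#' first stimuli of a high-frequency train: regress `QC_i` on the
#' cumulative QC released before stimulus `i` (for `i = 1..k`), extrapolate
#' the line to its x-intercept to estimate the releasable pool, and take
#' `pr = QC_1 / pool`.  When replenishment is in fact present the method
#' underestimates the release probability.
#'
#' @param qc_head Numeric vector of QCs from the start of the train
#'   (at least `k` values).
#' @param k Number of initial stimuli used (default 3).
#' @return A `qc_fit` with terms `pool` and `pr`.
#' @export
eq_method <- function(qc_head, k = 3) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  y <- as.numeric(qc_head)[seq_len(k)]
  if (anyNA(y)) stop("`qc_head` must supply at least k QC values", call. = FALSE)
  x <- cumsum(c(0, y))[seq_len(k)]
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  if (!is.finite(slope) || slope >= -1e-8)
    stop("EQ method inapplicable: QC does not decrease with cumulative release",
         call. = FALSE)
  pool <- -stats::coef(fit)[["(Intercept)"]] / slope
  est <- tibble::tibble(term = c("pool", "pr"),
                        estimate = c(pool, y[1] / pool))
  new_qc_fit("eq", est, diagnostics = list(slope = slope, k = k))
}

#' Fit a time-varying refilling-probability schedule
#'
#' Estimates per-stimulus refilling probabilities `pd_1..pd_n` for the
#' first `n_transient` stimuli plus a constant tail `pd`, holding the
#' release probability fixed (`pu = 0`, `p1 = 1`).  Two modes:
#'
#' * `"ls"` — least squares between the model-predicted normalized mean QC
#'   (which equals the occupancy `p_i` under these assumptions) and a
#'   normalized mean-QC trace.
#' * `"mle"` — maximum likelihood on an evoked-amplitude trace, using the
#'   compound binomial-Gaussian marginal: the amplitude at stimulus `i` has
#'   density \eqn{\sum_b \mathrm{Bin}(b; M, p_i p_r)\,
#'   \mathcal N(a; b\langle c\rangle, b (CV_q \langle c\rangle)^2)}, which
#'   accounts explicitly for quantal-size fluctuations.
#'
#' @param data For `"ls"`, a numeric vector of normalized mean QCs; for
#'   `"mle"`, a `qc_trace` with an `amplitude` column (or a numeric vector
#'   of amplitudes).
#' @param pr_fixed Fixed release probability.
#' @param n_transient Number of leading stimuli with free refilling
#'   probabilities (default 5).
#' @param mode `"ls"` or `"mle"`.
#' @param M Docking-site count (required for `"mle"`; if `NULL`, estimated
#'   as `round(mean steady QC / (pbar * pr))` from the amplitude trace).
#' @param c_mean,cv_q Quantal-size model for `"mle"`.
#' @return A `qc_fit` with terms `pd_1..pd_n` and `pd_tail`; optimizer
#'   convergence is reported in `diagnostics` (non-convergence is flagged,
#'   not silent).
#' @export
fit_time_varying_refill <- function(data, pr_fixed, n_transient = 5,
                                    mode = c("ls", "mle"),
                                    M = NULL, c_mean = NULL, cv_q = NULL) {
  mode <- match.arg(mode)
  check_prob(pr_fixed, "pr_fixed")
  npar <- n_transient + 1L
  terms <- c(paste0("pd_", seq_len(n_transient)), "pd_tail")

  occupancy_for <- function(x, n) {
    pdv <- c(x[seq_len(min(n_transient, n))],
             rep(x[npar], max(0L, n - n_transient)))
    occupancy_p_raw(1, rep(pr_fixed, n), pdv, rep(0, n), n)
  }

  if (mode == "ls") {
    y <- as.numeric(data)
    if (abs(y[1] - 1) > 1e-6)
      stop("LS mode expects a mean trace normalized to its first stimulus",
           call. = FALSE)
    n <- length(y)
    obj <- function(x) sum((occupancy_for(x, n) - y)^2)
    starts <- matrix(rep(c(0.3, 0.5, 0.7), each = npar), ncol = npar,
                     byrow = TRUE)
    best <- multi_start_optim(obj, npar, starts = starts)
    est <- tibble::tibble(term = terms, estimate = unname(best$par))
    return(new_qc_fit("time_varying_ls", est,
                      diagnostics = list(residual_norm = sqrt(best$value),
                                         convergence = best$convergence,
                                         converged = best$convergence == 0)))
  }

  # MLE mode
  amp <- if (is.numeric(data)) data
         else if ("amplitude" %in% names(data)) data$amplitude
  if (is.null(amp))
    stop("MLE mode needs an amplitude trace (add_quantal_noise output)",
         call. = FALSE)
  if (is.null(c_mean) || is.null(cv_q))
    stop("MLE mode needs `c_mean` and `cv_q`", call. = FALSE)
  n <- length(amp)
  if (is.null(M)) {
    # plug-in pool size: fit the schedule by LS on the normalized mean
    # amplitude first, then M = steady mean QC / (pbar * pr)
    qc_approx <- amp / c_mean
    norm_trace <- qc_approx / qc_approx[1]
    fit0 <- fit_time_varying_refill(norm_trace, pr_fixed = pr_fixed,
                                    n_transient = n_transient, mode = "ls")
    pd_tail0 <- fit0$estimates$estimate[npar]
    pbar0 <- steady_state_occupancy(pr_fixed, pd_tail0, 0)
    ss_qc <- mean(qc_approx[min(10, n):n])
    M <- max(1L, round(ss_qc / (pbar0 * pr_fixed)))
  }

  # Sparse support of the Gaussian amplitude densities: only (stimulus, b)
  # pairs where the density is non-negligible contribute to the marginal,
  # and the density factor does not depend on the schedule being fitted.
  if (cv_q <= 0)
    stop("MLE mode needs `cv_q` > 0 (use the LS mode for noiseless traces)",
         call. = FALSE)
  li <- lb <- ld <- vector("list", n)
  for (i in seq_len(n)) {
    if (amp[i] == 0) {
      li[[i]] <- i; lb[[i]] <- 0L; ld[[i]] <- 1
      next
    }
    centre <- amp[i] / c_mean
    half <- 10 * cv_q * sqrt(max(centre, 1)) + 2
    bs <- max(1L, floor(centre - half)):min(M, ceiling(centre + half))
    dnv <- stats::dnorm(amp[i], mean = bs * c_mean,
                        sd = sqrt(bs) * cv_q * c_mean)
    keep <- dnv > 0
    li[[i]] <- rep(i, sum(keep)); lb[[i]] <- bs[keep]; ld[[i]] <- dnv[keep]
  }
  supp_i <- unlist(li); supp_b <- unlist(lb); supp_dn <- unlist(ld)
  ifac <- factor(supp_i, levels = seq_len(n))

  negll <- function(x) {
    s <- occupancy_for(x, n) * pr_fixed
    contrib <- stats::dbinom(supp_b, M, s[supp_i]) * supp_dn
    lik <- as.numeric(rowsum(contrib, ifac))
    -sum(log(pmax(lik, 1e-300)))
  }
  start <- rep(0.5, npar)
  fit <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = rep(1e-4, npar), upper = rep(1 - 1e-4, npar),
                      control = list(maxit = 300))
  est <- tibble::tibble(term = terms, estimate = unname(fit$par))
  new_qc_fit("mle", est,
             diagnostics = list(logLik = -fit$value,
                                convergence = fit$convergence,
                                converged = fit$convergence == 0,
                                M = M))
}

#' Feasible (pr, pd) region under fluctuation-statistic constraints
#'
#' Evaluates the steady-state Fano factor, lag-1 correlation and normalized
#' depression on a regular grid over the open unit square (`pu = 0`) and
#' marks the cells consistent with the supplied bounds.  Omitted bounds are
#' unconstrained.  Intersecting an upper Fano bound, a lower correlation
#' bound and a depression window is how a measured QC trace narrows the
#' admissible presynaptic parameters.
#'
#' @param ff_max Upper bound on the Fano factor (or `NULL`).
#' @param rho_min Lower bound on the lag-1 correlation (or `NULL`).
#' @param dep_range Length-2 numeric `c(lo, hi)` window on the normalized
#'   depression \eqn{\bar p} (or `NULL`).
#' @param resolution Grid spacing (default 0.005).
#' @return A `feasible_region` tibble with columns `pr`, `pd`, the three
#'   per-constraint logicals and `feasible` (their conjunction).
#' @examples
#' fr <- feasible_region(ff_max = 0.55, rho_min = -0.06,
#'                       dep_range = c(0.45, 0.65), resolution = 0.02)
#' range(fr$pr[fr$feasible])
#' @export
feasible_region <- function(ff_max = NULL, rho_min = NULL, dep_range = NULL,
                            resolution = 0.005) {
  if (resolution <= 0 || resolution > 0.5)
    stop("empty grid: resolution must lie in (0, 0.5]", call. = FALSE)
  g <- seq(resolution, 1 - resolution, by = resolution)
  grid <- tidyr::expand_grid(pr = g, pd = g) |>
    dplyr::mutate(
      ff   = steady_state_fano(.data$pr, .data$pd, 0),
      rho  = steady_state_corr(.data$pr, .data$pd, 0),
      pbar = steady_state_occupancy(.data$pr, .data$pd, 0),
      ff_ok  = if (is.null(ff_max)) TRUE else .data$ff <= ff_max,
      rho_ok = if (is.null(rho_min)) TRUE else .data$rho >= rho_min,
      dep_ok = if (is.null(dep_range)) TRUE else
        .data$pbar >= dep_range[1] & .data$pbar <= dep_range[2],
      feasible = .data$ff_ok & .data$rho_ok & .data$dep_ok)
  class(grid) <- c("feasible_region", class(grid))
  attr(grid, "bounds") <- list(ff_max = ff_max, rho_min = rho_min,
                               dep_range = dep_range)
  grid
}
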