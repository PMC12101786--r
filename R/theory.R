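#' Docking-site occupancy recursion
#'
#' Computes the probability `p_i` that a docking site is occupied just
#' before the i-th action potential, for arbitrary time-varying release
#' (`pr`), refilling (`pd`) and undocking (`pu`) schedules, together with
#' the derived exact QC moments.  The occupancy obeys
#'
#' \deqn{p_{i+1} = p_i (1 - p_{r,i})(1 - p_{u,i}) +
#'                 (1 - p_i (1 - p_{r,i}))\, p_{d,i},}
#'
#' with `p_1` given.  The quantal content at stimulus `i` is binomial with
#' `M` trials and success probability `p_i p_{r,i}`, so the mean QC is
#' `M p_i p_{r,i}` and the Fano factor is `1 - p_i p_{r,i}` (equivalently
#' `1 - mean_qc / M`).
#'
#' @param params A [synapse_params()] object.
#' @param n_stimuli Number of stimuli (>= 1) to evaluate.
#' @return A tibble of class `occupancy_series` with columns `stimulus`,
#'   `p` (occupancy just before the AP), `mean_qc` and `fano`, plus an `M`
#'   attribute.
#' @examples
#' occupancy_recursion(synapse_params(M = 200, pr = 0.15, pd = 0.05), 20)
#' @export
occupancy_recursion <- function(params, n_stimuli) {
  stopifnot(inherits(params, "synapse_params"))
  if (length(n_stimuli) != 1L || n_stimuli < 1)
    stop("`n_stimuli` must be >= 1", call. = FALSE)
  n <- as.integer(n_stimuli)
  pr <- schedule_at(params$pr, seq_len(n))
  pd <- schedule_at(params$pd, seq_len(n))
  pu <- schedule_at(params$pu, seq_len(n))
  p <- occupancy_p_raw(params$p1, pr, pd, pu, n)
  out <- tibble::tibble(
    stimulus = seq_len(n),
    p        = p,
    mean_qc  = params$M * p * pr,
    fano     = 1 - p * pr)
  attr(out, "M") <- params$M
  attr(out, "params") <- params
  class(out) <- c("occupancy_series", class(out))
  out
}

#' Closed-form occupancy for constant parameters
#'
#' Explicit solution of the occupancy recursion when `pr`, `pd`, `pu` are
#' constant:
#' \deqn{p_i = \frac{p_d + \lambda^{i-1}\,(p_1 D - p_d)}{D}, \qquad
#'       \lambda = (1 - p_r)(1 - p_d - p_u),\quad
#'       D = p_d + p_u + p_r (1 - p_d - p_u).}
#'
#' @param p1 Initial occupancy probability.
#' @param pr,pu,pd Constant per-stimulus probabilities.
#' @param i Vector of 1-based stimulus indices.
#' @return Occupancy probabilities `p_i` (vectorised over `i`).
#' @export
occupancy_closed_form <- function(p1, pr, pd, pu = 0, i) {
  check_prob(p1, "p1"); check_prob(pr, "pr")
  check_prob(pd, "pd"); check_prob(pu, "pu")
  if (any(i < 1)) stop("stimulus indices are 1-based", call. = FALSE)
  D <- pd + pu + pr * (1 - pd - pu)
  if (D == 0)
    stop("degenerate parameters: pd + pu + pr(1 - pd - pu) = 0", call. = FALSE)
  lam <- (1 - pr) * (1 - pd - pu)
  (pd + lam^(i - 1) * (p1 * D - pd)) / D
}

# Bare numeric occupancy path used by fitting objectives, where the tibble
# construction of occupancy_recursion() would dominate the runtime.
occupancy_p_raw <- function(p1, pr, pd, pu, n) {
  p <- numeric(n)
  p[1] <- p1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      surv <- p[i] * (1 - pr[i])
      p[i + 1L] <- surv * (1 - pu[i]) + (1 - surv) * pd[i]
    }
  }
  p
}

check_prob <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' Exact quantal-content distribution at a stimulus
#'
#' The QC at stimulus `i` follows Binomial(`M`, `p_i * p_{r,i}`), where
#' `p_i` comes from [occupancy_recursion()].
#'
#' @inheritParams occupancy_recursion
#' @param i Single 1-based stimulus index.
#' @return Tibble with columns `qc` (0..M) and `prob`.
#' @export
qc_pmf <- function(params, i) {
  stopifnot(inherits(params, "synapse_params"), length(i) == 1L, i >= 1)
  occ <- occupancy_recursion(params, i)
  pri <- schedule_at(params$pr, i)
  prob_succ <- occ$p[i] * pri
  tibble::tibble(
    qc   = 0:params$M,
    prob = stats::dbinom(0:params$M, size = params$M, prob = prob_succ))
}

# Shared denominator of the steady-state formulas; errors on the fully
# degenerate all-zero case rather than returning a limit.
ss_denominator <- function(pr, pd, pu) {
  D <- pd + pu + pr * (1 - pd - pu)
  if (any(D == 0))
    stop("degenerate parameters: pd + pu + pr(1 - pd - pu) = 0; steady state undefined",
         call. = FALSE)
  D
}

#' Steady-state occupancy probability
#'
#' The fixed point of the occupancy recursion for constant parameters,
#' \deqn{\bar p = \frac{p_d}{p_d + p_u + p_r (1 - p_d - p_u)}.}
#' With `p1 = 1` and a constant release probability this also equals the
#' normalized synaptic depression (steady-state mean QC over first-stimulus
#' mean QC).
#'
#' @param pr,pd,pu Constant probabilities (vectorised).
#' @return Steady-state occupancy \eqn{\bar p}.
#' @examples
#' steady_state_occupancy(pr = 0.53, pd = 0.93)  # ~0.96
#' @export
steady_state_occupancy <- function(pr, pd, pu = 0) {
  check_prob(pr, "pr"); check_prob(pd, "pd"); check_prob(pu, "pu")
  pd / ss_denominator(pr, pd, pu)
}

#' Steady-state quantal-content Fano factor
#'
#' \deqn{FF = \frac{p_d + p_r + p_u(1 - p_r) - 2 p_r p_d}
#'                 {p_d + p_r + p_u(1 - p_r) - p_r p_d}
#'          = 1 - \bar p\, p_r.}
#' For `pu = 0` the expression is symmetric under swapping `pr` and `pd`,
#' and `1 - FF` is a lower bound on both probabilities.
#'
#' @inheritParams steady_state_occupancy
#' @return Fano factor in (0, 1].
#' @examples
#' steady_state_fano(pr = 0.93, pd = 0.53)  # ~0.49
#' @export
steady_state_fano <- function(pr, pd, pu = 0) {
  1 - steady_state_occupancy(pr, pd, pu) * pr
}

#' Steady-state QC autocorrelation
#'
#' Pearson correlation between quantal contents separated by `lag` stimuli
#' at steady state.  For `lag = 1`:
#' \deqn{\rho = \frac{-p_d (1 - p_r) p_r (1 - p_d - p_u)}
#'                   {p_r + p_d + p_u (1 - p_r) - 2 p_d p_r} \le 0.}
#' For `lag > 1` the correlation decays geometrically,
#' \eqn{\rho_\ell = \rho_1 \lambda^{\ell-1}} with
#' \eqn{\lambda = (1 - p_r)(1 - p_u - p_d)}, the subdominant eigenvalue of
#' the per-site occupancy chain (release-conditioned docking state
#' propagates linearly between stimuli, so covariances beyond lag 1 are
#' damped by \eqn{\lambda} per step).
#'
#' @inheritParams steady_state_occupancy
#' @param lag Positive integer lag (vectorised).
#' @return Correlation value(s), always in \[-0.125, 0\] when `pu = 0`.
#' @examples
#' steady_state_corr(pr = 0.5, pd = 0.5)  # -0.125, the global minimum
#' @export
steady_state_corr <- function(pr, pd, pu = 0, lag = 1) {
  check_prob(pr, "pr"); check_prob(pd, "pd"); check_prob(pu, "pu")
  if (any(lag < 1) || any(lag != round(lag)))
    stop("`lag` must be a positive integer", call. = FALSE)
  denom <- pr + pd + pu * (1 - pr) - 2 * pd * pr
  if (any(denom == 0))
    stop("degenerate parameters: correlation denominator is zero", call. = FALSE)
  rho1 <- -pd * (1 - pr) * pr * (1 - pd - pu) / denom
  lam <- (1 - pr) * (1 - pu - pd)
  rho1 * lam^(lag - 1)
}

#' Release probability minimising the lag-1 correlation at fixed refilling
#'
#' For a given refilling probability `pd` (with `pu = 0`), the lag-1 QC
#' correlation varies non-monotonically in the release probability and is
#' most negative where \eqn{\partial\rho/\partial p_r = 0}, i.e. at the
#' root of \eqn{p_r^2 (1 - 2 p_d) + 2 p_d p_r - p_d = 0} inside the unit
#' interval:
#' \deqn{p_r^* = \frac{\sqrt{p_d (1 - p_d)} - p_d}{1 - 2 p_d},}
#' with \eqn{p_r^* = 1/2} at \eqn{p_d = 1/2} (the removable singularity,
#' and the location of the global minimum \eqn{\rho = -0.125}).
#'
#' @param pd Refilling probability in (0, 1); vectorised.
#' @return The minimising release probability.
#' @export
rho_argmin_pr <- function(pd) {
  if (any(is.na(pd)) || any(pd <= 0) || any(pd >= 1))
    stop("`pd` must lie strictly inside (0, 1)", call. = FALSE)
  ifelse(abs(pd - 0.5) < 1e-12, 0.5,
         (sqrt(pd * (1 - pd)) - pd) / (1 - 2 * pd))
}

#' Normalized synaptic depression
#'
#' Steady-state mean QC divided by the first-stimulus mean QC,
#' \eqn{\bar p\, p_r / (p_1\, p_{r,1})}.  Steady-state values are taken on
#' the constant tails of the schedules.  Equals \eqn{\bar p} when `p1 = 1`
#' and the release probability is constant.
#'
#' @inheritParams occupancy_recursion
#' @return A single depression ratio.
#' @export
normalized_depression <- function(params) {
  stopifnot(inherits(params, "synapse_params"))
  tails <- tail_probs(params)
  pr1 <- schedule_at(params$pr, 1L)
  first <- params$p1 * pr1
  if (first == 0)
    stop("first-stimulus mean QC is zero; depression ratio undefined", call. = FALSE)
  pbar <- steady_state_occupancy(tails$pr, tails$pd, tails$pu)
  pbar * tails$pr / first
}

#' Parameter lower bounds implied by the Fano factor
#'
#' With `pu = 0`, any pair (`pr`, `pd`) consistent with a steady-state Fano
#' factor `ff` satisfies `pr >= 1 - ff` and `pd >= 1 - ff`, so a measured
#' Fano factor alone bounds both probabilities from below.
#'
#' @param ff Fano factor in (0, 1].
#' @return Tibble with columns `pr_min` and `pd_min`.
#' @export
fano_lower_bounds <- function(ff) {
  if (any(is.na(ff)) || any(ff < 0) || any(ff > 1))
    stop("`ff` must be in [0, 1]", call. = FALSE)
  tibble::tibble(pr_min = 1 - ff, pd_min = 1 - ff)
}

#' Evoked-amplitude fluctuation statistics
#'
#' Propagates quantal-size variability into the statistics of evoked
#' postsynaptic amplitudes.  With amplitude \eqn{A_i = \sum_{k=1}^{b_i} c_k}
#' (independent quantal sizes with mean \eqn{\langle c\rangle} and
#' coefficient of variation \eqn{CV_q}), the law of total (co)variance
#' gives
#' \deqn{FF^e = \langle c\rangle (FF + CV_q^2), \qquad
#'       \rho^e = \rho\, \frac{FF}{FF + CV_q^2}.}
#' Both reduce to the QC statistics at \eqn{\langle c\rangle = 1, CV_q = 0}.
#'
#' @param ff,rho Steady-state QC Fano factor and lag-1 correlation.
#' @param c_mean Mean quantal size (amplitude units, e.g. pA); > 0.
#' @param cv_q Coefficient of variation of quantal size; >= 0.
#' @return Tibble with columns `ff_e` (amplitude units) and `rho_e`.
#' @examples
#' evoked_stats(ff = 0.5, rho = -0.035, c_mean = 22, cv_q = 0.3)
#' @export
evoked_stats <- function(ff, rho, c_mean, cv_q) {
  if (any(c_mean <= 0)) stop("`c_mean` must be positive", call. = FALSE)
  if (any(cv_q < 0)) stop("`cv_q` must be non-negative", call. = FALSE)
  tibble::tibble(
    ff_e  = c_mean * (ff + cv_q^2),
    rho_e = rho * ff / (ff + cv_q^2))
}
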