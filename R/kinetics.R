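#' Convert docking/undocking rates to per-interval probabilities
#'
#' Each docking site is a two-state continuous-time Markov chain with
#' docking rate `k_d` (empty -> occupied, per second) and undocking rate
#' `k_u` (occupied -> empty).  Over an inter-stimulus interval of length
#' `dt` the transition probabilities are
#' \deqn{p_d = \frac{k_d}{k_d + k_u}\left(1 - e^{-(k_d + k_u) dt}\right),
#'  \qquad
#'       p_u = \frac{k_u}{k_d + k_u}\left(1 - e^{-(k_d + k_u) dt}\right),}
#' reducing to \eqn{p_d = 1 - e^{-k_d dt}} when `k_u = 0`.  Because the
#' interval length enters explicitly, the probabilities change with the
#' stimulation frequency `f = 1/dt`.
#'
#' @param k_d,k_u Non-negative rates (per second); vectorised.
#' @param dt Inter-stimulus interval in seconds; > 0.
#' @return Tibble with columns `pd` and `pu`.
#' @examples
#' rates_to_probs(k_d = 54.4, k_u = 19.1, dt = 0.02)
#' @export
rates_to_probs <- function(k_d, k_u = 0, dt) {
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  if (any(k_d < 0) || any(k_u < 0)) stop("rates must be >= 0", call. = FALSE)
  n <- max(length(k_d), length(k_u), length(dt))
  k_d <- rep_len(k_d, n); k_u <- rep_len(k_u, n); dt <- rep_len(dt, n)
  ktot <- k_d + k_u
  mix <- ifelse(ktot == 0, 0, -expm1(-ktot * dt))
  frac_d <- ifelse(ktot == 0, 0, k_d / pmax(ktot, .Machine$double.xmin))
  tibble::tibble(pd = frac_d * mix,
                 pu = (1 - frac_d) * mix * (ktot > 0))
}

#' Convert per-interval probabilities to docking/undocking rates
#'
#' Exact inverse of [rates_to_probs()]: the total rate is
#' \eqn{k_d + k_u = -\ln(1 - p_d - p_u)/dt}, split in proportion
#' `pd : pu`.  Requires `pd + pu < 1` — a chain that fully mixes within a
#' finite interval has no finite rates.
#'
#' @param pd,pu Per-interval refilling and undocking probabilities.
#' @param dt Inter-stimulus interval in seconds; > 0.
#' @return Tibble with columns `k_d` and `k_u` (per second).
#' @examples
#' probs_to_rates(pd = 0.57, pu = 0.2, dt = 0.02)  # k_d ~ 54 per second
#' @export
probs_to_rates <- function(pd, pu = 0, dt) {
  check_prob(pd, "pd"); check_prob(pu, "pu")
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  if (any(pd + pu >= 1))
    stop("pd + pu must be < 1: no finite rates reproduce full mixing in one interval",
         call. = FALSE)
  ktot <- -log1p(-(pd + pu)) / dt
  tot_p <- pd + pu
  tibble::tibble(
    k_d = ifelse(tot_p == 0, 0, ktot * pd / tot_p),
    k_u = ifelse(tot_p == 0, 0, ktot * pu / tot_p))
}
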