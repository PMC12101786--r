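#' Inter-stimulus interval models
#'
#' Describes action-potential timing for the simulator: `fixed` intervals
#' of length `dt` (the exact-theory regime), or i.i.d. random intervals
#' drawn from an exponential or gamma distribution.  With random intervals
#' the per-interval refilling/undocking probabilities are recomputed from
#' the kinetic rates for each sampled interval, and the quantal content is
#' no longer binomial.
#'
#' @param kind `"fixed"` or `"iid"`.
#' @param dt Interval length in seconds (fixed kind).
#' @param family `"exponential"` or `"gamma"` (iid kind).
#' @param mean Mean interval in seconds (exponential).
#' @param shape,scale Gamma parameters (seconds for `scale`).
#' @return An `interval_model` object.
#' @examples
#' interval_model("fixed", dt = 0.02)                 # 50 Hz train
#' interval_model("iid", family = "exponential", mean = 0.02)
#' @export
interval_model <- function(kind = c("fixed", "iid"), dt = NULL,
                           family = c("exponential", "gamma"),
                           mean = NULL, shape = NULL, scale = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (is.null(dt) || dt <= 0) stop("fixed intervals need `dt` > 0", call. = FALSE)
    return(structure(list(kind = "fixed", dt = dt), class = "interval_model"))
  }
  family <- match.arg(family)
  if (family == "exponential") {
    if (is.null(mean) || mean <= 0)
      stop("exponential intervals need `mean` > 0", call. = FALSE)
    structure(list(kind = "iid", family = "exponential", mean = mean),
              class = "interval_model")
  } else {
    if (is.null(shape) || is.null(scale) || shape <= 0 || scale <= 0)
      stop("gamma intervals need `shape` > 0 and `scale` > 0", call. = FALSE)
    structure(list(kind = "iid", family = "gamma", shape = shape, scale = scale),
              class = "interval_model")
  }
}

sample_intervals <- function(im, n) {
  switch(im$family,
         exponential = stats::rexp(n, rate = 1 / im$mean),
         gamma       = stats::rgamma(n, shape = im$shape, scale = im$scale))
}

new_qc_trace <- function(df, params = NULL, seed = NULL, recording_id = NULL) {
  attr(df, "params") <- params
  attr(df, "seed") <- seed
  if (!is.null(recording_id)) attr(df, "recording_id") <- recording_id
  class(df) <- unique(c("qc_trace", class(df)))
  df
}

#' Simulate one trial of the per-site release model
#'
#' Seeded Monte-Carlo realisation of the docking-site model under a
#' deterministic AP train.  Each of the `M` sites is initialised occupied
#' with probability `p1`.  At each stimulus, every docked vesicle fuses
#' independently with probability `pr_i` (fused sites empty instantly);
#' between stimuli, surviving occupied sites undock with probability `pu_i`
#' and empty sites (including those just emptied by fusion) refill with
#' probability `pd_i` — at most one transition per site per interval.
#'
#' @inheritParams occupancy_recursion
#' @param seed Integer seed; identical seeds give identical traces.
#' @param method `"site"` simulates every site as an explicit Bernoulli
#'   chain (the literal model); `"aggregate"` draws binomial counts on the
#'   occupied/empty totals, which is equidistributed because sites are
#'   identical and independent, and much faster for long trains.
#' @return A `qc_trace` tibble with columns `stimulus`, `qc` and
#'   `n_docked` (docked vesicles just before each AP).
#' @examples
#' simulate_trial(synapse_params(M = 100, pr = 0.5, pd = 0.4, pu = 0.1),
#'                n_stimuli = 10, seed = 1)
#' @export
simulate_trial <- function(params, n_stimuli, seed,
                           method = c("site", "aggregate")) {
  stopifnot(inherits(params, "synapse_params"))
  method <- match.arg(method)
  n <- as.integer(n_stimuli)
  if (n < 1) stop("`n_stimuli` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  pr <- schedule_at(params$pr, seq_len(n))
  pd <- schedule_at(params$pd, seq_len(n))
  pu <- schedule_at(params$pu, seq_len(n))
  M <- params$M
  qc <- integer(n); ndock <- integer(n)
  if (method == "site") {
    occ <- stats::runif(M) < params$p1
    for (i in seq_len(n)) {
      ndock[i] <- sum(occ)
      fuse <- occ & (stats::runif(M) < pr[i])
      qc[i] <- sum(fuse)
      occ <- occ & !fuse
      if (i < n) {
        undock <- occ & (stats::runif(M) < pu[i])
        refill <- !occ & (stats::runif(M) < pd[i])
        occ <- (occ & !undock) | refill
      }
    }
  } else {
    k <- stats::rbinom(1L, M, params$p1)
    for (i in seq_len(n)) {
      ndock[i] <- k
      qc[i] <- stats::rbinom(1L, k, pr[i])
      k <- k - qc[i]
      if (i < n) {
        lost <- stats::rbinom(1L, k, pu[i])
        gained <- stats::rbinom(1L, M - k, pd[i])
        k <- k - lost + gained
      }
    }
  }
  new_qc_trace(
    tibble::tibble(stimulus = seq_len(n), qc = as.numeric(qc),
                   n_docked = ndock),
    params = params, seed = seed)
}

#' Simulate an ensemble of independent trials
#'
#' Repeats [simulate_trial()] with per-trial seeds `seed + trial - 1`, so
#' any single trial can be reproduced in isolation.
#'
#' @inheritParams simulate_trial
#' @param n_trials Number of independent trials.
#' @return A tibble with columns `trial`, `stimulus`, `qc`.
#' @export
simulate_ensemble <- function(params, n_stimuli, n_trials, seed,
                              method = "aggregate") {
  stopifnot(inherits(params, "synapse_params"))
  n <- as.integer(n_stimuli)
  pr <- schedule_at(params$pr, seq_len(n))
  pd <- schedule_at(params$pd, seq_len(n))
  pu <- schedule_at(params$pu, seq_len(n))
  M <- params$M
  qc <- matrix(0L, nrow = n, ncol = n_trials)
  if (method == "aggregate") {
    for (t in seq_len(n_trials)) {
      set.seed(as.integer(seed) + t - 1L)
      k <- stats::rbinom(1L, M, params$p1)
      for (i in seq_len(n)) {
        b <- stats::rbinom(1L, k, pr[i])
        qc[i, t] <- b
        k <- k - b
        if (i < n) {
          k <- k - stats::rbinom(1L, k, pu[i]) +
            stats::rbinom(1L, M - k, pd[i])
        }
      }
    }
  } else {
    for (t in seq_len(n_trials)) {
      qc[, t] <- simulate_trial(params, n, seed = seed + t - 1L,
                                method = method)$qc
    }
  }
  tibble::tibble(
    trial    = rep(seq_len(n_trials), each = n),
    stimulus = rep(seq_len(n), times = n_trials),
    qc       = as.numeric(qc))
}

#' Simulate a train with random AP timing
#'
#' As [simulate_trial()], but inter-stimulus intervals are drawn i.i.d.
#' from `im` and the refilling/undocking probabilities for each interval
#' are recomputed from the continuous-time site kinetics via
#' [rates_to_probs()].  Under random AP timing the QC distribution is not
#' binomial and its Fano factor can exceed one.
#'
#' @param M,p1 Docking-site count and initial occupancy.
#' @param pr Release-probability schedule (scalar or [qc_schedule()]).
#' @param k_d,k_u Docking/undocking rates, per second.
#' @param im An [interval_model()] of kind `"iid"` (a degenerate check with
#'   kind `"fixed"` is also accepted and reduces to the fixed-train case).
#' @param n_stimuli Number of stimuli.
#' @param seed Integer seed.
#' @return A `qc_trace` tibble with columns `stimulus`, `time` (AP times,
#'   seconds, first AP at 0), `qc`, `n_docked`.
#' @export
simulate_random_train <- function(M, p1 = 1, pr, k_d, k_u = 0, im,
                                  n_stimuli, seed) {
  stopifnot(inherits(im, "interval_model"))
  n <- as.integer(n_stimuli)
  set.seed(as.integer(seed))
  prs <- schedule_at(qc_schedule(pr), seq_len(n))
  if (im$kind == "fixed") {
    gaps <- rep(im$dt, n - 1L)
  } else {
    gaps <- sample_intervals(im, n - 1L)
  }
  if (any(gaps <= 0)) stop("sampled interval <= 0", call. = FALSE)
  trans <- rates_to_probs(k_d, k_u, dt = gaps)
  qc <- integer(n); ndock <- integer(n)
  k <- stats::rbinom(1L, M, p1)
  for (i in seq_len(n)) {
    ndock[i] <- k
    qc[i] <- stats::rbinom(1L, k, prs[i])
    k <- k - qc[i]
    if (i < n) {
      lost <- stats::rbinom(1L, k, trans$pu[i])
      gained <- stats::rbinom(1L, M - k, trans$pd[i])
      k <- k - lost + gained
    }
  }
  new_qc_trace(
    tibble::tibble(stimulus = seq_len(n),
                   time = c(0, cumsum(gaps)),
                   qc = as.numeric(qc), n_docked = ndock),
    seed = seed)
}

#' Add quantal-size noise to a simulated trace
#'
#' Converts integer quantal contents into evoked amplitudes: each released
#' quantum contributes an independent Gaussian amplitude with mean `c_mean`
#' and standard deviation `cv_q * c_mean`, floored at zero (amplitudes are
#' physically non-negative; for `cv_q <= 0.5` the clipped mass is
#' negligible).  A QC of zero gives amplitude zero.
#'
#' @param trace A `qc_trace` with integer-valued `qc`.
#' @param c_mean Mean quantal size (e.g. pA).
#' @param cv_q Coefficient of variation of quantal size.
#' @param seed Integer seed.
#' @return The trace with an added `amplitude` column.
#' @export
add_quantal_noise <- function(trace, c_mean, cv_q, seed) {
  if (any(trace$qc != round(trace$qc)))
    stop("quantal-size noise applies to integer (simulated) QCs only",
         call. = FALSE)
  if (c_mean <= 0) stop("`c_mean` must be positive", call. = FALSE)
  if (cv_q < 0) stop("`cv_q` must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  qc <- as.integer(round(trace$qc))
  total <- sum(qc)
  draws <- pmax(stats::rnorm(total, mean = c_mean, sd = cv_q * c_mean), 0)
  grp <- rep.int(seq_along(qc), qc)
  amp <- numeric(length(qc))
  if (total > 0) {
    sums <- tapply(draws, factor(grp, levels = seq_along(qc)), sum)
    amp <- as.numeric(ifelse(is.na(sums), 0, sums))
  }
  trace$amplitude <- amp
  trace
}
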