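# Shared helpers: independent oracles and random-parameter draws.

# Brute-force fixed point of the occupancy recursion, independent of the
# closed form: iterate until convergence.
iterate_to_fixed_point <- function(p1, pr, pd, pu = 0, tol = 1e-14) {
  p <- p1
  repeat {
    surv <- p * (1 - pr)
    p_new <- surv * (1 - pu) + (1 - surv) * pd
    if (abs(p_new - p) < tol) return(p_new)
    p <- p_new
  }
}

# Random constant-parameter draws avoiding degenerate corners.
random_const_params <- function(n, seed, pu_zero = FALSE) {
  set.seed(seed)
  tibble::tibble(
    p1 = runif(n),
    pr = runif(n, 0.02, 0.98),
    pd = runif(n, 0.02, 0.98),
    pu = if (pu_zero) 0 else runif(n, 0, 0.3))
}

# Standard error of a Pearson correlation estimate at sample size n.
se_cor <- function(rho, n) (1 - rho^2) / sqrt(n - 3)

# Approximate standard error of an empirical variance/mean ratio for a
# near-binomial QC sequence (delta method on var and mean).
se_fano <- function(x) {
  n <- length(x)
  m <- mean(x); v <- var(x)
  mu4 <- mean((x - m)^4)
  se_var <- sqrt((mu4 - v^2 * (n - 3) / (n - 1)) / n)
  se_mean <- sd(x) / sqrt(n)
  sqrt((se_var / m)^2 + (v * se_mean / m^2)^2)
}

# Chi-square goodness-of-fit of observed integer QCs against a theoretical
# pmf, pooling tail bins so every expected count is >= 5.
chisq_pvalue <- function(obs_counts, probs) {
  n <- sum(obs_counts)
  expected <- n * probs
  # pool adjacent low-expectation bins
  groups <- integer(length(probs)); g <- 1L; acc <- 0
  for (j in seq_along(probs)) {
    groups[j] <- g
    acc <- acc + expected[j]
    if (acc >= 5 && j < length(probs)) { g <- g + 1L; acc <- 0 }
  }
  o <- tapply(obs_counts, groups, sum)
  e <- tapply(expected, groups, sum)
  if (length(o) < 2) return(1)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
}
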