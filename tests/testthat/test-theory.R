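test_that("occupancy recursion: saturation, fixed point and facilitation", {
  # full refill + full release keeps every site saturated
  sat <- occupancy_recursion(synapse_params(M = 10, p1 = 1, pr = 1, pd = 1),
                             25)
  expect_equal(sat$p, rep(1, 25))

  # long-run occupancy converges to the fixed point of the recursion
  occ <- occupancy_recursion(synapse_params(M = 10, pr = 0.15, pd = 0.05),
                             600)
  fp <- iterate_to_fixed_point(1, 0.15, 0.05)
  expect_equal(tail(occ$p, 1), fp, tolerance = 1e-10)
  expect_equal(fp, 0.05 / (0.05 + 0.15 - 0.0075), tolerance = 1e-12)

  # facilitation preset: mean QC rises over stimuli 1-3 then depresses
  fac <- synapse_params(M = 200, pr = qc_schedule(c(0.15, 0.2, 0.25), 0.3),
                        pd = 0.02)
  occ <- occupancy_recursion(fac, 30)
  expect_true(all(diff(occ$mean_qc[1:3]) > 0))
  expect_lt(occ$mean_qc[30], occ$mean_qc[3])

  # and the simulated ensemble mean tracks the exact mean QC
  ens <- simulate_ensemble(fac, 10, n_trials = 4000, seed = 11)
  emp <- tapply(ens$qc, ens$stimulus, mean)
  se <- tapply(ens$qc, ens$stimulus, sd) / sqrt(4000)
  expect_true(all(abs(emp - occ$mean_qc[1:10]) < 3.5 * se))
})

test_that("schedule validation names the offending schedule", {
  expect_error(synapse_params(M = 5, pr = 1.2, pd = 0.1), "pr")
  expect_error(synapse_params(M = 5, pr = 0.5,
                              pd = qc_schedule(c(0.3, -0.1), 0.2)),
               "pd.*index 2")
})

test_that("closed-form occupancy agrees with the recursion everywhere", {
  draws <- random_const_params(100, seed = 42)
  for (k in seq_len(nrow(draws))) {
    d <- draws[k, ]
    occ <- occupancy_recursion(
      synapse_params(M = 1, p1 = d$p1, pr = d$pr, pd = d$pd, pu = d$pu), 50)
    cf <- occupancy_closed_form(d$p1, d$pr, d$pd, d$pu, 1:50)
    expect_equal(occ$p, cf, tolerance = 1e-12)
  }
  expect_equal(occupancy_closed_form(1, 0.15, 0.05, 0, 1), 1)
  expect_error(occupancy_closed_form(1, 0, 0, 0, 5), "degenerate")
})

test_that("QC pmf is binomial with the exact mean and Fano factor", {
  params <- synapse_params(M = 100, pr = 0.5, pd = 0.4, pu = 0.1)
  pmf <- qc_pmf(params, 1)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  expect_equal(sum(pmf$qc * pmf$prob), 50, tolerance = 1e-9)
  m <- sum(pmf$qc * pmf$prob)
  v <- sum(pmf$qc^2 * pmf$prob) - m^2
  expect_equal(v / m, 0.5, tolerance = 1e-9)

  # pmf moments match the occupancy-series columns for time-varying runs
  tv <- synapse_params(M = 40, pr = qc_schedule(c(0.2, 0.6), 0.4),
                       pd = qc_schedule(c(0.9, 0.1), 0.5), pu = 0.05)
  occ <- occupancy_recursion(tv, 6)
  for (i in c(1, 3, 6)) {
    pmf <- qc_pmf(tv, i)
    m <- sum(pmf$qc * pmf$prob)
    v <- sum(pmf$qc^2 * pmf$prob) - m^2
    expect_equal(m, occ$mean_qc[i], tolerance = 1e-9)
    expect_equal(v / m, occ$fano[i], tolerance = 1e-9)
  }

  # zero release probability gives a point mass at zero
  pmf0 <- qc_pmf(synapse_params(M = 10, pr = 0, pd = 0.5), 2)
  expect_equal(pmf0$prob, c(1, rep(0, 10)))
})

test_that("Fano factor and mean QC satisfy FF_i = 1 - <b_i>/M exactly", {
  draws <- random_const_params(25, seed = 7)
  for (k in seq_len(nrow(draws))) {
    d <- draws[k, ]
    occ <- occupancy_recursion(
      synapse_params(M = 150, p1 = d$p1, pr = d$pr, pd = d$pd, pu = d$pu), 40)
    expect_equal(occ$fano + occ$mean_qc / 150, rep(1, 40), tolerance = 1e-12)
  }
})

test_that("larger mean QC always implies smaller Fano factor at equal M", {
  sets <- list(c(0.15, 0.3), c(0.15, 0.15), c(0.15, 0.05), c(0.6, 0.4))
  occs <- lapply(sets, function(s)
    occupancy_recursion(synapse_params(M = 200, pr = s[1], pd = s[2]), 30))
  for (a in seq_along(occs)) for (b in seq_along(occs)) {
    if (a == b) next
    gt <- occs[[a]]$mean_qc > occs[[b]]$mean_qc
    expect_true(all(occs[[a]]$fano[gt] < occs[[b]]$fano[gt]))
  }
})

test_that("occupancy converges geometrically to the steady state", {
  draws <- random_const_params(30, seed = 13)
  for (k in seq_len(nrow(draws))) {
    d <- draws[k, ]
    occ <- occupancy_recursion(
      synapse_params(M = 1, p1 = d$p1, pr = d$pr, pd = d$pd, pu = d$pu), 60)
    pbar <- steady_state_occupancy(d$pr, d$pd, d$pu)
    lam <- abs((1 - d$pr) * (1 - d$pu - d$pd))
    bound <- abs(d$p1 - pbar) * lam^(0:59)
    expect_true(all(abs(occ$p - pbar) <= bound + 1e-12))
  }
})

test_that("steady-state occupancy, Fano factor and depression limits", {
  expect_equal(steady_state_occupancy(0.15, 0.05), 0.05 / 0.1925,
               tolerance = 1e-12)
  expect_equal(steady_state_occupancy(0.53, 0.93), 0.96, tolerance = 0.005)
  expect_gt(steady_state_occupancy(0.4, 0.999), 0.995)  # pd -> 1 limit

  expect_equal(steady_state_fano(0.93, 0.53), 0.490, tolerance = 0.001)
  expect_gt(steady_state_fano(0.001, 0.5), 0.99)        # pr -> 0 gives FF -> 1
  # high-probability regime: FF ~ 2 - pd - pr within 0.02 (absolute)
  expect_lt(abs(steady_state_fano(0.95, 0.95) - (2 - 0.95 - 0.95)), 0.02)

  dep <- normalized_depression(synapse_params(M = 10, pr = 0.53, pd = 0.93))
  expect_equal(dep, 0.96, tolerance = 0.005)
  expect_gt(normalized_depression(synapse_params(M = 10, pr = 0.4, pd = 0.999)),
            0.99)
  expect_lt(normalized_depression(synapse_params(M = 10, pr = 0.4, pd = 1e-4)),
            0.001)
  expect_error(normalized_depression(synapse_params(M = 10, pr = 0, pd = 0.5)),
               "undefined")
})

test_that("FF and rho are swap-symmetric in (pr, pd) when pu = 0", {
  draws <- random_const_params(50, seed = 5, pu_zero = TRUE)
  expect_equal(steady_state_fano(draws$pr, draws$pd),
               steady_state_fano(draws$pd, draws$pr))
  expect_equal(steady_state_corr(draws$pr, draws$pd),
               steady_state_corr(draws$pd, draws$pr))
})

test_that("lag-1 correlation is bounded in [-0.125, 0] with its minimum at (0.5, 0.5)", {
  g <- seq(0.02, 0.98, by = 0.02)
  grid <- expand.grid(pr = g, pd = g)
  rho <- steady_state_corr(grid$pr, grid$pd)
  expect_true(all(rho <= 1e-12))
  expect_true(all(rho >= -0.125 - 1e-12))
  expect_equal(unlist(grid[which.min(rho), ]), c(pr = 0.5, pd = 0.5))
  expect_equal(steady_state_corr(0.5, 0.5), -0.125)
  expect_equal(steady_state_corr(1, 0.7), 0)   # pr = 1 erases memory
})

test_that("rho_argmin_pr gives the grid minimiser of rho over pr", {
  expect_equal(rho_argmin_pr(0.5), 0.5)
  # stationary-point equation at pd = 0.8: pr^2(1-2*0.8) + 1.6 pr - 0.8 = 0
  pr8 <- rho_argmin_pr(0.8)
  expect_equal(pr8^2 * (1 - 1.6) + 1.6 * pr8 - 0.8, 0, tolerance = 1e-12)
  expect_lt(rho_argmin_pr(1e-6), 2e-3)   # pd -> 0 limit
  for (pd in c(0.3, 0.5, 0.8)) {
    pr_star <- rho_argmin_pr(pd)
    prs <- seq(0.005, 0.995, by = 0.005)
    grid_min <- prs[which.min(steady_state_corr(prs, pd))]
    expect_equal(pr_star, grid_min, tolerance = 0.005)
    # local-minimum property
    eps <- 1e-4
    expect_lte(steady_state_corr(pr_star, pd),
               min(steady_state_corr(pr_star - eps, pd),
                   steady_state_corr(pr_star + eps, pd)))
  }
  expect_error(rho_argmin_pr(1), "inside")
})

test_that("1 - FF lower-bounds both probabilities", {
  expect_equal(fano_lower_bounds(1), tibble::tibble(pr_min = 0, pd_min = 0))
  expect_equal(fano_lower_bounds(0.5),
               tibble::tibble(pr_min = 0.5, pd_min = 0.5))
  draws <- random_const_params(50, seed = 99, pu_zero = TRUE)
  ff <- steady_state_fano(draws$pr, draws$pd)
  b <- fano_lower_bounds(ff)
  expect_true(all(draws$pr >= b$pr_min - 1e-12))
  expect_true(all(draws$pd >= b$pd_min - 1e-12))
})

test_that("evoked-amplitude statistics reduce correctly and match the closed form", {
  ev0 <- evoked_stats(ff = 0.37, rho = -0.08, c_mean = 1, cv_q = 0)
  expect_equal(ev0$ff_e, 0.37)
  expect_equal(ev0$rho_e, -0.08)

  ev <- evoked_stats(ff = 0.5, rho = -0.035, c_mean = 22, cv_q = 0.3)
  expect_equal(ev$ff_e, 22 * 0.59, tolerance = 1e-12)
  expect_equal(ev$rho_e, -0.035 * 0.5 / 0.59, tolerance = 1e-12)

  expect_error(evoked_stats(0.5, -0.03, c_mean = 0, cv_q = 0.3), "c_mean")
  expect_error(evoked_stats(0.5, -0.03, c_mean = 22, cv_q = -1), "cv_q")
})
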