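#' Named synthetic-recording presets
#'
#' Generates seeded synthetic QC traces for a set of named experimental
#' scenarios, returning the trace together with the ground-truth generating
#' parameters so that inference can be validated by recovery.
#'
#' Presets:
#'
#' * `"mntb_lso"` — emulates a 50-Hz, 3000-stimulus recording from an
#'   auditory brainstem inhibitory synapse: `pr = 0.93`, refilling schedule
#'   0.92, 0.73, 0.66, 0.53, 0.12 then 0.51, `p1 = 1`, `pu = 0`,
#'   `M = 100`, with Gaussian quantal-size noise (mean 22 pA, CV 0.3)
#'   producing evoked amplitudes.  Its steady-state Fano factor is ~0.51
#'   and lag-1 correlation ~ -0.03.
#' * `"fig2_blue"`, `"fig2_orange"`, `"fig2_gray"` — depression scenarios
#'   with `M = 200`, `pr = 0.15` and refilling 0.3 / 0.15 / 0.05.
#' * `"fig2_yellow"` — facilitation-then-depression: release schedule
#'   0.15, 0.2, 0.25 then 0.3 with refilling 0.02.
#' * `"fig3_low"` — low constant probabilities (`pr = 0.15`, `pd = 0.05`);
#'   Fano factor rises towards 1.
#' * `"fig3_high"` — high release (`pr = 0.9`) with a time-varying
#'   refilling schedule solved from the occupancy recursion so the
#'   normalized mean depression matches `"fig3_low"`; the Fano profile
#'   starts low and rises.
#' * `"fig3_sites"` — `pr = pd = 0.9`: the same mean depression can arise
#'   from a shrinking number of available docking sites, and the Fano
#'   factor stays low throughout.
#'
#' @param scenario Preset name.
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param n_stimuli Optional override of the preset's train length.
#' @return A list with elements `trace` (a `qc_trace`; for `"mntb_lso"`
#'   it includes an `amplitude` column), `params` (the generating
#'   [synapse_params()]) and, where quantal noise is applied, `c_mean` and
#'   `cv_q`.
#' @export
generate_fixture <- function(scenario, seed, n_stimuli = NULL) {
  presets <- c("mntb_lso", "fig2_blue", "fig2_orange", "fig2_gray",
               "fig2_yellow", "fig3_low", "fig3_high", "fig3_sites")
  if (!scenario %in% presets)
    stop("unknown preset: ", scenario, " (available: ",
         paste(presets, collapse = ", "), ")", call. = FALSE)

  if (scenario == "mntb_lso") {
    n <- n_stimuli %||% 3000L
    params <- synapse_params(
      M = 100, p1 = 1, pr = 0.93, pu = 0,
      pd = qc_schedule(c(0.92, 0.73, 0.66, 0.53, 0.12), tail = 0.51))
    trace <- simulate_trial(params, n, seed = seed, method = "aggregate")
    trace <- add_quantal_noise(trace, c_mean = 22, cv_q = 0.3,
                               seed = seed + 10000L)
    return(list(trace = trace, params = params, c_mean = 22, cv_q = 0.3))
  }

  n <- n_stimuli %||% 30L
  params <- switch(scenario,
    fig2_blue   = synapse_params(M = 200, pr = 0.15, pd = 0.3),
    fig2_orange = synapse_params(M = 200, pr = 0.15, pd = 0.15),
    fig2_gray   = synapse_params(M = 200, pr = 0.15, pd = 0.05),
    fig2_yellow = synapse_params(M = 200,
                                 pr = qc_schedule(c(0.15, 0.2, 0.25), 0.3),
                                 pd = 0.02),
    fig3_low    = synapse_params(M = 200, pr = 0.15, pd = 0.05),
    fig3_high   = fig3_high_params(n),
    fig3_sites  = synapse_params(M = 33, pr = 0.9, pd = 0.9))
  trace <- simulate_trial(params, n, seed = seed, method = "aggregate")
  list(trace = trace, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# High-release scenario matched in mean depression to the low-probability
# one: solve the occupancy recursion backwards for the refilling schedule
# that makes the normalized mean QC at pr = 0.9 track the pr=0.15/pd=0.05
# occupancy exactly.
fig3_high_params <- function(n) {
  pr_hi <- 0.9
  ref <- occupancy_recursion(synapse_params(M = 200, pr = 0.15, pd = 0.05),
                             n + 1L)$p
  pd_sched <- (ref[-1] - ref[-length(ref)] * (1 - pr_hi)) /
    (1 - ref[-length(ref)] * (1 - pr_hi))
  pd_sched <- pmin(pmax(pd_sched, 0), 1)
  synapse_params(M = 33, pr = pr_hi,
                 pd = qc_schedule(pd_sched, tail = pd_sched[length(pd_sched)]))
}
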