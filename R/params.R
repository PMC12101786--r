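#' Per-stimulus probability schedules
#'
#' A schedule gives the value of a per-stimulus probability (release,
#' refilling or undocking) at every stimulus index `i >= 1`.  It is stored
#' as an explicit prefix of values for the first stimuli followed by a
#' constant tail, matching the way time-varying refilling probabilities are
#' reported for high-frequency trains (a handful of transient values, then a
#' steady value).  A plain numeric scalar is promoted to a constant
#' schedule.
#'
#' @param values Numeric vector of probabilities for stimuli
#'   `1..length(values)`.  May be empty.
#' @param tail Single probability used for every stimulus beyond the prefix.
#'   Defaults to the last element of `values`.
#' @return An object of class `qc_schedule`.
#' @examples
#' qc_schedule(c(0.92, 0.73, 0.66, 0.53, 0.12), tail = 0.51)
#' qc_schedule(0.3)   # constant schedule
#' @export
qc_schedule <- function(values = numeric(0), tail = NULL) {
  if (inherits(values, "qc_schedule")) return(values)
  values <- as.numeric(values)
  if (is.null(tail)) {
    if (length(values) == 0L)
      stop("a schedule needs at least one value or an explicit tail",
           call. = FALSE)
    tail <- values[length(values)]
    values <- values[-length(values)]
  }
  tail <- as.numeric(tail)
  if (length(tail) != 1L || is.na(tail))
    stop("schedule tail must be a single non-missing value", call. = FALSE)
  structure(list(prefix = values, tail = tail), class = "qc_schedule")
}

#' Evaluate a schedule at stimulus indices
#'
#' @param s A `qc_schedule` (or scalar, promoted).
#' @param i Integer vector of 1-based stimulus indices.
#' @return Numeric vector of the same length as `i`.
#' @export
schedule_at <- function(s, i) {
  s <- qc_schedule(s)
  if (any(i < 1L)) stop("stimulus indices are 1-based", call. = FALSE)
  np <- length(s$prefix)
  out <- rep(s$tail, length(i))
  inside <- i <= np
  out[inside] <- s$prefix[i[inside]]
  out
}

#' @export
print.qc_schedule <- function(x, ...) {
  if (length(x$prefix) == 0L) {
    cat("<qc_schedule> constant", format(x$tail), "\n")
  } else {
    cat("<qc_schedule>", paste(format(x$prefix), collapse = ", "),
        "then", format(x$tail), "\n")
  }
  invisible(x)
}

# Validate that every value a schedule can produce is a probability.
# `up_to` bounds the prefix indices that will actually be used.
check_schedule <- function(s, name, up_to = Inf) {
  s <- qc_schedule(s)
  vals <- c(s$prefix, s$tail)
  bad <- which(is.na(vals) | vals < 0 | vals > 1)
  if (length(bad) > 0L) {
    idx <- bad[1]
    lab <- if (idx > length(s$prefix)) "tail" else paste0("index ", idx)
    stop(sprintf("schedule `%s` has invalid probability %s at %s (must be in [0, 1])",
                 name, format(vals[idx]), lab), call. = FALSE)
  }
  s
}

#' Synapse model parameters
#'
#' Bundles the full generative specification of the per-docking-site model:
#' the number of identical, independent docking sites `M`, the probability
#' `p1` that a site is occupied when the first action potential (AP)
#' arrives, and three per-stimulus probability schedules — `pr` (per-docked-
#' vesicle release/fusion probability at AP `i`), `pd` (per-empty-site
#' refilling probability between APs `i` and `i+1`), and `pu` (per-occupied-
#' site undocking probability between APs).
#'
#' @param M Positive integer number of docking sites.
#' @param pr,pd,pu Probability schedules (scalars, numeric vectors promoted
#'   via [qc_schedule()], or `qc_schedule` objects).  `pu` defaults to 0
#'   (no transient undocking).
#' @param p1 Initial per-site occupancy probability; defaults to 1 (a rested
#'   synapse with every docking site filled).
#' @return An object of class `synapse_params`.
#' @examples
#' synapse_params(M = 200, pr = 0.15, pd = 0.05)
#' synapse_params(M = 100, pr = 0.93,
#'                pd = qc_schedule(c(0.92, 0.73, 0.66, 0.53, 0.12), 0.51))
#' @export
synapse_params <- function(M, pr, pd, pu = 0, p1 = 1) {
  if (length(M) != 1L || is.na(M) || M < 1 || M != round(M))
    stop("`M` must be a single positive integer", call. = FALSE)
  if (length(p1) != 1L || is.na(p1) || p1 < 0 || p1 > 1)
    stop("`p1` must be a probability in [0, 1]", call. = FALSE)
  structure(
    list(M  = as.integer(M),
         p1 = as.numeric(p1),
         pr = check_schedule(pr, "pr"),
         pd = check_schedule(pd, "pd"),
         pu = check_schedule(pu, "pu")),
    class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("<synapse_params> M =", x$M, " p1 =", format(x$p1), "\n")
  for (nm in c("pr", "pd", "pu")) {
    cat(" ", nm, ": ")
    print(x[[nm]])
  }
  invisible(x)
}

# TRUE when all three schedules are constant (no prefix).
is_constant_params <- function(params) {
  all(vapply(params[c("pr", "pd", "pu")],
             function(s) length(s$prefix) == 0L, logical(1)))
}

# Constant tail values as a named list; steady-state quantities for
# time-varying schedules are defined on the tails.
tail_probs <- function(params) {
  list(pr = params$pr$tail, pd = params$pd$tail, pu = params$pu$tail)
}
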