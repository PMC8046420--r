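#' Instantaneous system state
#'
#' The full configuration of the lattice at one instant: simulation clock,
#' per-bin occupancy code and the condensin position/direction.  Occupancy
#' codes are 0 (empty), 1 (RNAP / mobile RNAP / bound obstacle) and, in the
#' backtrack model, 2 (backtracked RNAP).
#'
#' @param lattice a [lattice_config()].
#' @param occ optional integer vector of per-bin occupancy codes.
#' @param cond_bin condensin bin (1-based) or `NA` when absent.
#' @param cond_dir `+1` (head-to-tail, 5'->3') or `-1` (head-to-head).
#' @param time simulation clock (s).
#' @return An object of class `system_state`.
#' @examples
#' st <- system_state(lattice_config(), cond_bin = 1, cond_dir = +1)
#' @export
system_state <- function(lattice, occ = NULL, cond_bin = NA_integer_,
                         cond_dir = 1L, time = 0) {
  lattice <- validate_lattice(lattice)
  if (is.null(occ)) occ <- integer(lattice$n_bins)
  occ <- as.integer(occ)
  if (length(occ) != lattice$n_bins)
    stop("system_state: occ must have length n_bins")
  if (any(is.na(occ)) || any(occ < 0L) || any(occ > 2L))
    stop("system_state: occupancy codes must be 0, 1 or 2")
  if (!is.na(cond_bin) &&
      (cond_bin < 1L || cond_bin > lattice$n_bins))
    stop("system_state: condensin bin out of range")
  if (!cond_dir %in% c(-1L, 1L))
    stop("system_state: cond_dir must be +1 or -1")
  st <- list(time = time, occ = occ,
             cond_bin = as.integer(cond_bin),
             cond_dir = as.integer(cond_dir),
             lattice = lattice)
  class(st) <- "system_state"
  st
}

# channels list -> tidy data.frame
channels_df <- function(type, site, rate) {
  data.frame(label = EVENT_LABELS[type], site = as.integer(site),
             propensity = as.numeric(rate), stringsAsFactors = FALSE)
}

#' Draw the next stochastic event (direct-method Gillespie step)
#'
#' Given the current channel list, draws the exponentially distributed
#' waiting time (rate = sum of propensities) and selects one channel with
#' probability proportional to its propensity.  Uses R's global random
#' stream, so `set.seed()` makes draws reproducible.
#'
#' @param channels a data.frame with columns `label`, `site`, `propensity`
#'   (as returned by [simple_events()] and friends).
#' @return A list with elements `channel` (a one-row list with `label`,
#'   `site`, `propensity`, or `NULL` when absorbing), `dt` (waiting time, s;
#'   `Inf` when absorbing) and `absorbing` (logical).  A total propensity of
#'   zero signals an absorbing state and returns no event.
#' @examples
#' set.seed(1)
#' ch <- data.frame(label = "initiate", site = 1L, propensity = 0.05)
#' draw_next_event(ch)
#' @export
draw_next_event <- function(channels) {
  if (is.null(channels) || nrow(channels) == 0L ||
      sum(channels$propensity) <= 0)
    return(list(channel = NULL, dt = Inf, absorbing = TRUE))
  if (any(channels$propensity < 0))
    stop("draw_next_event: negative propensity")
  total <- sum(channels$propensity)
  dt <- rexp(1L, rate = total)
  idx <- if (nrow(channels) == 1L) 1L else
    sample.int(nrow(channels), 1L, prob = channels$propensity)
  list(channel = list(label = channels$label[idx],
                      site = channels$site[idx],
                      propensity = channels$propensity[idx]),
       dt = dt, absorbing = FALSE)
}

#' Event rules for a plan (reference implementation)
#'
#' Returns the pair of functions that define a model for [run_until()]:
#' `events(state)` enumerates the channels of a state and
#' `apply(state, channel)` applies a drawn channel.  This is the plain-R
#' reference implementation of the same rules the compiled engine uses; it
#' is convenient for small lattices, demonstrations and tests.
#'
#' @param plan a validated [simulation_plan()].
#' @return A list with functions `events` and `apply`.
#' @export
model_rules <- function(plan) {
  plan <- validate_plan(plan)
  par <- internal_params(plan)
  list(events = function(state) r_enumerate(par, state),
       apply = function(state, channel) r_apply(par, state, channel))
}

#' Run the stochastic simulation until a stop condition holds
#'
#' Direct-method Gillespie loop around [draw_next_event()]: repeatedly
#' enumerates channels, draws the next event, accumulates the time spent in
#' the current configuration (per-bin condensin residence and RNAP/obstacle
#' occupancy time-integrals) and applies the event.  Stops when
#' `stop_fn(state)` is `TRUE`, when `max_events` events have fired, or when
#' the system is absorbing.
#'
#' This is the reference R engine; the ensemble protocol
#' ([run_ensemble()]) uses the equivalent compiled engine.
#'
#' @param state a [system_state()].
#' @param rules a rule set from [model_rules()] (or any list with `events`
#'   and `apply` functions).
#' @param stop_fn predicate on the state; checked before each event.
#' @param max_events optional cap on the number of events.
#' @return A list with the final `state`, per-bin `residence` (s), per-bin
#'   `occupancy_time` (s), `n_events` and an `absorbing` flag.
#' @examples
#' plan <- simulation_plan("simple", n_events = 1, seed = 1)
#' st <- system_state(plan$lattice, cond_bin = 1, cond_dir = +1)
#' set.seed(1)
#' out <- run_until(st, model_rules(plan),
#'                  stop_fn = function(s) is.na(s$cond_bin))
#' @export
run_until <- function(state, rules, stop_fn, max_events = Inf) {
  stopifnot(inherits(state, "system_state"))
  n <- state$lattice$n_bins
  residence <- numeric(n)
  occupancy_time <- numeric(n)
  n_events <- 0L
  absorbing <- FALSE
  while (!isTRUE(stop_fn(state)) && n_events < max_events) {
    ch <- rules$events(state)
    drawn <- draw_next_event(ch)
    if (drawn$absorbing) { absorbing <- TRUE; break }
    if (!is.na(state$cond_bin))
      residence[state$cond_bin] <- residence[state$cond_bin] + drawn$dt
    occupied <- state$occ != 0L
    occupancy_time[occupied] <- occupancy_time[occupied] + drawn$dt
    state$time <- state$time + drawn$dt
    state <- rules$apply(state, drawn$channel)
    n_events <- n_events + 1L
  }
  list(state = state, residence = residence,
       occupancy_time = occupancy_time, n_events = n_events,
       absorbing = absorbing)
}
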