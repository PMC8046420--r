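# Plain-R reference implementation of the event rules.  These mirror the
# compiled engine exactly (a property test checks the two enumerations agree
# channel-for-channel on randomized states).

r_enumerate <- function(par, state) {
  occ <- state$occ
  n <- par$n_bins
  cond <- if (is.na(state$cond_bin)) 0L else state$cond_bin
  dir <- state$cond_dir
  type <- integer(0); site <- integer(0); rate <- numeric(0)
  add <- function(ty, si, ra) {
    type <<- c(type, ty); site <<- c(site, si); rate <<- c(rate, ra)
  }

  if (par$model %in% c(1L, 2L)) {
    # initiation at the TSS; a condensin on bin 1 is pushed to bin 2
    if (occ[1] == 0L && par$gamma_init > 0) {
      ok <- if (cond == 1L) (n >= 2L && occ[2] == 0L) else TRUE
      if (ok) add(1L, 1L, par$gamma_init)
    }
    for (bin in which(occ != 0L)) {
      s <- occ[bin]
      mobile <- par$model == 1L || s == 1L
      if (mobile && par$v_rnap > 0) {
        ok <- if (bin == n) TRUE
              else if (occ[bin + 1L] != 0L) FALSE
              else if (cond == bin + 1L)
                (bin + 2L > n) || occ[bin + 2L] == 0L
              else TRUE
        if (ok) add(2L, bin, par$v_rnap)
      }
      if (par$model == 1L) {
        if (bin >= par$term_start && par$gamma_term > 0)
          add(3L, bin, par$gamma_term)
      } else if (s == 1L) {
        if (par$kback[bin] > 0) add(4L, bin, par$kback[bin])
        if (par$mobile_term && bin >= par$term_start && par$gamma_term > 0)
          add(3L, bin, par$gamma_term)
      } else {
        if (par$k_on > 0) add(5L, bin, par$k_on)
        if (bin >= par$term_start && par$gamma_term > 0)
          add(3L, bin, par$gamma_term)
      }
    }
  } else {
    for (bin in seq_len(n)) {
      if (occ[bin] == 0L) {
        if (par$kbind[bin] > 0) add(6L, bin, par$kbind[bin])
      } else if (par$k_off > 0) add(7L, bin, par$k_off)
    }
  }

  if (cond > 0L && par$v_c > 0) {
    j <- cond + dir
    if (j < 1L || j > n) add(8L, cond, par$v_c)
    else if (occ[j] == 0L) add(8L, cond, par$v_c)
    else {
      r <- if (par$model == 2L) {
        if (occ[j] == 1L) par$v_jump_m else par$v_jump_b
      } else par$v_jump
      if (r > 0) add(9L, cond, r)
    }
  }
  channels_df(type, site, rate)
}

r_apply <- function(par, state, channel) {
  n <- par$n_bins
  occ <- state$occ
  cond <- if (is.na(state$cond_bin)) 0L else state$cond_bin
  dir <- state$cond_dir
  lab <- channel$label
  i <- channel$site

  check <- function(cond_ok) {
    if (!cond_ok)
      stop("stale event '", lab, "' at bin ", i,
           ": preconditions no longer hold")
  }
  switch(lab,
    initiate = {
      check(occ[1] == 0L && (cond != 1L || (n >= 2L && occ[2] == 0L)))
      if (cond == 1L) cond <- 2L
      occ[1] <- 1L
    },
    rnap_step = {
      check(occ[i] != 0L && (par$model == 1L || occ[i] == 1L))
      s <- occ[i]
      occ[i] <- 0L
      if (i < n) {
        check(occ[i + 1L] == 0L)
        if (cond == i + 1L) {
          check(i + 2L > n || occ[i + 2L] == 0L)
          cond <- if (i + 2L > n) 0L else i + 2L # pushed off => exit
        }
        occ[i + 1L] <- s
      }
    },
    rnap_terminate = { check(occ[i] != 0L); occ[i] <- 0L },
    switch_to_backtracked = { check(occ[i] == 1L); occ[i] <- 2L },
    switch_to_mobile = { check(occ[i] == 2L); occ[i] <- 1L },
    obstacle_bind = { check(occ[i] == 0L); occ[i] <- 1L },
    obstacle_unbind = { check(occ[i] == 1L); occ[i] <- 0L },
    condensin_step = {
      check(cond == i)
      j <- cond + dir
      cond <- if (j < 1L || j > n) 0L else { check(occ[j] == 0L); j }
    },
    condensin_bypass = {
      check(cond == i)
      j <- cond + dir
      check(j >= 1L && j <= n && occ[j] != 0L)
      if (par$model == 3L) {
        cond <- j
      } else if (isTRUE(par$hop_over)) {
        f <- j
        while (f >= 1L && f <= n && occ[f] != 0L) f <- f + dir
        cond <- if (f < 1L || f > n) 0L else f
      } else {
        occ[cond] <- occ[j]; occ[j] <- 0L
        cond <- j
      }
    },
    stop("unknown event label '", lab, "'"))

  state$occ <- occ
  state$cond_bin <- if (cond == 0L) NA_integer_ else cond
  state
}

state_par <- function(params, lattice, model) {
  plan <- list(model = model, rates = params, lattice = lattice,
               n_events = 1L, burn_in_time = 0, decorrelation_time = 0,
               directions = "head_to_tail", seed = 0L)
  class(plan) <- "simulation_plan"
  internal_params(validate_plan(plan))
}

#' Event channels of the simple (TASEP) model
#'
#' Enumerates every stochastic event available to a state under the simple
#' model: RNAP initiation at bin 1 (excluded by a resident RNAP), RNAP hops
#' under mutual exclusion (including hops that push the condensin toward 3',
#' suppressed when the condensin cannot be displaced), RNAP unbinding in the
#' termination zone, and the condensin's hop -- at `v_c` into an RNAP-free
#' bin or at the bypass rate `v_jump` past a blocking RNAP.
#'
#' @param state a [system_state()].
#' @param params a [simple_rates()] object.
#' @param lattice a [lattice_config()].
#' @return A data.frame of channels (`label`, `site`, `propensity`); an
#'   empty data.frame is legal and signals an absorbing state.
#' @examples
#' simple_events(system_state(lattice_config()), simple_rates(),
#'               lattice_config())
#' @export
simple_events <- function(state, params, lattice) {
  r_enumerate(state_par(params, lattice, "simple"), state)
}

#' @rdname simple_events
#' @param channel a channel drawn from the same state (a one-row list with
#'   `label` and `site`).  Applying a channel whose preconditions no longer
#'   hold is a programming error and fails loudly.
#' @export
apply_simple_event <- function(state, channel, params, lattice) {
  r_apply(state_par(params, lattice, "simple"), state, channel)
}

#' Event channels of the backtrack (TASEP-with-pauses) model
#'
#' As [simple_events()], with RNAPs split between a mobile state (which
#' hops, pushes the condensin and switches to backtracked at the per-bin
#' rate `kback[i]`) and a backtracked state (immobile; recovers at `k_on`
#' and unbinds at `gamma_term` inside the termination zone).  The condensin
#' bypass rate depends on the blocking RNAP's state (`v_jump_m` vs
#' `v_jump_b`; a rate of zero emits no channel, so the condensin waits).
#'
#' @inheritParams simple_events
#' @param params a [backtrack_rates()] object.
#' @export
backtrack_events <- function(state, params, lattice) {
  r_enumerate(state_par(params, lattice, "backtrack"), state)
}

#' @rdname backtrack_events
#' @param channel a channel drawn from the same state.
#' @export
apply_backtrack_event <- function(state, channel, params, lattice) {
  r_apply(state_par(params, lattice, "backtrack"), state, channel)
}

#' Event channels of the immobile-obstacle model
#'
#' Obstacles bind empty bins at `k_bind(i) = k_off * occ(i) / (1 - occ(i))`
#' (so each isolated bin relaxes to the target stationary occupancy
#' `occ(i)`) and unbind at `k_off`, independently of the condensin.  The
#' condensin hops at `v_c` toward an obstacle-free bin and enters an
#' obstacle-occupied bin at `v_slow`; obstacles are neither pushed nor
#' displaced.
#'
#' @inheritParams simple_events
#' @param params an [obstacle_rates()] object.
#' @export
obstacle_events <- function(state, params, lattice) {
  r_enumerate(state_par(params, lattice, "obstacle"), state)
}

#' @rdname obstacle_events
#' @param channel a channel drawn from the same state.
#' @export
apply_obstacle_event <- function(state, channel, params, lattice) {
  r_apply(state_par(params, lattice, "obstacle"), state, channel)
}
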