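# Two-stage protocol: RNAP-only burn-in, then an ensemble of independent
# single-condensin traversals.

occupancy_profile <- function(total, bstate, lattice, sampled_time,
                              blocks = NULL) {
  df <- bin_coords(lattice)
  df$occupancy <- as.numeric(total)
  df$occupancy_b <- as.numeric(bstate)
  attr(df, "sampled_time") <- sampled_time
  attr(df, "blocks") <- blocks
  class(df) <- c("occupancy_profile", "data.frame")
  df
}

residence_profile <- function(mean, sem, n_events, direction, lattice) {
  df <- bin_coords(lattice)
  df$mean <- as.numeric(mean)
  df$sem <- as.numeric(sem)
  df$n_events <- as.integer(n_events)
  attr(df, "direction") <- direction
  class(df) <- c("residence_profile", "data.frame")
  df
}

#' Stage 1: RNAP-only burn-in to transcriptional steady state
#'
#' Simulates the RNAP (or obstacle) dynamics alone, without any condensin,
#' for `plan$burn_in_time` seconds starting from an empty lattice.  The
#' stationary occupancy profile is estimated from the second half of the
#' burn-in only; the first half is discarded as the transient.  As a
#' convergence diagnostic, the first- and second-half occupancies are
#' compared and a warning is raised when any bin differs by more than 5%
#' absolute.
#'
#' The burn-in seeds R's RNG from `plan$seed`, so it is reproducible on its
#' own; [run_ensemble()] calls it the same way.
#'
#' @param plan a validated [simulation_plan()].
#' @param n_blocks number of equal time blocks used to accumulate the
#'   occupancy time-integrals (block-wise occupancies are retained for
#'   uncertainty estimates).
#' @return A list with `occupancy` (an `occupancy_profile` data.frame:
#'   `bin`, `start_bp`, `end_bp`, `occupancy`, `occupancy_b`), `state` (the
#'   final per-bin occupancy codes), `converged` and `max_half_diff`.
#' @examples
#' plan <- simulation_plan("simple", n_events = 10, burn_in_time = 200,
#'                         seed = 1)
#' bi <- burn_in(plan)
#' @export
burn_in <- function(plan, n_blocks = 10L) {
  plan <- validate_plan(plan)
  par <- internal_params(plan)
  n <- plan$lattice$n_bins
  n_blocks <- max(2L, as.integer(n_blocks))
  if (n_blocks %% 2L == 1L) n_blocks <- n_blocks + 1L

  if (plan$burn_in_time <= 0) {
    return(list(occupancy = occupancy_profile(numeric(n), numeric(n),
                                              plan$lattice, 0),
                state = integer(n), converged = TRUE, max_half_diff = 0))
  }
  set.seed(plan$seed)
  out <- cpp_run(par, integer(n), 0L, 1L, plan$burn_in_time,
                 FALSE, -1, n_blocks, FALSE, FALSE)
  block_len <- plan$burn_in_time / n_blocks
  total_b <- out$occ_blocks / block_len   # per-block occupancy probabilities
  bst_b <- out$occb_blocks / block_len
  half <- n_blocks / 2L
  first <- colMeans(total_b[seq_len(half), , drop = FALSE])
  second_rows <- seq(half + 1L, n_blocks)
  second <- colMeans(total_b[second_rows, , drop = FALSE])
  second_b <- colMeans(bst_b[second_rows, , drop = FALSE])
  max_half_diff <- max(abs(first - second))
  converged <- max_half_diff <= 0.05
  if (!converged)
    warning(sprintf(paste0("burn_in: occupancy differs by %.3f (absolute) ",
                           "between burn-in halves; increase burn_in_time"),
                    max_half_diff))
  list(occupancy = occupancy_profile(second, second_b, plan$lattice,
                                     sampled_time = plan$burn_in_time / 2,
                                     blocks = list(
                                       total = total_b[second_rows, ,
                                                       drop = FALSE],
                                       bstate = bst_b[second_rows, ,
                                                      drop = FALSE])),
       state = out$occ, converged = converged,
       max_half_diff = max_half_diff)
}

#' Stage 2: one condensin traversal
#'
#' Introduces a single condensin at the entry bin (bin 1 for head-to-tail,
#' the last bin for head-to-head) into an equilibrated lattice and simulates
#' the full system until the condensin exits the far boundary, recording the
#' time it spends at each bin.  If the entry bin is occupied, the lattice
#' dynamics is continued without the condensin until the bin frees, and the
#' condensin is inserted then (the waiting time is reported but not counted
#' as residence).
#'
#' The caller controls the RNG state (`set.seed()`); [run_ensemble()] seeds
#' each traversal from the plan seed.
#'
#' @param state per-bin occupancy codes from [burn_in()] (or a
#'   [system_state()]).
#' @param direction `"head_to_tail"` or `"head_to_head"`.
#' @param plan a validated [simulation_plan()].
#' @return A list with `residence` (per-bin time, s; sums exactly to
#'   `duration`), `duration` (traversal time, s), `wait_time` (s) and
#'   `state` (final occupancy codes, for continuing the lattice dynamics).
#' @export
run_traversal <- function(state, direction = DIRECTIONS, plan) {
  direction <- match.arg(direction)
  plan <- validate_plan(plan)
  if (inherits(state, "system_state")) state <- state$occ
  par <- internal_params(plan)
  n <- plan$lattice$n_bins
  if (length(state) != n) stop("run_traversal: state must have length n_bins")
  entry <- if (direction == "head_to_tail") 1L else n
  dirsign <- if (direction == "head_to_tail") 1L else -1L
  out <- cpp_run(par, as.integer(state), entry, dirsign, Inf, TRUE, -1, 0L,
                 FALSE, TRUE)
  if (out$absorbing)
    stop("run_traversal: absorbing state reached before the condensin",
         " could exit")
  list(residence = out$residence,
       duration = sum(out$residence),
       wait_time = out$wait_time,
       state = out$occ)
}

#' Run the full two-stage ensemble protocol
#'
#' Executes the complete protocol of the model study: a single RNAP-only
#' burn-in ([burn_in()]), then `n_events` independent condensin traversals
#' per requested direction ([run_traversal()]).  Between consecutive
#' traversals the RNAP/obstacle field is propagated alone for
#' `decorrelation_time` seconds so ensemble members are effectively
#' independent draws from the stationary law.  Traversal `k` of direction
#' `d` reseeds the RNG at `(2^21 * (seed + 1) + (d-1) * n_events + k)
#' mod (2^31 - 1)`: the whole ensemble is bit-reproducible under a fixed
#' plan, and the `2^21` spacing keeps the member seeds of ensembles with
#' different base seeds disjoint (plain `seed + k` schemes make two runs
#' with nearby seeds share almost all of their random streams).
#'
#' @param plan a validated [simulation_plan()].
#' @param keep_events keep the per-event residence matrices (needed for
#'   bootstrap statistics; about `8 * n_events * n_bins` bytes per
#'   direction).
#' @return An object of class `condensin_ensemble`: a list with `plan`,
#'   `occupancy` (stage-1 profile, never contaminated by the condensin),
#'   `burn_in` diagnostics, `residence` (named list of `residence_profile`
#'   data.frames per direction), `residence_avg` (unweighted mean of the two
#'   directional mean profiles, when both were run) and, if requested,
#'   `events` (per-direction matrices of per-event residence vectors).
#' @examples
#' plan <- simulation_plan("simple", n_events = 50, burn_in_time = 200,
#'                         seed = 1)
#' ens <- run_ensemble(plan)
#' @export
run_ensemble <- function(plan, keep_events = TRUE) {
  plan <- validate_plan(plan)
  if (plan$n_events < 100L)
    warning("run_ensemble: n_events < 100; standard errors are unreliable")
  par <- internal_params(plan)
  n <- plan$lattice$n_bins

  bi <- burn_in(plan)
  state <- bi$state

  residence <- list()
  events <- list()
  for (d_idx in seq_along(plan$directions)) {
    direction <- plan$directions[d_idx]
    ev <- matrix(0, nrow = plan$n_events, ncol = n)
    for (k in seq_len(plan$n_events)) {
      seed_k <- (2097152 * (plan$seed + 1) +
                 (d_idx - 1) * plan$n_events + k) %% 2147483647
      set.seed(seed_k)
      if (plan$decorrelation_time > 0) {
        adv <- cpp_run(par, state, 0L, 1L, plan$decorrelation_time, FALSE,
                       -1, 0L, FALSE, FALSE)
        state <- adv$occ
      }
      tr <- run_traversal(state, direction, plan)
      ev[k, ] <- tr$residence
      state <- tr$state
    }
    m <- colMeans(ev)
    sem <- apply(ev, 2L, sd) / sqrt(plan$n_events)
    residence[[direction]] <- residence_profile(m, sem, plan$n_events,
                                                direction, plan$lattice)
    if (keep_events) events[[direction]] <- ev
  }

  residence_avg <- NULL
  if (length(residence) == 2L) {
    m <- (residence[[1]]$mean + residence[[2]]$mean) / 2
    sem <- sqrt(residence[[1]]$sem^2 + residence[[2]]$sem^2) / 2
    residence_avg <- residence_profile(m, sem, plan$n_events, "average",
                                       plan$lattice)
  }

  out <- list(plan = plan, occupancy = bi$occupancy,
              burn_in = list(converged = bi$converged,
                             max_half_diff = bi$max_half_diff),
              residence = residence, residence_avg = residence_avg)
  if (keep_events) out$events <- events
  class(out) <- "condensin_ensemble"
  out
}

#' @export
print.condensin_ensemble <- function(x, ...) {
  cat(sprintf("<condensin_ensemble> model = %s, n_events = %d, seed = %d\n",
              x$plan$model, x$plan$n_events, x$plan$seed))
  for (d in names(x$residence)) {
    r <- x$residence[[d]]
    cat(sprintf("  %s: mean transit %.3f s, peak bin %d (%.4f s)\n",
                d, sum(r$mean), which.max(r$mean), max(r$mean)))
  }
  if (!is.null(x$occupancy)) {
    lat <- x$plan$lattice
    body <- seq(lat$gene_start_bin + 1L, lat$gene_end_bin - 1L)
    cat(sprintf("  gene-body RNAP occupancy: %.4f\n",
                mean(x$occupancy$occupancy[body])))
  }
  invisible(x)
}
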