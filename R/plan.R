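#' Assemble a simulation plan
#'
#' A plan bundles everything needed to reproduce a run: the model, its
#' kinetic parameters, the lattice geometry, the ensemble size, the two-stage
#' protocol settings and the random seed.
#'
#' @param model `"simple"`, `"backtrack"` or `"obstacle"`.
#' @param rates a matching [rate_params][simple_rates()] object; defaults to
#'   the model's default rates.
#' @param lattice a [lattice_config()].
#' @param n_events number of condensin traversals per direction (ensemble
#'   size).  The reference protocol uses 1e5; the desk-scale default is 1e4.
#' @param burn_in_time stage-1 RNAP-only equilibration time (s).
#' @param decorrelation_time RNAP-only time simulated between consecutive
#'   traversals so that ensemble members are effectively independent (s).
#' @param directions character subset of `c("head_to_tail", "head_to_head")`.
#'   Head-to-tail condensin enters at bin 1 and travels 5'->3'; head-to-head
#'   enters at the last bin and travels 3'->5'.
#' @param seed integer base seed; traversal `k` of direction `d` uses a seed
#'   derived from it, so a fixed seed makes the whole run reproducible.
#' @return An object of class `simulation_plan`.
#' @examples
#' plan <- simulation_plan("simple", n_events = 100, seed = 1)
#' @export
simulation_plan <- function(model = c("simple", "backtrack", "obstacle"),
                            rates = NULL, lattice = lattice_config(),
                            n_events = 10000L, burn_in_time = 2000,
                            decorrelation_time = 100,
                            directions = c("head_to_tail", "head_to_head"),
                            seed = 1L) {
  model <- match.arg(model)
  if (is.null(rates)) {
    rates <- switch(model,
                    simple = simple_rates(),
                    backtrack = backtrack_rates(),
                    obstacle = obstacle_rates())
  }
  plan <- list(model = model, rates = rates, lattice = lattice,
               n_events = as.integer(n_events),
               burn_in_time = as.numeric(burn_in_time),
               decorrelation_time = as.numeric(decorrelation_time),
               directions = directions, seed = as.integer(seed))
  class(plan) <- "simulation_plan"
  validate_plan(plan)
}

#' Validate a simulation plan
#'
#' Checks every invariant of the plan (lattice geometry, rate signs and
#' orderings, ensemble size, directions, seed) and fails with a message
#' naming the violated field.  Unit conversions (bp/s to bins/s) are applied
#' downstream by the engine, not stored in the plan, so a validated plan
#' still carries the user-facing units.
#'
#' @param plan a [simulation_plan()].
#' @return The validated plan, invisibly identical to its input.
#' @export
validate_plan <- function(plan) {
  if (!inherits(plan, "simulation_plan"))
    stop("validate_plan: not a simulation_plan")
  if (!plan$model %in% c("simple", "backtrack", "obstacle"))
    stop("validate_plan: unknown model '", plan$model, "'")
  expected <- switch(plan$model, simple = "simple_rates",
                     backtrack = "backtrack_rates",
                     obstacle = "obstacle_rates")
  if (!inherits(plan$rates, expected))
    stop("validate_plan: model '", plan$model, "' requires ", expected,
         ", got ", class(plan$rates)[1])
  validate_lattice(plan$lattice)
  validate_rates(plan$rates)
  if (is.na(plan$n_events) || plan$n_events < 1L)
    stop("validate_plan: n_events must be >= 1")
  if (is.na(plan$burn_in_time) || plan$burn_in_time < 0)
    stop("validate_plan: burn_in_time must be >= 0")
  if (is.na(plan$decorrelation_time) || plan$decorrelation_time < 0)
    stop("validate_plan: decorrelation_time must be >= 0")
  if (length(plan$directions) < 1L ||
      !all(plan$directions %in% DIRECTIONS))
    stop("validate_plan: directions must be a non-empty subset of ",
         paste(DIRECTIONS, collapse = ", "))
  if (is.na(plan$seed))
    stop("validate_plan: seed must be an integer")
  if (plan$model == "obstacle")
    resolve_occupancy(plan$rates, plan$lattice)
  plan
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat(sprintf("<simulation_plan> model = %s, n_events = %d, seed = %d\n",
              x$model, x$n_events, x$seed))
  cat(sprintf("  burn-in %g s, decorrelation %g s, directions: %s\n",
              x$burn_in_time, x$decorrelation_time,
              paste(x$directions, collapse = ", ")))
  print(x$lattice)
  invisible(x)
}

# ---- internal engine parameters (rates in bins/s, flat list for C++) -------

internal_params <- function(plan) {
  lat <- plan$lattice
  r <- plan$rates
  w <- lat$bin_size_bp
  p <- list(model = switch(plan$model, simple = 1L, backtrack = 2L,
                           obstacle = 3L),
            n_bins = lat$n_bins, term_start = lat$term_zone_start_bin,
            gamma_init = 0, gamma_term = 0, v_rnap = 0, v_c = 0, v_jump = 0,
            k_on = 0, v_jump_m = 0, v_jump_b = 0, k_off = 0,
            mobile_term = FALSE,
            hop_over = identical(r$bypass_mode, "hop_over"),
            kback = numeric(lat$n_bins), kbind = numeric(lat$n_bins))
  if (plan$model == "simple") {
    p$gamma_init <- r$gamma_init
    p$gamma_term <- r$gamma_term
    p$v_rnap <- r$v_rnap / w
    p$v_c <- r$v_c / w
    p$v_jump <- r$v_jump / w
  } else if (plan$model == "backtrack") {
    p$gamma_init <- r$gamma_init
    p$gamma_term <- r$gamma_term
    p$v_rnap <- r$v_rnap / w
    p$v_c <- r$v_c / w
    p$k_on <- r$k_on
    p$v_jump_m <- r$v_jump_m / w
    p$v_jump_b <- r$v_jump_b / w
    p$mobile_term <- isTRUE(r$mobile_unbind)
    p$kback <- if (r$k_back_min > 0) build_kback_profile(r, lat)
               else numeric(lat$n_bins)
  } else {
    occ <- resolve_occupancy(r, lat)
    p$v_c <- r$v_c / w
    p$v_jump <- r$v_slow / w
    p$k_off <- r$k_off
    p$kbind <- r$k_off * occ / (1 - occ)
  }
  p
}

# ---- presets ---------------------------------------------------------------

#' Named parameter presets for the backtrack model
#'
#' Fully populated plans for the wild-type-like and tfs1DN-like situations
#' and the supplementary parameter variants:
#' \describe{
#'   \item{wt}{k_on = 0.2/s, k_back_min = 0.002/s ("slow" switching),
#'     gamma_term = 0.2/s, v_jump_m = 15 bp/s, v_jump_b = 0.}
#'   \item{tfs1dn}{as `wt` but k_on = 0.02/s (10-fold longer backtracked
#'     dwell time, mimicking dominant-negative TFIIS).}
#'   \item{s4-slow}{as `wt` with gamma_term = 0.4/s.}
#'   \item{s4-fast}{"fast" switching: k_back_min = 0.1/s with k_on scaled by
#'     the same 50-fold factor (k_on = 10/s) so the stationary backtracked
#'     fraction matches the slow regime; gamma_term = 0.4/s.}
#'   \item{s4-vjumpb10}{as `wt` but with a partial bypass of backtracked
#'     RNAPs, v_jump_b = 10 bp/s.}
#'   \item{s4-lowinit}{as `wt` with gamma_init = 0.025 RNAP/s.}
#' }
#'
#' @param name preset name (see above).
#' @param ... overrides passed to [simulation_plan()] (`n_events`, `seed`,
#'   `burn_in_time`, ...).
#' @return A validated [simulation_plan()].
#' @examples
#' plan_preset("wt", n_events = 500, seed = 3)
#' @export
plan_preset <- function(name = c("wt", "tfs1dn", "s4-slow", "s4-fast",
                                 "s4-vjumpb10", "s4-lowinit"), ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("wt", "tfs1dn", "s4-slow", "s4-fast", "s4-vjumpb10",
                   "s4-lowinit"))
    stop("unknown preset '", paste(name, collapse = ","), "'")
  rates <- switch(name,
    "wt" = backtrack_rates(),
    "tfs1dn" = backtrack_rates(k_on = 0.02),
    "s4-slow" = backtrack_rates(gamma_term = 0.4),
    "s4-fast" = backtrack_rates(gamma_term = 0.4, k_back_min = 0.1,
                                k_on = 10),
    "s4-vjumpb10" = backtrack_rates(v_jump_b = 10),
    "s4-lowinit" = backtrack_rates(gamma_init = 0.025))
  simulation_plan("backtrack", rates = rates, ...)
}

#' @rdname plan_preset
#' @export
make_wt_plan <- function(...) plan_preset("wt", ...)

#' @rdname plan_preset
#' @export
make_tfs1dn_plan <- function(...) plan_preset("tfs1dn", ...)

# ---- flat-file serialization ----------------------------------------------

PLAN_SCALAR_KEYS <- c("model", "n_events", "burn_in_time",
                      "decorrelation_time", "directions", "seed")
LATTICE_KEYS <- c("n_bins", "bin_size_bp", "gene_start_bin", "gene_end_bin",
                  "term_zone_start_bin", "term_zone_end_bin")
RATE_KEYS <- list(
  simple = c("gamma_init", "gamma_term", "v_rnap", "v_c", "v_jump",
             "bypass_mode"),
  backtrack = c("gamma_init", "gamma_term", "v_rnap", "v_c", "k_on",
                "k_back_min", "k_back_fold", "v_jump_m", "v_jump_b",
                "mobile_unbind", "bypass_mode"),
  obstacle = c("v_c", "v_slow", "k_off", "occupancy"))

#' Write / read a simulation plan as a flat key-value file
#'
#' Plans are serialized as a flat YAML mapping with one documented schema:
#' the scalar keys `model`, `n_events`, `burn_in_time`,
#' `decorrelation_time`, `directions` (comma-separated), `seed`; the lattice
#' keys `lattice.<field>`; and the model's rate keys `rates.<field>`
#' (obstacle occupancy is written as a comma-separated numeric list or a toy
#' profile name).  Unknown keys are an error on read; a written plan reads
#' back identical.
#'
#' @param plan a validated [simulation_plan()].
#' @param path file path.
#' @return `write_plan` returns `path` invisibly; `read_plan` returns the
#'   parsed, validated plan.
#' @examples
#' p <- simulation_plan("backtrack", n_events = 10, seed = 2)
#' f <- tempfile(fileext = ".yaml")
#' write_plan(p, f)
#' identical_plan <- read_plan(f)
#' @export
write_plan <- function(plan, path) {
  plan <- validate_plan(plan)
  kv <- list(model = plan$model, n_events = plan$n_events,
             burn_in_time = plan$burn_in_time,
             decorrelation_time = plan$decorrelation_time,
             directions = paste(plan$directions, collapse = ","),
             seed = plan$seed)
  for (k in LATTICE_KEYS) kv[[paste0("lattice.", k)]] <- plan$lattice[[k]]
  for (k in RATE_KEYS[[plan$model]]) {
    v <- plan$rates[[k]]
    if (k == "occupancy" && is.numeric(v))
      v <- paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                 collapse = ",")
    kv[[paste0("rates.", k)]] <- v
  }
  yaml::write_yaml(kv, path, precision = 15)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  kv <- yaml::read_yaml(path)
  kv <- kv[!startsWith(names(kv), "manifest.")] # provenance keys, not config
  model <- kv[["model"]]
  if (is.null(model) || !model %in% c("simple", "backtrack", "obstacle"))
    stop("read_plan: missing or unknown model")
  allowed <- c(PLAN_SCALAR_KEYS, paste0("lattice.", LATTICE_KEYS),
               paste0("rates.", RATE_KEYS[[model]]))
  unknown <- setdiff(names(kv), allowed)
  if (length(unknown))
    stop("read_plan: unknown key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(allowed, names(kv))
  if (length(missing))
    stop("read_plan: missing key(s): ", paste(missing, collapse = ", "))

  lat_args <- lapply(setNames(LATTICE_KEYS, LATTICE_KEYS),
                     function(k) kv[[paste0("lattice.", k)]])
  rate_args <- lapply(setNames(RATE_KEYS[[model]], RATE_KEYS[[model]]),
                      function(k) kv[[paste0("rates.", k)]])
  if (model == "obstacle" && is.character(rate_args$occupancy) &&
      grepl(",", rate_args$occupancy))
    rate_args$occupancy <-
      as.numeric(strsplit(rate_args$occupancy, ",")[[1]])
  rates <- switch(model,
                  simple = do.call(simple_rates, rate_args),
                  backtrack = do.call(backtrack_rates, rate_args),
                  obstacle = do.call(obstacle_rates, rate_args))
  simulation_plan(model, rates = rates,
                  lattice = do.call(lattice_config, lat_args),
                  n_events = kv[["n_events"]],
                  burn_in_time = kv[["burn_in_time"]],
                  decorrelation_time = kv[["decorrelation_time"]],
                  directions = strsplit(kv[["directions"]], ",")[[1]],
                  seed = kv[["seed"]])
}
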