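#' Kinetic parameters of the simple (TASEP) model
#'
#' Rates of the simple model: RNAPs bind the TSS (bin 1) at `gamma_init`,
#' hop 5'->3' at speed `v_rnap` under mutual exclusion, and unbind at
#' `gamma_term` anywhere in the termination zone.  A single condensin hops at
#' `v_c` into RNAP-free bins and at the reduced bypass rate `v_jump` past a
#' blocking RNAP; moving RNAPs can push the condensin one bin toward 3'.
#'
#' Speeds are given in bp/s and converted to bins/s internally (40 bp/s on a
#' 100-bp lattice is 0.4 bins/s).
#'
#' @param gamma_init initiation rate (RNAP/s).
#' @param gamma_term termination-zone unbinding rate (1/s).
#' @param v_rnap RNAP elongation speed (bp/s).
#' @param v_c condensin translocation speed (bp/s).
#' @param v_jump condensin bypass rate past an RNAP (bp/s); must be <= `v_c`.
#' @param bypass_mode how a bypass resolves: `"exchange"` (the condensin and
#'   the single blocking RNAP swap positions, the default) or `"hop_over"`
#'   (the condensin lands on the first free bin beyond the contiguous RNAP
#'   block; kept as a switch for sensitivity analysis).
#' @return An object of class `c("simple_rates", "rate_params")`.
#' @examples
#' simple_rates()          # defaults: 0.05 RNAP/s, 0.4/s, 40 bp/s, 1 kbp/s
#' simple_rates(v_jump = 15)
#' @export
simple_rates <- function(gamma_init = 0.05, gamma_term = 0.4,
                         v_rnap = 40, v_c = 1000, v_jump = 1,
                         bypass_mode = c("exchange", "hop_over")) {
  r <- list(gamma_init = gamma_init, gamma_term = gamma_term,
            v_rnap = v_rnap, v_c = v_c, v_jump = v_jump,
            bypass_mode = match.arg(bypass_mode))
  class(r) <- c("simple_rates", "rate_params")
  validate_rates(r)
}

#' Kinetic parameters of the backtrack (TASEP-with-pauses) model
#'
#' As [simple_rates()], but each RNAP switches between a mobile, elongating
#' state (mRNAP) and a backtracked, immobile state (bRNAP).  Only mRNAPs hop
#' (and push the condensin); only bRNAPs unbind in the termination zone.  The
#' mobile-to-backtracked rate is position dependent: `k_back_min` in the gene
#' body and `k_back_fold * k_back_min` in the termination zone (see
#' [build_kback_profile()]).  bRNAPs recover mobility at the homogeneous rate
#' `k_on`.  The condensin bypass rate depends on the state of the blocking
#' RNAP: `v_jump_m` for a mobile one, `v_jump_b` for a backtracked one
#' (0 means the condensin must wait).
#'
#' @param gamma_init,gamma_term,v_rnap,v_c as in [simple_rates()]
#'   (`gamma_term` defaults to 0.2/s in this model).
#' @param k_on backtracked-to-mobile recovery rate (1/s).
#' @param k_back_min gene-body backtracking rate (1/s).
#' @param k_back_fold fold increase of the backtracking rate in the
#'   termination zone (dimensionless, >= 1; default 200).
#' @param v_jump_m bypass rate past a mobile RNAP (bp/s).
#' @param v_jump_b bypass rate past a backtracked RNAP (bp/s); must satisfy
#'   `v_jump_b <= v_jump_m <= v_c`.
#' @param mobile_unbind if `TRUE`, mobile RNAPs may also unbind in the
#'   termination zone.  This is a model-reduction switch: with
#'   `k_back_min = 0`, `k_back_fold = 1` and `mobile_unbind = TRUE` the model
#'   collapses exactly onto the simple model.
#' @param bypass_mode as in [simple_rates()]; under `"hop_over"` the bypass
#'   rate is set by the state of the first blocking RNAP.
#' @return An object of class `c("backtrack_rates", "rate_params")`.
#' @examples
#' backtrack_rates()                 # wild-type-like defaults
#' backtrack_rates(k_on = 0.02)      # tfs1DN-like: 10x longer backtracks
#' @export
backtrack_rates <- function(gamma_init = 0.05, gamma_term = 0.2,
                            v_rnap = 40, v_c = 1000,
                            k_on = 0.2, k_back_min = 0.002,
                            k_back_fold = 200,
                            v_jump_m = 15, v_jump_b = 0,
                            mobile_unbind = FALSE,
                            bypass_mode = c("exchange", "hop_over")) {
  r <- list(gamma_init = gamma_init, gamma_term = gamma_term,
            v_rnap = v_rnap, v_c = v_c, k_on = k_on,
            k_back_min = k_back_min, k_back_fold = k_back_fold,
            v_jump_m = v_jump_m, v_jump_b = v_jump_b,
            mobile_unbind = isTRUE(mobile_unbind),
            bypass_mode = match.arg(bypass_mode))
  class(r) <- c("backtrack_rates", "rate_params")
  validate_rates(r)
}

#' Kinetic parameters of the immobile-obstacle model
#'
#' Obstacles bind and unbind chromatin independently at each bin; the
#' condensin hops at `v_c` into obstacle-free bins and enters an
#' obstacle-occupied bin at the strongly reduced rate `v_slow`.  Obstacles
#' are neither pushed nor displaced.  The per-bin binding rate is derived
#' from a target stationary occupancy profile by detailed balance:
#' `k_bind(i) = k_off * occ(i) / (1 - occ(i))`.
#'
#' @param v_c condensin speed (bp/s; default 1 kbp/s).
#' @param v_slow slowed condensin rate next to an obstacle (bp/s; default
#'   10 bp/s).
#' @param k_off obstacle unbinding rate (1/s; default 1/60, i.e. a 1-min
#'   mean bound lifetime).
#' @param occupancy per-bin target stationary occupancy, each in `[0, 1)`;
#'   either a numeric vector (length `n_bins`) or the name of a built-in toy
#'   profile, see [toy_occupancy()].
#' @return An object of class `c("obstacle_rates", "rate_params")`.
#' @examples
#' obstacle_rates(occupancy = "plateau")
#' @export
obstacle_rates <- function(v_c = 1000, v_slow = 10, k_off = 1 / 60,
                           occupancy = "plateau") {
  r <- list(v_c = v_c, v_slow = v_slow, k_off = k_off,
            occupancy = occupancy)
  class(r) <- c("obstacle_rates", "rate_params")
  validate_rates(r)
}

validate_rates <- function(r) {
  num_fields <- names(r)[vapply(r, is.numeric, logical(1))]
  for (f in setdiff(num_fields, "occupancy")) {
    v <- r[[f]]
    if (length(v) != 1L || is.na(v) || v < 0)
      stop("rate_params: field '", f, "' must be a single non-negative number")
  }
  if (inherits(r, "simple_rates") && r$v_jump > r$v_c)
    stop("rate_params: v_jump must be <= v_c (", r$v_jump, " > ", r$v_c, ")")
  if (inherits(r, "backtrack_rates")) {
    if (!(r$v_jump_b <= r$v_jump_m && r$v_jump_m <= r$v_c))
      stop("rate_params: need v_jump_b <= v_jump_m <= v_c")
    if (r$k_back_fold < 1)
      stop("rate_params: k_back_fold must be >= 1, got ", r$k_back_fold)
  }
  if (inherits(r, "obstacle_rates")) {
    if (r$v_slow > r$v_c) stop("rate_params: v_slow must be <= v_c")
    if (is.numeric(r$occupancy)) {
      if (any(is.na(r$occupancy)) || any(r$occupancy < 0) ||
          any(r$occupancy >= 1))
        stop("rate_params: obstacle occupancy must lie in [0, 1) at every bin")
    } else if (!is.character(r$occupancy) || length(r$occupancy) != 1L) {
      stop("rate_params: occupancy must be numeric per-bin values or a toy",
           " profile name")
    }
  }
  r
}

#' Position-dependent backtracking-rate profile
#'
#' The mobile-to-backtracked switching rate equals `k_back_min` at every bin
#' upstream of the termination zone and `k_back_fold * k_back_min` inside it
#' (bins `term_zone_start_bin` to `term_zone_end_bin`), the default being a
#' 200-fold stronger rate of backtracking in the termination zone.
#'
#' @param params a [backtrack_rates()] object.
#' @param lattice a [lattice_config()] object.
#' @return Numeric vector of per-bin rates (1/s), length `n_bins`.
#' @examples
#' kb <- build_kback_profile(backtrack_rates(), lattice_config())
#' kb[10]  # 0.002 in the gene body
#' kb[22]  # 0.4 in the termination zone (200-fold)
#' @export
build_kback_profile <- function(params, lattice) {
  stopifnot(inherits(params, "backtrack_rates"))
  lattice <- validate_lattice(lattice)
  if (params$k_back_min <= 0)
    stop("build_kback_profile: k_back_min must be positive for the",
         " backtrack model")
  kb <- rep(params$k_back_min, lattice$n_bins)
  zone <- seq(lattice$term_zone_start_bin, lattice$term_zone_end_bin)
  kb[zone] <- params$k_back_fold * params$k_back_min
  kb
}

#' Built-in toy obstacle-occupancy profiles
#'
#' Two illustrative stationary-occupancy profiles for the obstacle model.
#' Their exact shapes are a package choice (smooth, strictly positive and
#' mirror-symmetric about the lattice centre, so that direction symmetry of
#' the condensin residence profile is exact in distribution):
#' `"plateau"` is a single broad Gaussian plateau, `"two_block"` two bumps.
#'
#' @param name `"plateau"` or `"two_block"`.
#' @param lattice a [lattice_config()] object.
#' @return Numeric vector of per-bin occupancies in `[0, 1)`.
#' @examples
#' occ <- toy_occupancy("two_block", lattice_config())
#' @export
toy_occupancy <- function(name = c("plateau", "two_block"),
                          lattice = lattice_config()) {
  name <- match.arg(name)
  lattice <- validate_lattice(lattice)
  n <- lattice$n_bins
  mid <- (n + 1) / 2
  i <- seq_len(n)
  if (name == "plateau") {
    occ <- 0.05 + 0.55 * exp(-((i - mid) / (0.15 * n))^2)
  } else {
    w <- 0.09 * n
    occ <- 0.04 + 0.30 * exp(-((i - (mid - 0.2 * n)) / w)^2) +
                  0.30 * exp(-((i - (mid + 0.2 * n)) / w)^2)
  }
  occ
}

# resolve the obstacle occupancy field to a per-bin numeric vector
resolve_occupancy <- function(params, lattice) {
  occ <- params$occupancy
  if (is.character(occ)) occ <- toy_occupancy(occ, lattice)
  if (length(occ) != lattice$n_bins)
    stop("obstacle occupancy must have length n_bins = ", lattice$n_bins)
  if (any(occ < 0) || any(occ >= 1))
    stop("obstacle occupancy must lie in [0, 1) at every bin")
  occ
}
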