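# Synthetic ChIP-like tracks.  These emulate the structure of normalized
# ChIP-qPCR data (per-bin counting noise, moving-average blurring from
# sonication-fragment size, normalization to an in-gene reference position)
# so that the model-vs-track comparison machinery is testable without any
# external data.  The tracks are synthetic stand-ins, not real ChIP data.

# moving average over an odd window, edges renormalized to the bins present
moving_average <- function(v, width) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L)
    stop("smoothing_bins must be a positive odd integer")
  if (width == 1L) return(v)
  half <- width %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - half):min(n, i + half)
    mean(v[w])
  }, numeric(1))
}

#' Synthesize a noisy ChIP-like track from a model profile
#'
#' Converts a per-bin model profile into synthetic counts: the expected
#' count is `depth` times the moving-average-smoothed profile, and observed
#' counts are drawn from a counting-noise law with variance
#' `lambda * (1 + overdispersion * lambda)` (Poisson when
#' `overdispersion = 0`, negative binomial otherwise).  Draws use R's RNG,
#' so results are deterministic under `set.seed()` (or via `seed`).
#'
#' @param profile a residence/occupancy profile data.frame or numeric
#'   vector of non-negative per-bin values.
#' @param depth expected counts per unit signal (> 0).
#' @param overdispersion overdispersion knob (>= 0; 0 = pure counting
#'   noise).
#' @param smoothing_bins odd moving-average width in bins emulating
#'   sonication-fragment blurring (1 = no smoothing).
#' @param seed optional integer; when given, the RNG is seeded first.
#' @return An object of class `chip_track`: a data.frame with `bin` and
#'   `signal` (counts), with the generation settings in attributes.
#' @examples
#' tr <- synthesize_track(rep(1, 100), depth = 1000, seed = 1)
#' @export
synthesize_track <- function(profile, depth, overdispersion = 0,
                             smoothing_bins = 3L, seed = NULL) {
  v <- profile_values(profile)
  if (any(!is.finite(v)) || any(v < 0))
    stop("synthesize_track: profile must be non-negative")
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("synthesize_track: depth must be a single positive number")
  if (overdispersion < 0)
    stop("synthesize_track: overdispersion must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  lambda <- depth * moving_average(v, smoothing_bins)
  counts <- if (overdispersion == 0) {
    rpois(length(lambda), lambda)
  } else {
    ifelse(lambda == 0, 0,
           rnbinom(length(lambda), size = 1 / overdispersion, mu = lambda))
  }
  track <- data.frame(bin = seq_along(v), signal = as.numeric(counts))
  attr(track, "depth") <- depth
  attr(track, "overdispersion") <- overdispersion
  attr(track, "smoothing_bins") <- as.integer(smoothing_bins)
  attr(track, "normalized") <- FALSE
  attr(track, "reference_bin") <- NA_integer_
  class(track) <- c("chip_track", "data.frame")
  track
}

#' Normalize a track to an in-gene reference position
#'
#' Divides every bin by the signal at the reference bin, mimicking percent-IP
#' values normalized to a fixed site within the gene body.  The normalized
#' track has value 1 at the reference bin and is invariant under uniform
#' rescaling of the counts.
#'
#' @param track a `chip_track` (or data.frame with `bin` and `signal`).
#' @param reference_bin the reference bin; its signal must be > 0.
#' @return The normalized `chip_track`.
#' @examples
#' tr <- synthesize_track(rep(2, 100), depth = 500, seed = 1)
#' normalize_track(tr, reference_bin = 10)
#' @export
normalize_track <- function(track, reference_bin = 10L) {
  stopifnot(is.data.frame(track), "signal" %in% names(track))
  reference_bin <- as.integer(reference_bin)
  if (reference_bin < 1L || reference_bin > nrow(track))
    stop("normalize_track: reference bin out of range")
  ref <- track$signal[reference_bin]
  if (!is.finite(ref) || ref <= 0)
    stop("normalize_track: zero signal at the reference bin")
  track$signal <- track$signal / ref
  attr(track, "normalized") <- TRUE
  attr(track, "reference_bin") <- reference_bin
  track
}

#' Compare the shape of a track with a model profile
#'
#' Rank (Spearman) correlation across bins between a ChIP-like track and a
#' model profile, plus the difference of their termination-zone enrichment
#' statistics -- the qualitative model-vs-data comparison used to judge
#' whether a model reproduces an observed condensin pattern.
#'
#' @param track a `chip_track` (normalized or not; both statistics are
#'   scale-invariant).
#' @param profile a residence/occupancy profile or numeric vector on the
#'   same lattice.
#' @param lattice the shared [lattice_config()].
#' @return A list with `rank_correlation` and `enrichment_difference`
#'   (track minus profile).
#' @export
compare_shapes <- function(track, profile, lattice = lattice_config()) {
  tv <- profile_values(track)
  pv <- profile_values(profile)
  if (length(tv) != length(pv))
    stop("compare_shapes: track and profile must share the lattice")
  if (length(unique(tv)) < 2L || length(unique(pv)) < 2L)
    stop("compare_shapes: constant input, rank correlation undefined")
  list(rank_correlation = cor(tv, pv, method = "spearman"),
       enrichment_difference =
         termination_enrichment(tv, lattice) -
         termination_enrichment(pv, lattice))
}
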