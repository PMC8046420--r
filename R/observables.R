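# Shape statistics over occupancy and residence profiles.  Window choices
# are frozen constants (relative to the lattice geometry) so that the shape
# claims they operationalize are testable and non-circular:
#   termination window = first 6 termination-zone bins,
#   gene-body window   = bins gene_start+4 .. gene_start+14,
#   5' half            = gene_start .. gene_end/2,
#   3' half            = gene_end/2+1 .. gene_end-1.
# With the default lattice these are bins 20-25, 5-15, 1-10 and 11-19.

profile_values <- function(x) {
  if (inherits(x, "residence_profile")) return(x$mean)
  if (inherits(x, "occupancy_profile")) return(x$occupancy)
  if (is.data.frame(x)) {
    for (col in c("mean", "occupancy", "signal", "value"))
      if (col %in% names(x)) return(x[[col]])
    stop("cannot find a value column in profile data.frame")
  }
  as.numeric(x)
}

term_window <- function(lattice) {
  seq(lattice$term_zone_start_bin,
      min(lattice$term_zone_start_bin + 5L, lattice$term_zone_end_bin))
}

body_window <- function(lattice) {
  seq(lattice$gene_start_bin + 4L,
      min(lattice$gene_start_bin + 14L, lattice$gene_end_bin - 1L))
}

#' Termination-zone enrichment of a profile
#'
#' Ratio of the mean profile value over the start of the termination zone
#' (bins 20--25 on the default lattice) to the mean over the gene-body
#' window (bins 5--15).  A value above 1 indicates a 3' peak; the statistic
#' is invariant under uniform rescaling of the profile.
#'
#' @param x a residence/occupancy profile data.frame, a [chip_track]
#'   (see [synthesize_track()]), or a bare numeric vector of per-bin values.
#' @param lattice the [lattice_config()] the profile lives on.
#' @return A single dimensionless ratio.
#' @examples
#' termination_enrichment(rep(1, 100), lattice_config())  # flat -> 1
#' @export
termination_enrichment <- function(x, lattice = lattice_config()) {
  v <- profile_values(x)
  if (length(v) != lattice$n_bins)
    stop("termination_enrichment: profile length != n_bins")
  denom <- mean(v[body_window(lattice)])
  if (!is.finite(denom) || denom == 0)
    stop("termination_enrichment: zero gene-body mean, ratio undefined")
  mean(v[term_window(lattice)]) / denom
}

#' 5' tilt of a profile over the gene body
#'
#' Ratio of the mean profile value over the 5' half of the gene (bins 1--10
#' on the default lattice) to the mean over the 3' half (bins 11--19).
#' Values above 1 indicate occupancy shifted toward the 5' end.
#'
#' @inheritParams termination_enrichment
#' @return A single dimensionless ratio.
#' @export
tilt_5prime <- function(x, lattice = lattice_config()) {
  v <- profile_values(x)
  if (length(v) != lattice$n_bins)
    stop("tilt_5prime: profile length != n_bins")
  half <- lattice$gene_end_bin %/% 2L
  five <- seq(lattice$gene_start_bin, half)
  three <- seq(half + 1L, lattice$gene_end_bin - 1L)
  denom <- mean(v[three])
  if (!is.finite(denom) || denom == 0)
    stop("tilt_5prime: zero 3'-half mean, ratio undefined")
  mean(v[five]) / denom
}

#' Log-linear (exponential) fit of a profile segment
#'
#' Least-squares fit of `log(value)` against bin index over a bin range,
#' quantifying how exponential a profile is: an exactly exponential profile
#' gives `r_squared = 1` with slope `log(fold change per bin)`.
#'
#' @inheritParams termination_enrichment
#' @param bins bin indices of the fitted range; all values there must be
#'   strictly positive.
#' @return A list with `rate_per_bin` (the slope of the log-linear fit) and
#'   `r_squared`.
#' @examples
#' fit_exponential(2^(1:100), bins = 2:19)  # slope log(2), R^2 = 1
#' @export
fit_exponential <- function(x, bins) {
  v <- profile_values(x)
  if (any(bins < 1L) || any(bins > length(v)))
    stop("fit_exponential: bins out of range")
  y <- v[bins]
  if (any(!is.finite(y)) || any(y <= 0))
    stop("fit_exponential: values must be strictly positive on the range")
  fit <- lm(log(y) ~ bins)
  tss <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  list(rate_per_bin = unname(coef(fit)[2]), r_squared = r2)
}

#' Percentile bootstrap over a retained event matrix
#'
#' `profile_sem_bootstrap()` resamples the per-event residence vectors (rows
#' of `events`) and returns per-bin percentile confidence intervals for the
#' ensemble-mean profile.  `bootstrap_stat()` does the same for any scalar
#' statistic of the mean profile (for example
#' `function(v) termination_enrichment(v, lattice)`).
#'
#' @param events numeric matrix, one row per traversal, one column per bin.
#' @param n_resamples number of bootstrap resamples (warned below 100).
#' @param conf confidence level.
#' @return `profile_sem_bootstrap`: a data.frame with `bin`, `mean`, `lo`,
#'   `hi`.  `bootstrap_stat`: a named vector `estimate`, `lo`, `hi`.
#' @examples
#' ev <- matrix(rexp(500), nrow = 50)
#' ci <- profile_sem_bootstrap(ev, n_resamples = 200)
#' @export
profile_sem_bootstrap <- function(events, n_resamples = 1000L,
                                  conf = 0.95) {
  stopifnot(is.matrix(events))
  if (n_resamples < 100L)
    warning("profile_sem_bootstrap: n_resamples < 100 gives unstable CIs")
  n <- nrow(events)
  alpha <- (1 - conf) / 2
  boots <- matrix(0, nrow = n_resamples, ncol = ncol(events))
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- colMeans(events[idx, , drop = FALSE])
  }
  data.frame(bin = seq_len(ncol(events)), mean = colMeans(events),
             lo = apply(boots, 2L, quantile, probs = alpha),
             hi = apply(boots, 2L, quantile, probs = 1 - alpha))
}

#' @rdname profile_sem_bootstrap
#' @param stat_fn function mapping a per-bin mean profile (numeric vector)
#'   to a scalar.
#' @export
bootstrap_stat <- function(events, stat_fn, n_resamples = 1000L,
                           conf = 0.95) {
  stopifnot(is.matrix(events), is.function(stat_fn))
  if (n_resamples < 100L)
    warning("bootstrap_stat: n_resamples < 100 gives unstable CIs")
  n <- nrow(events)
  alpha <- (1 - conf) / 2
  stats <- vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    stat_fn(colMeans(events[idx, , drop = FALSE]))
  }, numeric(1))
  c(estimate = stat_fn(colMeans(events)),
    lo = unname(quantile(stats, alpha)),
    hi = unname(quantile(stats, 1 - alpha)))
}

#' Summary-statistics table of an ensemble
#'
#' Computes the package's shape statistics (termination-zone enrichment, 5'
#' tilt of the occupancy, log-linear fit of the within-gene residence) for
#' every direction of an ensemble, with bootstrap confidence intervals where
#' a retained event matrix allows it, and returns them as one tidy table.
#'
#' @param ens a [run_ensemble()] result (with `keep_events = TRUE` for CIs).
#' @param preset optional preset label recorded in the table.
#' @param n_resamples bootstrap resamples for the CIs.
#' @return A data.frame with columns `model`, `preset`, `direction`,
#'   `statistic`, `value`, `ci_lo`, `ci_hi`, `n_events`, `seed`.
#' @export
summarize_ensemble <- function(ens, preset = NA_character_,
                               n_resamples = 1000L) {
  stopifnot(inherits(ens, "condensin_ensemble"))
  lat <- ens$plan$lattice
  rows <- list()
  add <- function(direction, statistic, value, lo = NA_real_,
                  hi = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = ens$plan$model, preset = preset, direction = direction,
      statistic = statistic, value = value, ci_lo = lo, ci_hi = hi,
      n_events = ens$plan$n_events, seed = ens$plan$seed,
      stringsAsFactors = FALSE)
  }
  te_fn <- function(v) termination_enrichment(v, lat)
  for (d in names(ens$residence)) {
    r <- ens$residence[[d]]
    if (!is.null(ens$events[[d]])) {
      ci <- bootstrap_stat(ens$events[[d]], te_fn, n_resamples)
      add(d, "termination_enrichment", ci["estimate"], ci["lo"], ci["hi"])
    } else {
      add(d, "termination_enrichment", te_fn(r$mean))
    }
    add(d, "mean_transit_s", sum(r$mean))
    add(d, "argmax_bin", which.max(r$mean))
    gene_bins <- seq(lat$gene_start_bin + 1L, lat$gene_end_bin - 1L)
    if (all(r$mean[gene_bins] > 0)) {
      fe <- fit_exponential(r$mean, gene_bins)
      add(d, "loglinear_rate_per_bin", fe$rate_per_bin)
      add(d, "loglinear_r_squared", fe$r_squared)
    }
  }
  if (!is.null(ens$residence_avg))
    add("average", "termination_enrichment", te_fn(ens$residence_avg$mean))
  if (!is.null(ens$occupancy)) {
    add("occupancy", "tilt_5prime", tilt_5prime(ens$occupancy, lat))
    add("occupancy", "termination_enrichment", te_fn(ens$occupancy))
    gene_bins <- seq(lat$gene_start_bin + 1L, lat$gene_end_bin - 1L)
    tot <- ens$occupancy$occupancy[gene_bins]
    add("occupancy", "gene_body_cv", sd(tot) / mean(tot))
    if (any(ens$occupancy$occupancy_b > 0))
      add("occupancy", "brnap_gene_body_share",
          mean(ens$occupancy$occupancy_b[gene_bins]) / mean(tot))
  }
  do.call(rbind, rows)
}
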