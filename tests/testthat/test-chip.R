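lat <- lattice_config()

# a smooth deterministic stand-in profile with gene-body rise + 3' peak;
# strictly graded everywhere so rank statistics are well defined
reference_profile <- function() {
  i <- seq_len(100)
  0.3 + 0.012 * i + 0.04 * pmin(i, 20) + 1.5 * exp(-((i - 21) / 3)^2)
}

test_that("tracks converge to the smoothed profile at high depth", {
  prof <- reference_profile()
  tr <- synthesize_track(prof, depth = 1e6, overdispersion = 0,
                         smoothing_bins = 3, seed = 1)
  sm <- condensinTASEP:::moving_average(prof, 3)
  rms <- sqrt(mean((tr$signal / 1e6 - sm)^2)) / mean(sm)
  expect_lt(rms, 0.01)
  expect_error(synthesize_track(prof, depth = 0), "depth")
  expect_error(synthesize_track(prof, depth = 10, smoothing_bins = 2),
               "odd")
})

test_that("flat profiles give flat normalized tracks", {
  tr <- synthesize_track(rep(2, 100), depth = 5e4, seed = 2)
  ntr <- normalize_track(tr, reference_bin = 10)
  expect_equal(ntr$signal[10], 1.0)
  expect_true(all(abs(ntr$signal - 1) < 0.05))
})

test_that("width-1 smoothing is the identity", {
  v <- reference_profile()
  expect_identical(condensinTASEP:::moving_average(v, 1L), v)
  # interior bins of a width-3 average are the local means
  sm <- condensinTASEP:::moving_average(v, 3L)
  expect_equal(sm[50], mean(v[49:51]))
  expect_equal(sm[1], mean(v[1:2]))  # edge renormalized to available bins
})

test_that("normalization is scale-invariant and guards the reference", {
  tr <- synthesize_track(reference_profile(), depth = 1e4, seed = 3)
  n1 <- normalize_track(tr, 10)
  tr2 <- tr
  tr2$signal <- tr2$signal * 2
  expect_equal(normalize_track(tr2, 10)$signal, n1$signal)
  tr0 <- tr
  tr0$signal[10] <- 0
  expect_error(normalize_track(tr0, 10), "reference")
  expect_error(normalize_track(tr, 500), "range")
})

test_that("overdispersion widens counting noise as specified", {
  prof <- rep(1, 2000)
  pois <- synthesize_track(prof, depth = 100, overdispersion = 0,
                           smoothing_bins = 1, seed = 4)
  od <- synthesize_track(prof, depth = 100, overdispersion = 0.05,
                         smoothing_bins = 1, seed = 5)
  # var(pois) ~ 100; var(od) ~ 100 * (1 + 5) = 600
  expect_lt(var(pois$signal), 200)
  expect_gt(var(od$signal), 350)
})

test_that("shape comparison separates matched from mismatched profiles", {
  prof <- reference_profile()
  tr <- synthesize_track(prof, depth = 1e5, seed = 6)
  self <- compare_shapes(tr, prof, lat)
  expect_gt(self$rank_correlation, 0.95)
  expect_lt(abs(self$enrichment_difference), 0.2)
  # reversed monotone profile anti-correlates with itself
  mono <- seq(1, 5, length.out = 100)
  tr_mono <- synthesize_track(mono, depth = 1e5, smoothing_bins = 1,
                              seed = 7)
  expect_lt(compare_shapes(tr_mono, rev(mono), lat)$rank_correlation,
            -0.95)
  expect_error(compare_shapes(data.frame(bin = 1:100, signal = rep(1, 100)),
                              prof, lat), "constant")
})

test_that("enrichment statistics survive synthesis across seeds", {
  prof <- reference_profile()
  te_true <- termination_enrichment(prof, lat)
  rel_err <- vapply(1:20, function(s) {
    tr <- synthesize_track(prof, depth = 1e4, smoothing_bins = 3, seed = s)
    abs(termination_enrichment(tr$signal, lat) - te_true) / te_true
  }, numeric(1))
  expect_true(all(rel_err < 0.05))
})
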