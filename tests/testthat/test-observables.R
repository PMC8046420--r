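lat <- lattice_config()

test_that("termination enrichment and 5' tilt behave on known shapes", {
  expect_equal(termination_enrichment(rep(3.7, 100), lat), 1.0)
  expect_equal(tilt_5prime(rep(0.2, 100), lat), 1.0)

  # single spike at bin 21 with an empty gene body: undefined ratio
  spike <- replace(rep(0, 100), 21, 5)
  expect_error(termination_enrichment(spike, lat), "undefined")
  expect_error(tilt_5prime(replace(rep(0, 100), 2, 1), lat), "undefined")

  # a profile elevated over bins 20-25 scores > 1; its mirror scores < 1
  peaked <- rep(1, 100); peaked[20:25] <- 4
  expect_gt(termination_enrichment(peaked, lat), 1)
  tilted <- c(rep(2, 10), rep(1, 90))
  expect_gt(tilt_5prime(tilted, lat), 1)
  expect_lt(tilt_5prime(c(rep(1, 10), rep(2, 90)), lat), 1)

  # both statistics are invariant under uniform rescaling
  set.seed(2)
  prof <- runif(100, 0.5, 2)
  expect_equal(termination_enrichment(prof * 37, lat),
               termination_enrichment(prof, lat))
  expect_equal(tilt_5prime(prof * 0.01, lat), tilt_5prime(prof, lat))
})

test_that("log-linear fit recovers exact exponentials and flats", {
  y <- 2^(seq_len(100))
  fit <- fit_exponential(y, bins = 2:19)
  expect_equal(fit$rate_per_bin, log(2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-10)

  flat <- fit_exponential(rep(5, 100), bins = 2:19)
  expect_equal(flat$rate_per_bin, 0, tolerance = 1e-12)

  expect_error(fit_exponential(replace(rep(1, 100), 10, 0), bins = 2:19),
               "positive")
  # rescaling leaves the slope untouched
  expect_equal(fit_exponential(y * 100, bins = 5:15)$rate_per_bin,
               fit_exponential(y, bins = 5:15)$rate_per_bin)
})

test_that("bootstrap intervals collapse for constant data and shrink with n", {
  ev <- matrix(0.25, nrow = 200, ncol = 10)
  ci <- profile_sem_bootstrap(ev, n_resamples = 200)
  expect_equal(ci$lo, ci$hi)
  expect_equal(ci$mean, rep(0.25, 10))

  set.seed(7)
  big <- matrix(rexp(3200 * 5), nrow = 3200, ncol = 5)
  w <- function(n) {
    ci <- profile_sem_bootstrap(big[seq_len(n), , drop = FALSE],
                                n_resamples = 400)
    mean(ci$hi - ci$lo)
  }
  ratio <- w(200) / w(3200)
  expect_gt(ratio, 2.2)  # ideal 4
  expect_lt(ratio, 7)

  expect_warning(profile_sem_bootstrap(ev, n_resamples = 50), "resamples")
})

test_that("bootstrap_stat brackets the plug-in estimate", {
  set.seed(9)
  ev <- matrix(rexp(500 * 100, rate = 10), nrow = 500)
  ci <- bootstrap_stat(ev, function(v) termination_enrichment(v, lat),
                       n_resamples = 300)
  expect_true(ci["lo"] <= ci["estimate"] && ci["estimate"] <= ci["hi"])
})

test_that("direction-averaged enrichment lies between the directional ones", {
  set.seed(4)
  for (rep in 1:5) {
    a <- runif(100, 0.2, 2)
    b <- runif(100, 0.2, 2)
    te <- c(termination_enrichment(a, lat), termination_enrichment(b, lat),
            termination_enrichment((a + b) / 2, lat))
    expect_gte(te[3], min(te[1:2]) - 1e-12)
    expect_lte(te[3], max(te[1:2]) + 1e-12)
  }
})

test_that("ensemble summaries carry the keyed statistics table", {
  plan <- quick_plan("backtrack", n_events = 60)
  ens <- suppressWarnings(run_ensemble(plan))
  tab <- summarize_ensemble(ens, preset = "wt", n_resamples = 120)
  expect_true(all(c("model", "preset", "direction", "statistic", "value",
                    "ci_lo", "ci_hi", "n_events", "seed") %in% names(tab)))
  te <- tab[tab$statistic == "termination_enrichment" &
            tab$direction == "head_to_tail", ]
  expect_true(te$ci_lo <= te$value && te$value <= te$ci_hi)
  expect_true("brnap_gene_body_share" %in% tab$statistic)
})
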