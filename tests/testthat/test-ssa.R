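test_that("waiting times and channel choice follow the direct method", {
  set.seed(1)
  # single channel: exponential waiting time with the channel's rate
  ch1 <- data.frame(label = "initiate", site = 1L, propensity = 0.5)
  dts <- replicate(10000, draw_next_event(ch1)$dt)
  expect_lt(abs(mean(dts) - 2), 3 * sd(dts) / sqrt(length(dts)))

  # two channels, rates 1 and 3: second picked ~75% of the time
  ch2 <- data.frame(label = c("a", "b"), site = c(1L, 2L),
                    propensity = c(1, 3))
  picks <- replicate(10000, draw_next_event(ch2)$channel$label)
  p_b <- mean(picks == "b")
  expect_lt(abs(p_b - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  # zero total propensity signals an absorbing state, no event
  out <- draw_next_event(data.frame(label = character(0), site = integer(0),
                                    propensity = numeric(0)))
  expect_true(out$absorbing)
  expect_null(out$channel)
  expect_identical(out$dt, Inf)
})

test_that("run_until conserves time and respects absorbing states", {
  lat <- lattice_config()
  # no initiation, no condensin: absorbing immediately
  plan0 <- quick_plan(rates = simple_rates(gamma_init = 0))
  out <- run_until(system_state(lat), model_rules(plan0),
                   stop_fn = function(s) s$time >= 10)
  expect_true(out$absorbing)
  expect_equal(sum(out$state$occ), 0)

  # condensin alone: accumulated residence equals the exit time exactly
  plan <- quick_plan(rates = simple_rates(gamma_init = 0))
  st <- system_state(lat, cond_bin = 1L, cond_dir = 1L)
  set.seed(11)
  out <- run_until(st, model_rules(plan),
                   stop_fn = function(s) is.na(s$cond_bin))
  expect_equal(sum(out$residence), out$state$time,
               tolerance = 1e-9)
  expect_equal(out$n_events, 100L)  # 100 hops to cross and leave 100 bins
})

test_that("channels on a 3-bin lattice match a hand enumeration", {
  lat <- tiny_lattice()
  params <- simple_rates()
  # state: RNAP at bin 1, condensin at bin 2 moving 5'->3', bin 3 empty.
  # By hand: the RNAP at 1 may step (push: condensin to 3, which is free);
  # bin 1 is below the termination zone so no unbinding; initiation blocked;
  # condensin hops into free bin 3 at v_c.  Exactly two channels.
  st <- system_state(lat, occ = c(1L, 0L, 0L), cond_bin = 2L, cond_dir = 1L)
  expected <- data.frame(label = c("condensin_step", "rnap_step"),
                         site = c(2L, 1L), propensity = c(10, 0.4),
                         stringsAsFactors = FALSE)
  got_r <- sort_channels(simple_events(st, params, lat))
  expect_equal(got_r, expected, ignore_attr = TRUE)
  plan <- simulation_plan("simple", rates = params, lattice = lat,
                          n_events = 1, seed = 1)
  expect_equal(sort_channels(cpp_channels(plan, st)), expected,
               ignore_attr = TRUE)

  # same state but bin 3 occupied: the blocked push suppresses the bin-1
  # hop; the bin-3 RNAP may walk off (rnap_step) or unbind (zone bin), and
  # the condensin's only move is the bypass at v_jump
  st2 <- system_state(lat, occ = c(1L, 0L, 1L), cond_bin = 2L, cond_dir = 1L)
  got2 <- sort_channels(simple_events(st2, params, lat))
  expect_equal(got2$label,
               c("condensin_bypass", "rnap_step", "rnap_terminate"))
  expect_equal(got2$site, c(2L, 3L, 3L))
  expect_equal(got2$propensity, c(0.01, 0.4, 0.4))
})

test_that("reference R rules and the compiled engine enumerate identically", {
  lat <- lattice_config(n_bins = 30, gene_end_bin = 8,
                        term_zone_start_bin = 8, term_zone_end_bin = 30)
  plans <- list(
    simple = simulation_plan("simple", rates = simple_rates(v_jump = 15),
                             lattice = lat, n_events = 1, seed = 1),
    backtrack = simulation_plan(
      "backtrack", rates = backtrack_rates(v_jump_b = 5), lattice = lat,
      n_events = 1, seed = 1),
    obstacle = simulation_plan(
      "obstacle",
      rates = obstacle_rates(occupancy = seq(0.02, 0.6, length.out = 30)),
      lattice = lat, n_events = 1, seed = 1))
  set.seed(99)
  for (model in names(plans)) {
    plan <- plans[[model]]
    rules <- model_rules(plan)
    for (rep in 1:40) {
      st <- random_state(model, lat)
      expect_equal(sort_channels(rules$events(st)),
                   sort_channels(cpp_channels(plan, st)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("compiled trajectories conserve time bin by bin", {
  plan <- quick_plan("backtrack", n_events = 30)
  bi <- suppressWarnings(burn_in(plan))
  set.seed(5)
  for (rep in 1:5) {
    tr <- run_traversal(bi$state, "head_to_head", plan)
    expect_equal(sum(tr$residence), tr$duration, tolerance = 1e-9)
    expect_true(all(tr$residence >= 0))
    bi$state <- tr$state
  }
})
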