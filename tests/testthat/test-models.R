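lat <- lattice_config()

test_that("simple-model channels follow the TASEP + condensin rules", {
  params <- simple_rates()
  # empty lattice: initiation is the only possible event, at gamma_init
  ch <- simple_events(system_state(lat), params, lat)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$label, "initiate")
  expect_equal(ch$propensity, 0.05)

  # exclusion: RNAP at 5 is blocked by RNAP at 6; only the RNAP at 6 steps
  st <- system_state(lat, occ = replace(integer(100), c(5, 6), 1L))
  ch <- simple_events(st, params, lat)
  steps <- ch[ch$label == "rnap_step", ]
  expect_equal(steps$site, 6L)
  expect_equal(steps$propensity, 0.4)

  # a blocking RNAP turns the condensin hop into a bypass at v_jump
  params15 <- simple_rates(v_jump = 15)
  st <- system_state(lat, occ = replace(integer(100), 51, 1L),
                     cond_bin = 50L, cond_dir = 1L)
  ch <- simple_events(st, params15, lat)
  expect_false("condensin_step" %in% ch$label)
  byp <- ch[ch$label == "condensin_bypass", ]
  expect_equal(byp$propensity, 0.15)  # 15 bp/s = 0.15 bins/s
})

test_that("applying simple-model events moves, pushes and exchanges", {
  params <- simple_rates()
  # push: RNAP stepping into the condensin's bin displaces it toward 3'
  st <- system_state(lat, occ = replace(integer(100), 10, 1L),
                     cond_bin = 11L, cond_dir = -1L)
  out <- apply_simple_event(st, list(label = "rnap_step", site = 10L),
                            params, lat)
  expect_equal(which(out$occ == 1L), 11L)
  expect_equal(out$cond_bin, 12L)

  # bypass is a position exchange with the blocking RNAP
  st <- system_state(lat, occ = replace(integer(100), 31, 1L),
                     cond_bin = 30L, cond_dir = 1L)
  out <- apply_simple_event(st, list(label = "condensin_bypass", site = 30L),
                            params, lat)
  expect_equal(out$cond_bin, 31L)
  expect_equal(which(out$occ == 1L), 30L)

  # termination empties the bin and changes nothing else
  st <- system_state(lat, occ = replace(integer(100), c(5, 25), 1L))
  out <- apply_simple_event(st, list(label = "rnap_terminate", site = 25L),
                            params, lat)
  expect_equal(which(out$occ == 1L), 5L)

  # stale events fail loudly
  st <- system_state(lat)
  expect_error(
    apply_simple_event(st, list(label = "rnap_step", site = 10L),
                       params, lat),
    "stale event")
})

test_that("backtrack-model channels depend on RNAP state and position", {
  params <- backtrack_rates(gamma_term = 0.2, k_back_min = 0.002,
                            k_back_fold = 200)
  # mobile RNAP inside the termination zone backtracks 200-fold faster
  st <- system_state(lat, occ = replace(integer(100), 22, 1L))
  ch <- backtrack_events(st, params, lat)
  expect_equal(ch$propensity[ch$label == "switch_to_backtracked"], 0.4)
  expect_false("rnap_terminate" %in% ch$label)  # mobile RNAPs cannot unbind

  # backtracked RNAP in the zone: recovers at k_on and unbinds at gamma_term
  st <- system_state(lat, occ = replace(integer(100), 22, 2L))
  ch <- backtrack_events(st, params, lat)
  expect_equal(ch$propensity[ch$label == "switch_to_mobile"], 0.2)
  expect_equal(ch$propensity[ch$label == "rnap_terminate"], 0.2)
  expect_false("rnap_step" %in% ch$label)       # bRNAPs are immobile

  # backtracked RNAP outside the zone can neither unbind nor move
  st <- system_state(lat, occ = replace(integer(100), 10, 2L))
  ch <- backtrack_events(st, params, lat)
  expect_equal(sort(ch$label), c("initiate", "switch_to_mobile"))

  # v_jump_b = 0: no bypass channel, the condensin must wait
  st <- system_state(lat, occ = replace(integer(100), 51, 2L),
                     cond_bin = 50L, cond_dir = 1L)
  ch <- backtrack_events(st, params, lat)
  expect_false(any(grepl("condensin", ch$label)))
  # ... but a mobile blocker is bypassed at v_jump_m
  st$occ[51] <- 1L
  ch <- backtrack_events(st, params, lat)
  expect_equal(ch$propensity[ch$label == "condensin_bypass"], 0.15)
})

test_that("obstacle-model channels implement two-state site kinetics", {
  occ_target <- rep(0, 100)
  occ_target[40] <- 0.5
  params <- obstacle_rates(occupancy = occ_target)
  # empty bin with occ 0.5: k_bind = k_off (detailed balance); occ 0 bins
  # emit no binding channel at all
  st <- system_state(lat)
  ch <- obstacle_events(st, params, lat)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$label, "obstacle_bind")
  expect_equal(ch$site, 40L)
  expect_equal(ch$propensity, 1 / 60)

  # bound obstacle next to the condensin: bypass at v_slow = 0.1 bins/s,
  # and the obstacle itself may unbind
  st <- system_state(lat, occ = replace(integer(100), 40, 1L),
                     cond_bin = 39L, cond_dir = 1L)
  ch <- obstacle_events(st, params, lat)
  expect_equal(ch$propensity[ch$label == "condensin_bypass"], 0.1)
  expect_equal(ch$propensity[ch$label == "obstacle_unbind"], 1 / 60)
  # bypass does not displace the obstacle
  out <- apply_obstacle_event(st, list(label = "condensin_bypass",
                                       site = 39L), params, lat)
  expect_equal(out$cond_bin, 40L)
  expect_equal(which(out$occ == 1L), 40L)
})

test_that("hop-over bypass lands past a contiguous block", {
  params <- simple_rates(v_jump = 15, bypass_mode = "hop_over")
  st <- system_state(lat, occ = replace(integer(100), 51:53, 1L),
                     cond_bin = 50L, cond_dir = 1L)
  out <- apply_simple_event(st, list(label = "condensin_bypass", site = 50L),
                            params, lat)
  expect_equal(out$cond_bin, 54L)
  expect_equal(which(out$occ == 1L), 51:53)  # RNAPs unmoved
})

test_that("single occupancy holds along simulated trajectories", {
  plan <- quick_plan("backtrack", n_events = 20,
                     rates = backtrack_rates(gamma_init = 0.2,
                                             v_jump_b = 5))
  rules <- model_rules(plan)
  st <- system_state(lat, cond_bin = 1L, cond_dir = 1L)
  set.seed(3)
  for (step in 1:400) {
    ch <- rules$events(st)
    drawn <- draw_next_event(ch)
    if (drawn$absorbing) break
    st <- rules$apply(st, drawn$channel)
    expect_true(all(st$occ %in% 0:2))
    if (!is.na(st$cond_bin)) {
      expect_true(st$cond_bin >= 1 && st$cond_bin <= 100)
      expect_equal(st$occ[st$cond_bin], 0L)  # exchange keeps the bin free
    }
  }
})
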