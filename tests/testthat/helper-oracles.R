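# Shared fixtures and independent oracles, built in code.

# Exact stationary law of the RNAP-only simple model on a tiny lattice,
# computed by brute force from the verbal rules: enumerate all 2^n occupancy
# states, assemble the CTMC generator, solve the balance equations.
# Deliberately independent of the package's event enumeration.
ctmc_stationary_simple <- function(n_bins, term_start, gamma_init,
                                   gamma_term, v_bins) {
  n_states <- 2^n_bins
  Q <- matrix(0, n_states, n_states)
  occ_of <- function(s) as.integer(intToBits(s - 1L))[seq_len(n_bins)]
  idx_of <- function(occ) sum(occ * 2^(seq_len(n_bins) - 1L)) + 1L
  for (s in seq_len(n_states)) {
    occ <- occ_of(s)
    if (occ[1] == 0L) {                       # initiation at the TSS
      to <- occ; to[1] <- 1L
      Q[s, idx_of(to)] <- Q[s, idx_of(to)] + gamma_init
    }
    for (i in which(occ == 1L)) {
      if (i < n_bins && occ[i + 1L] == 0L) {  # exclusion hop
        to <- occ; to[i] <- 0L; to[i + 1L] <- 1L
        Q[s, idx_of(to)] <- Q[s, idx_of(to)] + v_bins
      }
      if (i == n_bins) {                      # walks off the 3' boundary
        to <- occ; to[i] <- 0L
        Q[s, idx_of(to)] <- Q[s, idx_of(to)] + v_bins
      }
      if (i >= term_start) {                  # termination-zone unbinding
        to <- occ; to[i] <- 0L
        Q[s, idx_of(to)] <- Q[s, idx_of(to)] + gamma_term
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, n_states))          # pi %*% Q = 0, sum(pi) = 1
  b <- c(rep(0, n_states), 1)
  as.numeric(qr.solve(A, b))
}

# a 3-bin lattice with an active termination zone (gene bins 1-2, zone 2-3)
tiny_lattice <- function() {
  lattice_config(n_bins = 3, bin_size_bp = 100, gene_start_bin = 1,
                 gene_end_bin = 2, term_zone_start_bin = 2,
                 term_zone_end_bin = 3)
}

# random (possibly condensin-carrying) states for R-vs-compiled rule checks
random_state <- function(model, lattice) {
  n <- lattice$n_bins
  codes <- switch(model, simple = 0:1, backtrack = 0:2, obstacle = 0:1)
  occ <- sample(codes, n, replace = TRUE)
  cond <- sample(c(NA_integer_, seq_len(n)), 1L)
  if (!is.na(cond)) occ[cond] <- 0L  # the condensin's bin is RNAP-free
  system_state(lattice, occ = occ, cond_bin = cond,
               cond_dir = sample(c(-1L, 1L), 1L))
}

cpp_channels <- function(plan, state) {
  par <- condensinTASEP:::internal_params(plan)
  cond <- if (is.na(state$cond_bin)) 0L else state$cond_bin
  ch <- condensinTASEP:::cpp_enumerate(par, state$occ, cond, state$cond_dir)
  condensinTASEP:::channels_df(ch$type, ch$site, ch$rate)
}

sort_channels <- function(df) {
  df[order(df$label, df$site, df$propensity), , drop = FALSE]
}

# small fast plan for structural tests
quick_plan <- function(model = "simple", ...) {
  defaults <- list(model = model, n_events = 50L, burn_in_time = 100,
                   decorrelation_time = 5, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_plan, args)
}
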