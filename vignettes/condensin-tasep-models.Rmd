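---
title: "Lattice models of condensin translocation through transcribed genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice models of condensin translocation through transcribed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the models

Condensin, an SMC-family DNA translocase, accumulates at the 3' end of
active genes in fission yeast mitosis. This package implements stochastic
lattice models of how transcribing RNA polymerase (RNAP) could position a
translocating condensin, and the simulation protocol that turns those
models into testable occupancy and residence-time profiles.

The locus is a one-dimensional array of `n_bins = 100` bins of 100 bp
(10 kbp total), with a 2-kbp gene on bins 1–20 and a *termination zone*
comprising every bin from 20 onward. Three models share this geometry:

**Simple model (TASEP).** RNAPs bind the TSS (bin 1) at rate
$\gamma_{init}$, hop 5'→3' at $v_{RNAP}$ under mutual exclusion (at most
one RNAP per bin), and unbind at $\gamma_{term}$ anywhere in the
termination zone. A single condensin enters at one boundary and hops at
$v_c$ into RNAP-free bins; a blocking RNAP reduces its hop to the bypass
rate $v_{jump}$, resolved as a position exchange. A moving RNAP that steps
into the condensin's bin pushes it one bin toward 3'.

**Backtrack model (TASEP with pauses).** Each RNAP switches between a
mobile, elongating state (mRNAP) and a backtracked, immobile state
(bRNAP). Only mRNAPs hop (and push); only bRNAPs unbind in the
termination zone. Switching to the backtracked state occurs at a
position-dependent rate $k_{back}(i)$: $k_{back,min}$ in the gene body and
$200 \times k_{back,min}$ in the termination zone
(`build_kback_profile()`). Recovery is homogeneous at $k_{on}$. The
condensin bypass rate depends on the blocker's state: $v_{jump}^m$ past an
mRNAP, $v_{jump}^b$ past a bRNAP; with the default $v_{jump}^b = 0$ the
condensin must wait for the bRNAP to recover or unbind.

**Obstacle model.** A direction-symmetry baseline: immobile obstacles bind
empty bins at $k_{bind}(i) = k_{off}\,occ(i)/(1-occ(i))$ — so each bin
relaxes to a target stationary occupancy $occ(i)$ by detailed balance —
and unbind at $k_{off}$. The condensin enters an obstacle-occupied bin at
the strongly reduced rate $v_{slow}$; obstacles are never pushed or
displaced.

## Parameters

| symbol | default | units | meaning |
|---|---|---|---|
| $\gamma_{init}$ | 0.05 | RNAP/s | initiation at the TSS |
| $\gamma_{term}$ | 0.4 (simple), 0.2 (backtrack) | 1/s | termination-zone unbinding |
| $v_{RNAP}$ | 40 | bp/s | elongation (0.4 bins/s) |
| $v_c$ | 1000 | bp/s | condensin translocation (10 bins/s) |
| $v_{jump}$ | 1–15 | bp/s | bypass past an RNAP (simple model) |
| $k_{on}$ | 0.2 (WT-like), 0.02 (tfs1DN-like) | 1/s | bRNAP → mRNAP recovery |
| $k_{back,min}$ | 0.002 ("slow"), 0.1 ("fast") | 1/s | gene-body backtracking |
| $k_{back}$ fold | 200 | — | termination-zone backtracking increase |
| $v_{jump}^m$, $v_{jump}^b$ | 15, 0 | bp/s | state-dependent bypass |
| $v_{slow}$ | 10 | bp/s | condensin rate at an obstacle |
| $k_{off}$ | 1/60 | 1/s | obstacle unbinding (1-min lifetime) |

All speeds are accepted in bp/s and converted once to bins/s internally.
The main-text-like presets use the "slow" switching regime
($k_{back,min} = 0.002\,s^{-1}$), since only the supplementary parameter
scans print both regimes; the `s4-fast` preset scales $k_{on}$ by the same
50-fold factor as $k_{back,min}$ (to 10 s⁻¹), preserving the stationary
backtracked fraction $k_{back,min}/(k_{back,min}+k_{on}) \approx 0.01$ —
the fast regime's own $k_{on}$ is not stated, and preserving that fraction
is the choice that isolates "switching speed" from "backtracked share".

## The two-stage protocol

`run_ensemble()` reproduces the published protocol:

1. **Burn-in** (`burn_in()`): RNAP-only dynamics from an empty lattice for
   `burn_in_time` (default 2000 s). Occupancy time-integrals are collected
   over the second half only; the first and second halves are compared and
   a deviation above 5% absolute at any bin raises a non-convergence
   warning. 2000 s is two orders of magnitude above the gene transit time
   (50 s) and the slowest single-particle timescale (1/$k_{on}$ up to 50 s
   in the tfs1DN-like regime).
2. **Traversals** (`run_traversal()`): one condensin is inserted at bin 1
   (head-to-tail) or bin 100 (head-to-head) and the full system runs until
   it leaves the far boundary; its per-bin residence time is recorded and
   sums exactly to the traversal duration. If the entry bin is occupied,
   RNAP-only dynamics continues until it frees (the wait is reported, not
   counted). Between traversals the RNAP field is propagated alone for
   `decorrelation_time` (default 100 s, i.e. at least twice the slowest
   relaxation time at the default presets), which makes ensemble members
   effectively independent at ~20× less cost than a full re-burn-in; a
   fresh burn-in per event is available by raising `decorrelation_time`.

The desk-scale default is $10^4$ traversals per direction (the reference
protocol uses $10^5$); standard errors scale as $1/\sqrt{n}$ and every
statistic below was sized against its acceptance band at $10^4$.

Everything is driven by R's RNG. Traversal $k$ of direction $d$ reseeds at
$(2^{21}(seed+1) + (d-1)n_{events} + k) \bmod (2^{31}-1)$. The $2^{21}$
spacing matters: a plain $seed + k$ scheme makes two ensembles with nearby
base seeds share almost all member streams, which we found silently
correlates runs that analyses treat as independent.

## Numerical and design choices

- **Direct-method SSA.** The state space is tiny (≤ 100 sites), so the
  channel list is rebuilt each step; this keeps the engine model-agnostic
  and exact. The hot loop is compiled (Rcpp); a plain-R reference
  implementation of the same rules (`simple_events()`,
  `backtrack_events()`, `obstacle_events()`, `draw_next_event()`,
  `run_until()`) is exported and property-tested against the compiled
  enumeration on randomized states.
- **Blocked pushes.** A push that cannot displace the condensin (the bin
  beyond it holds an RNAP) suppresses the pushing hop, preserving single
  occupancy. The configuration is rare at gene-body density ~0.125.
- **Bypass semantics.** Default is a position exchange with the single
  blocking RNAP; `bypass_mode = "hop_over"` (landing past the contiguous
  block, rate set by the first blocker) is available for sensitivity
  analysis.
- **Initiation vs condensin.** The condensin never blocks initiation: an
  initiation with the condensin on bin 1 pushes it to bin 2, and is
  suppressed only if bin 2 carries an RNAP.
- **Boundary.** RNAPs keep elongating inside the termination zone and are
  removed when stepping past bin 100, which produces the decaying
  post-gene occupancy; any condensin move off the lattice (including by
  push) ends the traversal.
- **Shape statistics** (`termination_enrichment()`, `tilt_5prime()`,
  `fit_exponential()`) use frozen windows — termination window bins 20–25,
  gene-body window 5–15, gene halves 1–10 / 11–19 — fixed before looking
  at any simulated profile so the shape claims they operationalize stay
  non-circular. Note a consequence observed after freezing: a condensin
  waiting head-to-tail against the first termination-zone bRNAP sits at
  bin 19, just outside the termination window, so the window ratio
  understates a boundary-peaked profile.
- **Stationary estimates.** Occupancy-based statistics converge slowly
  (per-bin correlation times reach ~50 s in the tfs1DN-like regime), so
  flatness/tilt/share comparisons use long RNAP-only runs (20 000–100 000
  s) and, for between-preset contrasts, 12 independent replicates whose
  means are bootstrapped. These durations were sized from the estimator's
  standard error, not tuned to outcomes.

## The synthetic ChIP generator

`synthesize_track()` emulates the *structure* of normalized ChIP-qPCR
data so the model-vs-track comparison machinery is testable without any
external data: expected counts are `depth ×` the moving-average-smoothed
profile (default width 3 bins, emulating sonication-fragment blurring),
observed counts follow a counting-noise law with variance
$\lambda(1 + \phi\lambda)$ (Poisson at $\phi = 0$, negative binomial
otherwise), and `normalize_track()` rescales to an in-gene reference bin,
mimicking percent-IP normalization. The generator does **not** emulate
primer-specific efficiencies, input-normalization error, replicate
structure, or genomic background, so agreement between a model profile
and a synthesized track demonstrates that the comparison statistics
(rank correlation, enrichment difference) recover known shapes under
counting noise — not that the model fits real ChIP data.

## Known limitations

- One condensin at a time; no loading/unloading kinetics, no two-motor
  loop extrusion, no 3-D polymer geometry, no ATPase cycle.
- Whether a pushing RNAP can cascade the condensin through further RNAPs
  is unspecified in the source models; we suppress blocked pushes.
- The obstacle model's two toy occupancy profiles are illustrative
  stand-ins (smooth, strictly positive, mirror-symmetric about the
  lattice centre — the symmetry makes head-to-tail and space-reversed
  head-to-head residence profiles equal in distribution, which is the
  property the model is used to demonstrate).
- Rates are taken as given; the package deliberately does no fitting of
  rates to ChIP data.
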