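# condensinTASEP

Stochastic lattice models of condensin translocation through transcribed
genes, for chromosome-biology groups who want to test how RNA polymerase
(RNAP) dynamics — elongation, pushing, and especially backtracking — shapes
the distribution of a translocating SMC complex along a gene.

## The models

A 10-kbp locus is a 1-D lattice of 100 bins (100 bp each) carrying a 2-kbp
gene on bins 1–20; bins ≥ 20 form the termination zone. Three exactly
simulated (Gillespie) models share this geometry:

- **Simple model** — RNAP elongation is a totally asymmetric simple
  exclusion process (TASEP): initiation at the TSS at rate γ_init, hops at
  v_RNAP = 40 bp/s under mutual exclusion, unbinding at γ_term in the
  termination zone. A single condensin translocates at v_c = 1 kbp/s,
  passes a blocking RNAP only at a reduced bypass rate v_jump (1–15 bp/s),
  and can be pushed one bin toward 3' by a moving RNAP.
- **Backtrack model** — TASEP with pauses: each RNAP switches between a
  mobile state (mRNAP, hop rate v_RNAP, switches off at a position-
  dependent rate k_back(i), 200-fold higher in the termination zone) and a
  backtracked state (bRNAP, immobile, recovers at k_on, unbinds at γ_term
  in the zone). Condensin bypass depends on the blocker's state: 15 bp/s
  past an mRNAP, 0 past a bRNAP (it must wait).
- **Obstacle model** — immobile obstacles bind/unbind each bin (1-min mean
  lifetime, binding rate set by detailed balance to a target occupancy
  profile); condensin enters an obstacle-occupied bin at ~10 bp/s. Used as
  the direction-symmetry baseline.

The simulation protocol has two stages per ensemble member: an RNAP-only
burn-in to transcriptional steady state (stationary occupancy profiles),
then one condensin traversal — inserted at bin 1 (head-to-tail) or bin 100
(head-to-head) — until it exits the far side, recording the time spent at
each bin. Ensemble means of these per-bin times are the model's
counterpart of a condensin ChIP track.

## Worked example

```r
library(condensinTASEP)

plan <- make_wt_plan(n_events = 2000, seed = 42)  # backtrack model, WT-like
ens  <- run_ensemble(plan)
print(ens)
#> <condensin_ensemble> model = backtrack, n_events = 2000, seed = 42
#>   head_to_tail: mean transit 24.211 s, peak bin 19 (1.1394 s)
#>   head_to_head: mean transit 36.176 s, peak bin 21 (2.0563 s)
#>   gene-body RNAP occupancy: 0.1604

lat <- plan$lattice
termination_enrichment(ens$residence$head_to_head, lat)
#> 0.856
tilt_5prime(ens$occupancy, lat)
#> 1.114
```

A free condensin (no transcription) crosses 100 bins at 10 bins/s, so the
mean transit is 10 s; here transcription slows it to 24 s co-directionally
and 36 s head-on, and the residence profile peaks at bins 19–21 — the
condensin stalls against backtracked RNAPs at the start of the termination
zone, the model's account of the 3' condensin peak seen in vivo.
`termination_enrichment()` is the mean residence over bins 20–25 divided by
the mean over gene-body bins 5–15; `tilt_5prime()` compares the 5' and 3'
halves of the gene's RNAP occupancy. `summarize_ensemble()` collects these
statistics with bootstrap confidence intervals, and `synthesize_track()` /
`compare_shapes()` turn profiles into noisy ChIP-like tracks and score
model-vs-track shape agreement.

The tfs1DN-like preset (`make_tfs1dn_plan()`, k_on 0.2 → 0.02 s⁻¹) prolongs
backtracks tenfold: RNAP occupancy tilts 5'-ward, the backtracked share
rises ~10-fold, and condensin loses its termination-zone specificity.

A command-line front end is installed at
`system.file("scripts", "condensin-sim", package = "condensinTASEP")`:

```sh
Rscript inst/scripts/condensin-sim --preset wt --events 10000 --seed 1 \
        --direction both --out runs/wt
```

writing `occupancy.tsv`, `residence_{ht,hh,avg}.tsv`, `stats.tsv` and a
reproducibility manifest (TSV and/or bedGraph on the synthetic chromosome
`sim_locus`).

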