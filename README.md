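# ptpdyn

Post-processing toolkit for molecular-dynamics studies of catalytic-loop
dynamics in protein tyrosine phosphatases (PTPs) — SHP-1, SHP-2, PTP1B,
YopH and relatives.  PTP activity is gated by the mobile WPD-loop, which
swings between an open (inactive) and a closed (catalytic) conformation;
oncogenic substitutions remote from the active site alter catalysis by
perturbing the allosteric network that controls this motion.  `ptpdyn`
turns trajectories into the quantities such a study reports, for
computational enzymologists and structural bioinformaticians:

* **Conformational landscapes** — per-frame distance-RMSD of the full
  WPD×P C&alpha; pair set against a closed reference,

  dRMSD(t) = sqrt( (1/N) &Sigma;<sub>(i,j)</sub> (d<sub>ij</sub>(t) −
  d<sup>ref</sup><sub>ij</sub>)² ),

  WPD–P centre-of-mass separations, 2D occupancy histograms with
  open/closed anchors, and open / semi-closed / closed state labels.
* **Flexibility** — per-residue RMSF after iterated-mean superposition,
  and &Delta;RMSF between two systems (positive = first more flexible).
* **Correlated motions** — scalar dynamic cross-correlation maps
  C<sub>ij</sub> = &lang;&Delta;r<sub>i</sub>·&Delta;r<sub>j</sub>&rang; /
  sqrt(&lang;|&Delta;r<sub>i</sub>|²&rang;&lang;|&Delta;r<sub>j</sub>|²&rang;),
  restriction to structurally conserved regions shared across proteins,
  and dominant-mode (PCA) projections.
* **Allosteric networks** — shortest path maps (SPM): contact-gated
  residue graphs weighted w<sub>ij</sub> = −log|C<sub>ij</sub>|, pruned by
  normalized all-pairs shortest-path usage (all tied geodesics counted);
  SPM conservation between proteins; overlay of mutation hotspots
  (positions with ≥2 distinct substitutions) classified on-SPM / &lt;4 Å /
  ≥4 Å by closest heavy atom.
* **Reaction energetics** — empirical valence bond (EVB) free-energy
  profiles assembled from &lambda;-window diabatic energies by forward
  exponential averaging plus umbrella correction onto the coupled ground
  surface, activation/reaction free energies, replicate statistics
  (one-way ANOVA + Tukey HSD with significance stars), reactive-geometry
  clustering, and transition-state-theory conversion
  &Delta;G<sup>‡</sup> = RT·ln(k<sub>B</sub>T/(h·k<sub>cat</sub>)).

A synthetic-data module generates every input with analytic ground truth
(Gaussian ensembles with planted covariance, two-state Markov loop
switching, harmonic diabats sampled exactly, variant tables with planted
hotspots), so the full pipeline is testable without microsecond MD.

## Worked example

A two-state WPD-loop surrogate (closed occupancy 0.7, mean dwell 20
frames) classified on a landscape built from its own closed reference:

```r
library(ptpdyn)

p_loop <- matrix(c(0, 0, 0,  3.8, 0, 0,  7.6, 0, 0), ncol = 3, byrow = TRUE)
closed <- rbind(sweep(p_loop, 2, c(0, 6, 0), "+"), p_loop)
open   <- rbind(sweep(p_loop, 2, c(0, 12, 3), "+"), p_loop)

run <- gen_two_state_loop(two_state_loop_spec(
  open, closed, occupancy_closed = 0.7, mean_dwell = 20,
  jitter_sd = 0.25, n_frames = 10000, seed = 1))

bead <- function(m) coord_ensemble(as.vector(t(m)),
  data.frame(elety = "CA", resid = "ALA", resno = 1:6, chain = "A"))
wpd <- loop_definition("WPD", 1:3); pl <- loop_definition("P", 4:6)
ref <- build_reference(bead(closed), wpd, pl)

drmsd <- compute_drmsd(run$ensemble, ref)
com   <- compute_com_distance(run$ensemble, wpd, pl)
anchors <- list(
  closed = c(compute_drmsd(bead(closed), ref),
             compute_com_distance(bead(closed), wpd, pl)),
  open   = c(compute_drmsd(bead(open), ref),
             compute_com_distance(bead(open), wpd, pl)))
table(classify_states(drmsd, com, anchors))
#> closed   open
#>   6911   3089
```

The recovered closed fraction (0.6911) matches the generator's stationary
occupancy 0.7 within the Markov-chain standard error, and every frame is
labelled consistently with the hidden state sequence.  The EVB stage
recovers analytic barriers from synthetic window energies:

```r
spec <- harmonic_diabat_spec(k_force = 100, x1 = 0, x2 = 1, dG0 = -2,
                             H12 = 1, frames_per_window = 5000, seed = 2)
prof <- gap_profile(gen_evb_windows(spec), n_bins = 200)
prof
#> free_energy_profile: dG_act = 10.68, dG_rxn = -2.02 kcal/mol (200 bins)
analytic_adiabatic_profile(spec)[c("dg_act", "dg_rxn")]
#> $dg_act ~ 10.54   $dg_rxn ~ -2.00
tst_barrier(1, 300)
#> [1] 17.57  # kcal/mol for kcat = 1/s at 300 K
plan_accounting(default_study_plan())$cumulative_us
#> [1] 399    # microseconds across the reference MD campaign
```

A thin command-line wrapper over the same functions lives at
`inst/cli/ptpdyn.R` (subcommands `synth`, `landscape`, `rmsf`, `dccm`,
`spm`, `variants`, `evb`, `stats`, `plan`, `identity`), driven by a YAML
config with `--config/--seed/--out` overrides.

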