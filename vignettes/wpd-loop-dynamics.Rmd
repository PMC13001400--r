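---
title: "Loop dynamics, allosteric networks and EVB energetics in protein tyrosine phosphatases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop dynamics, allosteric networks and EVB energetics in protein tyrosine phosphatases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptpdyn)
```

## The scientific problem

Protein tyrosine phosphatases (PTPs) share a conserved catalytic domain
whose activity is gated by a mobile loop, the WPD-loop, carrying the
general-acid aspartate.  The loop interconverts between an open (inactive)
and a closed (catalytically competent) conformation, and the kinetics of
that interconversion — not active-site chemistry — explains much of the
orders-of-magnitude spread in PTP turnover numbers.  In SHP-1 and SHP-2,
oncogenic substitutions far from the active site perturb catalysis by
rewiring the allosteric network that controls WPD-loop motion.

`ptpdyn` implements the post-processing layer of such a study: given MD
trajectories (or synthetic surrogates with known ground truth), it builds
loop conformational landscapes, flexibility and correlation profiles,
shortest-path-map allosteric networks with mutation-hotspot overlays, and
empirical valence bond (EVB) free-energy profiles.  It does **not** run MD
or EVB sampling; trajectories, variant tables and window energies are
inputs.

## Conformational landscape metrics

**dRMSD.** For a WPD-loop of residues $W$ and P-loop of residues $P$, a
reference (closed) structure defines the table
$d^{\mathrm{ref}}_{ij}$, $i \in W$, $j \in P$, of C$\alpha$–C$\alpha$
distances over the full cross product.  A frame's metric is
$$\mathrm{dRMSD}(t) = \sqrt{\tfrac{1}{N}\sum_{(i,j)} \big(d_{ij}(t) -
d^{\mathrm{ref}}_{ij}\big)^2},$$
built from internal distances only, hence exactly invariant to rigid-body
motion (no superposition is performed, and the tests rotate frames 100
times to prove it).  Two open readings of "all combined distances" exist:
the cross-product reading is the default, and `intra_loop = TRUE` adds all
pairs within the union of both loops.  We divide by $N$ (root *mean*)
rather than using the root sum so values are comparable across loops of
different lengths; the convention is recorded with the reference set.
When the trajectory protein differs from the reference protein, residues
map through an `alignment_map`; an unmappable pair aborts the calculation,
because silently shrinking $N$ would rescale the metric.

**Landscapes and states.** The per-frame (dRMSD, WPD–P centre-of-mass
distance) pairs are binned into a 2D occupancy histogram whose total count
always equals the frame count (out-of-range points are clamped into edge
bins, never dropped).  Anchor points are the same two metrics evaluated on
the open and closed reference structures.  Frames are labelled
closed/semi-closed/open by distance to the anchors in anchor-normalised
coordinates; the radii default to 25 % of the inter-anchor distance
because published landscapes mark anchors but print no cutoffs — the
radii are parameters, recorded in output, and the defaults recover
generator ground truth with $\ge 99\,\%$ accuracy on two-state synthetic
loops.

**RMSF.** $\mathrm{RMSF}_i = \sqrt{\langle |r_i(t) - \langle r_i \rangle
|^2\rangle}$ over C$\alpha$ atoms after least-squares superposition onto
the iterated mean structure (two passes, the usual practice; one pass and
no-fit variants remain available for oracle tests).  The superposition
selection defaults to the whole C$\alpha$ set; a domain-core selection can
be passed instead when termini artifacts matter.
$\Delta\mathrm{RMSF}_i = \mathrm{RMSF}_i(a) - \mathrm{RMSF}_i(b)$ is
positive where the first system is more flexible.

**Reactive conformations.** A frame is productive for the hydrolysis step
when every configured atom-pair distance is *strictly* below its cutoff
("less than", so boundary values fail).  The default criteria are the
PTP phosphoenzyme-intermediate ones in SHP-1 numbering: general-acid
carboxylate O (Asp419) within 4.5 Å of the phosphocysteine phosphorus and
Gln500 side-chain C within 8 Å of the same phosphorus.

## Correlated motions and the shortest path map

The dynamic cross-correlation map is the scalar form
$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}},$$
the quantity standard trajectory tools produce on a $[-1, 1]$ scale.
Superposition (default on) removes rigid-body drift that would otherwise
inflate correlations; replicas are superposed independently and then
concatenated.  Zero-variance residues get zeroed rows with a warning
rather than NaNs.  A subsampling stride is a parameter because published
maps rarely state one.  Cross-protein comparison keeps only positions
mapped in *every* protein (so map edges are not protein termini; retained
ids are recorded), and the restriction is idempotent.

The SPM graph places an edge between residues in contact (mean
C$\alpha$–C$\alpha$ distance below 6 Å, the published convention for this
method) with weight $w_{ij} = -\log|C_{ij}|$.  The absolute value keeps
anti-correlated contacts as communication carriers — in YopH the
loop–helix couplings flip sign — with the sign kept as metadata.  Edge
usage counts **all** tied shortest paths via igraph's
`all_shortest_paths`, not one arbitrary geodesic, so usage is
deterministic under ties; tests verify exact agreement with exhaustive
simple-path enumeration on every fixture up to 7 nodes.  Usage is
normalised to the maximum edge; pruning keeps edges at or above a
threshold (default 0.3, a parameter recorded in output — no published
pruning rule exists, and nothing downstream depends on the default).
SPM conservation between proteins maps SPM residues through an alignment
and reports both directions, since the measure is asymmetric.

Oncogenic hotspots are positions with at least two *distinct*
substitutions (report counts are metadata, not evidence).  Against the
SPM they classify as on-SPM (distance 0 by convention), near
(closest heavy-atom distance $< 4$ Å, strict) or far ($\ge 4$ Å);
hydrogens are excluded because the crystal structures used for such
overlays typically lack them.  Positions missing from the structure are
reported unclassifiable, never dropped.

## EVB free-energy assembly

Two diabatic states with energies $\epsilon_1, \epsilon_2$ are mixed by
the mapping potential $E_m = (1-\lambda_m)\epsilon_1 +
\lambda_m\epsilon_2$ over a $\lambda$ grid (51 windows by default, the
standard protocol).  Window free energies accumulate by forward
exponential averaging,
$$\Delta G(\lambda_{m+1}) = \Delta G(\lambda_m) - k_BT
\ln\langle e^{-(E_{m+1}-E_m)/k_BT}\rangle_m,$$
the classic EVB mapping estimator; a bidirectional variant exists as a
hysteresis diagnostic, and a warning fires when the exponential average's
effective sample size degrades below 10 (and below half the window).
Frames are then binned on the gap coordinate $x = \epsilon_1 -
\epsilon_2$ and umbrella-corrected onto the ground surface
$E_g = \tfrac{1}{2}(\epsilon_1+\epsilon_2) -
\tfrac{1}{2}\sqrt{(\epsilon_1-\epsilon_2)^2 + 4H_{12}^2}$
with constant coupling $H_{12}$ supplied per system (EVB parameters are
inputs, never baked in).  Multi-window contributions to a bin combine by
sample-count weighting; the reactant minimum is shifted to exactly zero.

Numerical choices: the bin range trims 0.5 % tails of the gap
distribution; stationary points are located on a 3-bin moving-average
smoothed profile (robust to bin noise) and refined on the raw profile;
the reactant state sits on the low-gap side where diabat 1 dominates.
The display default is 50 bins, but for **barrier extraction** we use 200
bins: with harmonic diabats the gap spans $\mathcal{O}(k\,\Delta x \cdot
\mathrm{range})$, and at 50 bins the width ($\approx 3$ kcal/mol here)
averages over the barrier-top cusp of the $H_{12}=0$ surface and biases
$\Delta G^\ddagger$ low by $\sim 0.5$ kcal/mol; at 200 bins the bias is
below 0.1 kcal/mol across the validation grid while per-bin counts stay
in the hundreds.  Empty interior bins are interpolated with a warning;
fewer than three occupied bins is an error.

Replicate barriers are compared by one-way ANOVA followed by Tukey's HSD
(the studentized-range distribution, via `stats::aov` and
`stats::TukeyHSD`), starred `*` for $p<0.05$ and `**` for $p<0.01$;
unequal variances are noted, not rejected.  Experimental rate constants
convert through transition state theory,
$\Delta G^\ddagger_{\exp} = RT\ln\!\big(k_BT/(h\,k_{\mathrm{cat}})\big)$,
with transmission coefficient 1 and $RT$ in kcal/mol
($k_B T/\hbar$-scale prefactor, so $k_{\mathrm{cat}} = k_BT/h$ maps to
exactly zero).  Reactive geometries cluster by average-linkage
agglomerative clustering on pairwise-superposed heavy-atom RMSD, with
medoid representatives.

## What the synthetic generators emulate — and what they do not

The generators replace microsecond MD with processes whose ground truth
is analytic, so every stage can be validated end to end:

* `gen_gaussian_ensemble` — equilibrium fluctuations with prescribed
  inter-residue covariance.  Sample DCCM entries converge to the planted
  correlations at the $3/\sqrt{n}$ rate.
* `gen_two_state_loop` — open/closed switching as a two-state Markov
  chain parameterised by stationary closed occupancy and mean closed
  dwell (the simplest process with tunable autocorrelation, mimicking
  slow loop interconversion), plus isotropic positional jitter.  The
  chain's lag-1 autocorrelation feeds Markov-aware standard errors for
  occupancy recovery tests.
* `gen_evb_windows` — harmonic diabats with a *common* force constant,
  which makes every mapping potential exactly quadratic: window samples
  are exact Gaussian draws, so no sampler error contaminates the
  free-energy oracle, and the adiabatic barrier has a closed/bracketed
  analytic value (Marcus $\lambda_{\mathrm{reorg}}/4$ in the symmetric
  uncoupled case).
* `gen_variant_table` — COSMIC-export-like substitution tables with
  planted hotspots.

Seeds are explicit spec fields and generation never touches the global
RNG stream, so parallel tests cannot interfere.  What these surrogates
deliberately lack: anharmonicity, solvent and force-field physics,
multi-state kinetics beyond two states, correlated jitter, and any
realistic protein geometry.  Passing tests therefore demonstrate that the
*estimators* are correct and converge at the expected statistical rates —
not that any MD-derived biological conclusion is reproduced.  The study's
landscape shapes, DCCM patterns, SPM layouts and barrier orderings derive
from hundreds of microseconds of sampling and are out of desk-scale
reach by design.

## Validation problem sizes

The test suite exercises: planted-correlation DCCM recovery on
50,000-frame ensembles over 10 seeds (tolerance $3/\sqrt{n}$); two-state
occupancy recovery on 10,000 frames within 3 Markov-chain standard
errors; EVB barrier/reaction free-energy recovery on 51 windows × 5,000
frames across a 3×3 grid of ($\Delta G_0$, $H_{12}$) within 0.3 kcal/mol
of the analytic surface; SPM usage against exhaustive enumeration on all
fixtures up to 7 nodes; and exact arithmetic oracles for dRMSD, COM
distances, reactive filtering, plan accounting and TST conversion.  These
sizes were chosen so statistical tolerances are comfortably resolved by
the expected estimator variance.

## Known limitations

* Sequence identity depends on the alignment; the internal global aligner
  (BLOSUM62, gap open 10 / extend 0.5, identity over alignment length
  excluding terminal gaps, internal gaps as mismatches) reproduces common
  aligner conventions but not any specific external tool — supply that
  tool's alignment via `given_alignment` for exact reproduction, and note
  that published catalytic-domain identities also depend on unstated
  domain boundaries, which are inputs here.
* Residue numbering is the author numbering of the input file and is
  never renumbered; variant tables and structures must share a numbering
  (SHP-1 numbering in particular varies across sources).
* `shortest_path_map` recomputes all-pairs shortest paths exactly; on
  graphs beyond a few thousand edges this is the slow step.
* Hotspot counts from public mutation databases are snapshot-dependent;
  the package reports its own counts with provenance and makes no attempt
  to reproduce any dated tally.
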