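---
title: "Calling folding kinetics from coarse trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling folding kinetics from coarse trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`foldq` reads a folding trajectory through one summary statistic: the
fraction of native contacts *Q* between pairs of secondary-structure
elements (SSEs). The underlying picture of folding is hierarchical —
secondary structure forms first and tertiary contacts between elements
assemble afterwards — so the *unit* of analysis is the SSE pair, not the
residue. A pair's *Q* series answers "when do these two elements dock?",
and the collection of docking times answers "does the chain fold in one
step or several?".

The statistical chain is:

1. **Native contacts.** Residues are reduced to their Cβ bead (Cα for
   glycine). Two residues in *different* SSEs are in native contact when
   their native-structure distance is strictly below the cutoff (8.0 Å).
   Elements shorter than 4 residues are discarded first: a 3-residue
   "helix" contributes more annotation noise than signal.
2. **Q series.** A contact of native distance *d* counts as formed in a
   frame when the frame distance is at most *ξ·d* (*ξ* = 1.2). The
   multiplicative tolerance absorbs thermal-scale fluctuation without a
   second absolute threshold.
3. **Transition times.** *Q* is differentiated by finite differences
   (central in the interior, one-sided at both ends) and the derivative is
   smoothed with Friedman's supersmoother; the argmax is the pair's
   transition time *t\**, reported as a fraction of the trajectory.
   Differentiate-then-smooth, in that order; the one-sided endpoints let a
   trajectory that starts near-native place its transition at frame 0
   instead of being silently truncated, and argmax ties resolve to the
   earliest frame (a folding event *starts*).
4. **Phase clustering.** A Gaussian KDE with Scott's-rule bandwidth
   *h* = σ̂·*m*^(−1/5) is evaluated on a 512-point grid over [0, 1]. Local
   maxima above a relative prominence threshold are folding phases; density
   minima between adjacent peaks partition the pairs. One peak means
   two-state; several mean multistate, and the pairs assigned to the first
   peak define the first-intermediate contact vector.

Per-protein aggregation is the fraction of two-state decoys, thresholded at
50% (inclusive on the multistate side) for the unsupervised call, or fed as
a continuous score to AUROC and to a logistic regression under repeated
stratified five-fold cross-validation for the supervised metrics.

## Parameters that matter

| parameter | default | unit | why this value |
|---|---|---|---|
| `cutoff` | 8.0 | Å | Cβ–Cβ contact definition customary in coarse-grained native-contact analyses |
| `xi` | 1.2 | – | fluctuation tolerance; a formed contact may breathe to 120% of its native distance |
| `min_sse_len` | 4 | residues | shorter STRIDE-style elements are annotation noise |
| `activity_threshold` | 0.2 | ΔQ | a pair whose Q range never exceeds 0.2 has no folding signal; its argmax would be noise-driven |
| `grid_points` | 512 | – | KDE grid resolution; also floors the bandwidth at 1/512 so σ̂ = 0 stays finite |
| `min_prominence` | 0.15 | fraction of max density | see calibration below |
| `n_boot` | 100 000 | – | bootstrap replicates for the AUROC-vs-random test |
| `cv_repeats` × `folds` | 1000 × 5 | – | repeated stratified CV for supervised metrics |

The activity filter is not part of the core statistical chain but is
necessary in practice: pairs formed from frame 0 (compact starting
conformations) otherwise contribute an arbitrary transition time.

### Calibrating the peak threshold

Peak counting needs a prominence rule — "two or more peaks" is not
operational until one says how small a density wiggle still counts. The
package's rule: a local maximum is a phase only if its topographic
prominence is at least `min_prominence` of the global density maximum,
where a flank that runs off the [0, 1] grid without meeting higher density
contributes a base of zero (the density keeps decaying outside the domain,
so edge peaks are not penalized by grid truncation). The default 0.15 is
calibrated on the synthetic generator so that a single-phase trajectory
yields exactly one peak in ≥ 99% of seeded runs while two-phase schedules
at the generator's gap range are still recovered in ≥ 98% of runs. Smaller
values admit straggler transition times as spurious phases; larger ones
start to merge genuine phases on small proteins.

### Why protein size matters

Scott's rule ties the bandwidth to the *number of SSE-pair transition
times m*. For two docking phases separated by *D* with balanced clusters,
σ̂ ≈ *D*/2 and so *D*/*h* ≈ 2·*m*^(1/5) — scale-free in *D* and growing
only with the fifth root of *m*. Around *m* = 4 the density is barely
bimodal for any gap; from *m* ≈ 8 (six-plus elements) phases separate
cleanly. This is an intrinsic property of the method, not of the
generator, and it bounds the protein sizes on which multistate calls are
trustworthy. The synthetic benchmark therefore defaults to chains of
54–103 residues (8–15 elements).

## The synthetic generator

`make_native()` lays rigid rods of beads (3.8 Å spacing, the Cα virtual
bond) on a two-column grid 6 Å apart, joined by 2-residue linkers, so that
grid-neighbouring rods share native contacts under the 8 Å cutoff.
`simulate_trajectory()` starts every element displaced 50 Å along a random
direction (directions kept ≥ 20 Å apart in displacement space, so the
start has no native contacts) and translates it rigidly to its native pose
with a logistic ramp centred at its phase group's docking time τ and width
*w* (default 0.03 of the trajectory; the ramp is ~98% complete within ±*w*
and snaps exactly to the native pose at its tail). Each residue receives an
individual docking offset (sd *w*/2): elements zip into place over ~*w*
instead of snapping in a single frame. Without this, all contact formation
compresses into the last Ångström of approach, *Q* becomes a 1–2-frame
step, and the supersmoother localizes the resulting derivative spike
unstably — an artefact of step-like input, reproducible with the reference
`stats::supsmu` as well. Isotropic Gaussian noise (default 0.2 Å) is added
to every coordinate.

`make_benchmark()` assembles a cohort: lengths uniform in 54–103 residues,
kinetics class drawn from a logistic model on centred length (log-odds
slope `coupling` toward multistate, intercept solved so the expected
two-state share is `p_two_state`), single-phase docking times τ ~ U(0.3,
0.7), two-phase times τ₁ ~ U(0.15, 0.3) and τ₂ ~ U(0.65, 0.85) (gap ≥
0.35), first phase group of ⌊*n*/2⌋+1 elements (balancing the SSE-pair
counts of the two phases for the ladder contact topology), ln *k*<sub>f</sub>
= *a* + *b*·τ_onset + ε, per-decoy schedule jitter, optional decoy class
flips, and HDX-style vectors equal to the planted first-intermediate
vector of multistate proteins. Every decoy draws its own recorded sub-seed
from (master seed, protein id, decoy index).

What the generator does **not** emulate: rotational diffusion,
intra-element unfolding, misfolded or off-pathway excursions, back-and-forth
recrossing of the transition region, compact starting states, and any
particular search heuristic of a real structure predictor. Green tests
therefore certify the *analysis machinery* — that planted phase structure
is recovered under coordinate noise — not performance on real predictor
trajectories, whose pathologies are exactly the interesting open question.

## Numerical choices

* **Supersmoother.** Implemented natively: three candidate spans (0.05,
  0.2, 0.5 of *n*), symmetric windows truncated at the series ends,
  leave-one-out cross-validated absolute residuals (closed-form leverage)
  smoothed at the midrange span select a per-point span, selected spans are
  themselves smoothed, fitted values are interpolated between bracketing
  candidate fits, and the result passes once more through the smallest
  span. `bass` (0–10) shifts the choice toward the largest span. Fixed-span
  mode is a single pass and is verified against a brute-force per-window
  `lm()` oracle at 1e-8; series shorter than 10 points fall back to one
  span-0.3 fit, flagged via attribute. The variable-span fit is
  cross-checked against `stats::supsmu` on smooth signals in the test
  suite.
* **Bandwidth floor.** *h* ≥ 1/`grid_points`, so a degenerate sample (all
  *t\** identical, or a single included pair) still yields a one-peak
  density rather than a division by zero.
* **Onset.** Defined as the minimum included *t\** (the event's start); an
  alternative `first_peak` definition (first mode minus one bandwidth) is
  kept as a config option since "where folding starts" admits both
  readings.
* **Contact tolerance.** Frame distances are compared against
  (ξ·d)²·(1+1e-9), so a frame equal to the native structure to machine
  precision counts as formed even at ξ = 1.
* **Jaccard(∅, ∅) = 1.** Two all-zero binary vectors agree perfectly;
  the convention keeps all-zero predictions comparable.
* **HDX mapping.** Experimental protection is annotated per element; the
  package compares per *pair*, marking a pair observed-formed iff both its
  elements are structured in the intermediate. This mapping is a package
  decision — the conservative reading of element-level protection.
* **Contact order.** Reuses the pipeline's inter-element Cβ contact set
  (sequence separations over chain length × contact count) rather than the
  classic all-heavy-atom 6 Å definition, so one contact definition serves
  the whole pipeline; absolute RCO values are therefore not directly
  comparable to literature values, rank correlations are.
* **Supervised feature.** The logistic regression regresses on the
  *continuous* fraction of two-state decoys by default (`cv_feature =
  "binary"` switches to the thresholded call); the continuous score
  strictly generalizes the binary rule.
* **Permutation scheme.** Classifiers compared on the same proteins are
  paired, so the null swaps the two scores per protein with probability ½;
  the statistic is the AUROC difference, two-sided.

## Problem sizes

The test suite validates recovery at 50 proteins × 20 decoys per kinetics
class (200-frame decoys, 0.2 Å noise), rate-sign recovery at 100 proteins
× 3 decoys, and null calibration at 40 proteins × 8 decoys plus 1000
uniform-score draws on a 90/80 cohort; statistical-test replicates are
scaled to a few hundred per test, with the full defaults (100 000
bootstrap, 1000×5 CV) exercised at reduced replicate counts. These sizes
are the package's validation choices: large enough for the binomial bands
asserted, small enough to run on a laptop in minutes.

## Limitations

* Multistate resolution degrades below ~8 SSE elements (see the bandwidth
  discussion); on small proteins the method is biased toward two-state.
* Scott's rule assumes roughly Gaussian clusters; heavily skewed transition
  time distributions can merge or split phases.
* The supersmoother's argmax on near-step inputs carries a systematic early
  bias of a few frames; comparisons across trajectories (ranks,
  correlations) are unaffected, absolute onsets inherit it.
* Only translation-based docking is simulated; the generator cannot
  emulate trajectories whose contacts form and break repeatedly, and no
  claim about real predictor trajectories follows from synthetic recovery
  alone.
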