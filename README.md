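# foldq

Folding-pathway kinetics from coarse protein trajectories, via the fraction
of native contacts between secondary-structure elements.

## The problem

Experimental refolding studies classify proteins as **two-state folders**
(one concerted transition, no populated intermediate) or **multistate
folders** (one or more intermediates). Given a coarse folding trajectory —
an ordered series of one-bead-per-residue conformations for a protein whose
native structure is known — `foldq` decides which regime the trajectory
exhibits, locates the folding phases, extracts the intermediate's contact
topology, and scores all of this against reference data: formal kinetics
labels, folding rate constants (ln *k*<sub>f</sub>) and hydrogen–deuterium
exchange (HDX) annotations of intermediate structure. It is aimed at anyone
who wants to ask whether simulated or predicted "folding" trajectories carry
real kinetic information.

## The method

For a native structure with secondary-structure elements (SSEs, helices and
strands of ≥ 4 residues), two residues are in **native contact** when their
Cβ atoms (Cα for glycine) are closer than 8.0 Å. For each SSE pair (*i*,
*j*) and trajectory frame *t*,

&nbsp;&nbsp;&nbsp;&nbsp;*Q<sub>ij</sub>(t)* = fraction of the pair's native
contacts with frame distance ≤ *ξ·d*<sub>native</sub>, with flexibility
multiplier *ξ* = 1.2.

The per-pair **transition time** *t\** is the maximum of the
finite-difference derivative of *Q<sub>ij</sub>* after smoothing with
Friedman's supersmoother. A Gaussian kernel density estimate over all
*t\**, with Scott's-rule bandwidth *h* = σ̂·*m*<sup>−1/5</sup>, clusters the
transitions into phases: **one density peak ⇒ two-state, two or more ⇒
multistate**, and the pairs assigned to the first peak form the predicted
first-intermediate contact vector. Downstream evaluation uses balanced
accuracy, F1, Mann–Whitney AUROC, Jaccard similarity, relative contact
order, Spearman correlation with ln *k*<sub>f</sub>, repeated stratified
cross-validated logistic regression, and bootstrap/permutation significance
tests against random and chain-length baselines.

Because real trajectory generators (structure-prediction pipelines) are far
beyond desk scale, the package ships a synthetic generator
(`make_native()`, `phase_schedule()`, `simulate_trajectory()`,
`make_benchmark()`) that plants known phase schedules, length–class
couplings, rate-constant models and HDX vectors, so every stage can be
validated against ground truth.

## Worked example

Simulate one decoy of a two-phase folder (five elements dock at 25% of the
trajectory, three more at 70%) and analyze it:

```r
library(foldq)

nat   <- make_native(n_elements = 8, element_len = 5, spacing = 6, seed = 1)
sched <- phase_schedule(
  setNames(c(1L,1L,1L,1L,1L,2L,2L,2L), nat$sse$element_id),
  group_times = c(0.25, 0.70), transition_width = 0.03)
sim   <- simulate_trajectory(nat$structure, nat$sse, sched,
                             n_frames = 200, noise_sd = 0.2, seed = 7)

contacts <- native_contacts(nat$structure, nat$sse, cutoff = 8.0)
call     <- analyze_trajectory(sim$trajectory, contacts)
call
#> <fq_kinetics_call> multistate: 2 peak(s) at 0.313, 0.701; onset 0.271; h = 0.1353
tidy(call)
#> # A tibble: 2 x 4
#>    peak position height n_pairs
#>   <int>    <dbl>  <dbl>   <int>
#> 1     1    0.313   1.44       5
#> 2     2    0.701   1.46       5
```

The call is **multistate**: the ten SSE-pair transition times cluster into
two KDE peaks near the planted docking times (0.25 and 0.70), with five
pairs docking in each phase; the folding event starts at 27% of the
trajectory, and the Scott bandwidth used was 0.135. The predicted
first-intermediate vector matches the planted one exactly:

```r
truth <- sim$truth$intermediate_vectors[[1]]
jaccard(intermediate_vector(call)[names(truth)], truth)
#> [1] 1
contact_order(contacts)
#> [1] 0.2419...   # relative contact order of the toy native structure
```

`autoplot(call)` draws the transition-time density with its peaks;
`autoplot()` methods also exist for Q series, sweeps and onset–rate plots.
Cohort-scale runs go through `make_benchmark()` → `benchmark_calls()` →
`run_evaluate()` (or the disk-based `run_simulate()` / `run_analyze()`
pipeline with per-decoy JSON records and resumability).

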