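---
title: "Methods: modelling the PhoR/PhoB phosphate starvation response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the PhoR/PhoB phosphate starvation response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the numerical methods, and the study
protocols implemented in `phoregulon`, including the rationale for every
problem size used by the heavier stochastic and calibration studies.
Code chunks are shown but not evaluated at build time; all of them run
as written.

## The model

Under inorganic-phosphate (Pi) starvation, the *Escherichia coli* sensor
kinase PhoR autophosphorylates and transfers phosphoryl groups to the
response regulator PhoB. Phosphorylated PhoB dimerises into the active
transcription factor, which binds the PhoA and PhoB promoters and drives
expression of the Pho regulon, including alkaline phosphatase (PhoA),
the standard expression readout. PhoR is bifunctional: its
unphosphorylated dimer acts as a phosphatase on PhoB-P, closing the
cycle.

The package encodes this as a mass-action chemical reaction network with
16 species and 29 reactions:

* **Autophosphorylation** (R1, R2, reversible): the PhoR dimer `DiPhoR`
  is phosphorylated in two steps to `DiPhoRp` and `DiPhoRpp`. The
  forward rates r1/r2 are the model's proxy for external Pi: starvation
  corresponds to their control values, higher external Pi to fold
  factors below one.
* **Phosphotransfer** (R3-R6): `DiPhoRpp` and `DiPhoRp` bind `PhoB`
  into transient complexes (`C_RppB`, `C_RpB`, reversible) that release
  phosphorylated `PhoBp`.
* **Dimerisation** (R7, reversible): two `PhoBp` form the active
  transcription factor `DiPhoBpp`.
* **Phosphatase branch** (R8, R9): `DiPhoR` binds `PhoBp` (`C_RBp`) and
  dephosphorylates it.
* **Promoter binding** (R10, R11, reversible): `DiPhoBpp` converts the
  inactive promoters `pPhoA`/`pPhoB` (10 genomic copies each) into the
  active forms `pPhoAa`/`pPhoBa`.
* **Expression** (R12-R16, catalytic): active promoters transcribe
  `mRNAa`/`mRNAb`; `mRNAa` translates into `PhoA`, `mRNAb` into both
  `PhoB` and `DiPhoR` (the autoregulatory feedback on the sensor and
  regulator pools).
* **Degradation/dilution** (R17-R21): first-order decay of the three
  proteins and both transcripts. Promoters and phosphotransfer
  complexes do not decay, which makes each promoter's total copy number
  a structural invariant: every stoichiometric column satisfies
  `S[pPhoA, ] + S[pPhoAa, ] = 0` (and likewise for pPhoB).

`default_rates()` carries the control value, units, literature bounds
(where a physiological range is known) and a provenance tag for each of
the 29 rate constants. `write_network_json()` dumps the full network as
a plain-text interchange document; an SBML exporter is out of scope
because no SBML binding is available in the supported R stack.

## Units and volume

Concentrations are in micromolar, time in seconds. A cytoplasmic volume
of 1 cubic micrometre (the conventional *E. coli* cell volume) gives the
conversion factor `omega = 602.214076` molecules per uM, so one molecule
corresponds to 0.00166 uM — which is exactly the initial condition used
for each transcript (one mRNA molecule per cell). Promoters start at
10 copies, i.e. `10 / omega` uM. `concentration_to_count()` rounds half
away from zero and `count_to_concentration()` inverts it exactly on
integer counts.

## Deterministic engine

`simulate_ode()` integrates `dy/dt = S v(y)` with `deSolve::lsoda`. The
network couples promoter binding at 1e4 per uM per second to protein
decay at 1e-4 per second — eight orders of magnitude — so a
stiff-capable method with tight tolerances (rtol 1e-8, atol 1e-12 uM) is
required; looser settings visibly distort the sub-micromolar transient
species. The default horizon is the 4.5 h starvation window
(16 200 s) sampled every 10 s. Sub-tolerance negative excursions are
clipped to zero; anything below -1e-9 uM aborts.

The full control run takes about 0.16 s, which is why the deterministic
scans below use full horizons throughout.

## Stochastic engine

`simulate_ssa()` implements the exact Gillespie direct method in C++
over molecule counts. Deterministic rate constants convert to
stochastic ones as `c = k` (unimolecular), `c = k / omega`
(heterobimolecular) and `c = 2 k / omega` with the combinatorial factor
`n (n - 1) / 2` (the PhoBp homodimerisation), so the SSA propensities
reproduce the mass-action velocities in the large-volume limit
(`propensity()` exposes this per reaction). The induced network cycles
phosphoryl groups at over 1e5 events per simulated second and rises
above 1e6 as protein pools grow, so the inner loop uses sparse state
updates, a reaction dependency graph with an incrementally maintained
total propensity, and a xoshiro256++ generator seeded from R's RNG —
`set.seed()` fully determines a trajectory, and `run_ensemble()` gives
replicate `i` the seed `base_seed + i` so ensembles are reproducible
and order-independent. Throughput is roughly 1.8e7 events per second on
one CPU; a full-horizon control trajectory (~3e10 events) is therefore
deliberately *not* the unit of stochastic experimentation here.

## Noise study protocol

`unbinding_noise_study()` quantifies how the transcription-factor
unbinding rate (r10r = r11r at 100, 1000 or 5000 per second) shapes
expression noise. Protocol, with sizes chosen by this package:

1. Integrate the deterministic model (with the modified unbinding rate)
   to `anchor_time = 450` s — a mid-induction operating point at which
   promoter occupancy has long equilibrated (promoter kinetics relax in
   milliseconds) and mRNA is near its plateau.
2. Discretise the state to counts, keeping each promoter total at
   exactly 10 copies, and draw each replicate's mRNA counts from a
   Poisson law at the deterministic mean. Poisson is the stationary law
   of the transcription/decay birth-death motif, so the ensemble starts
   essentially at stationarity and needs almost no stochastic burn-in.
3. Run 100 replicates for 40 s each and pool the samples of the window
   10-40 s (1 s grid) across replicates; report sd/mean per species via
   `noise_ratio()`.

The short window is a cost decision, not a statistical one: fluctuation
statistics converge through the 100-replicate ensemble, while the
fully induced network burns millions of events per simulated second,
so long single runs would dominate the budget without adding
independent information (the mRNA autocorrelation time, 1/r20 = 182 s,
exceeds any affordable window anyway). Expected behaviour, and what we
actually resolve:

* Active-promoter noise (`pPhoAa`, `pPhoBa`): occupancy is binomial-like
  with `p = k_on [TF] / (k_on [TF] + k_off)`; raising `k_off` lowers `p`
  and raises the CV sharply. The ordering across 100/1000/5000 per
  second is large (roughly 0.02 / 0.06 / 0.18) and reproduces robustly.
* Transcript noise (`mRNAa`, `mRNAb`): promoter switching at >= 100 per
  second is four to five orders of magnitude faster than mRNA turnover,
  so switching noise is filtered almost completely and transcript noise
  stays near Poisson, `CV = 1 / sqrt(mean)`. The CV rises at 5000 per
  second mainly because mean occupancy (hence mean mRNA) drops, while
  the 100 -> 1000 step changes the expected CV by only ~1-2% — below
  Monte-Carlo resolution at any affordable ensemble size. A strict CV
  ordering for transcripts between 100 and 1000 per second is therefore
  not statistically decidable with this (or any desk-scale) protocol,
  and results for that comparison should be read as "equal within
  error".

## Calibration

`fit_rates()` estimates free rate constants from PhoA (and optionally
PhoB) reporter time courses by bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`):

* **Log-parameterisation.** The rates span eight decades, so
  optimisation runs in log10 space with box bounds from the literature
  ranges (rates with only an upper limit get `value/100` as the lower
  bound; unconstrained rates get `value/100` to `value*100`).
* **Tie groups.** Symmetric rates share one optimisation variable
  (r1/r2, r1r/r2r, the four complex dissociation rates, r4/r6), which
  both reflects the model's symmetry and removes trivially redundant
  directions; see `default_free_groups()`.
* **Residuals.** Each observable contributes
  `(s * model - observed) / max(observed)`, putting PhoA and PhoB on
  comparable scales. With `scale_mode = "fit"` the linear gain `s` is
  profiled analytically (`s = sum(m y) / sum(m^2)`) at every
  evaluation, which makes the fit exactly invariant to rescaling an
  observable — appropriate for fluorescence in arbitrary units.
* **Multi-start.** Starts are sampled log-uniformly within the bounds
  from a fixed seed; the best converged start wins, and the per-start
  record is kept in the result.
* **Derivative steps.** The optimiser's forward-difference Jacobian
  uses a step of about 1e-3 log10 units (`epsfcn = 1e-6`) and the ODE
  is solved at rtol 1e-9 during fitting. These two settings matter
  together: weakly identified directions (next section) move the
  residuals by parts in 1e4, and the default machine-epsilon-sized
  steps would measure nothing but solver noise along them.

`two_step_fit()` runs the documented two-stage protocol: fit to PhoA
alone, then restart from that optimum with PhoB included, reporting the
shift in the fitted model's PhoA time-to-peak as the contribution of
the expression feedback.

## Identifiability

PhoA is a dead-end reporter: it feeds nothing back. Its observable is
`r13 * integral(mRNAa)` and mRNAa production is `r12 * pPhoAa`, so the
data pin the *product* r12 * r13 very strongly, while the split is
informed only by the transcript the cell starts with (one molecule),
a relative signal of about 2.6e-4 in the PhoA curve. Consequences,
measured with the synthetic-data machinery below:

* At zero measurement noise the split is recoverable — but only with
  the derivative and tolerance settings above; `recovery_experiment()`
  then returns r12 and r13 to within ~1e-6 relative.
* At 5% multiplicative noise the split is unidentifiable: estimates
  slide along the product manifold until a box bound stops them, and
  median relative errors for the individual rates sit far above any
  useful threshold even though the product remains accurate to a few
  percent. The r14/r15 pair on the PhoB side behaves the same way (the
  feedback through r16 is too weak to break the degeneracy).

Recovery experiments therefore hold the reporter scale factors fixed at
truth: a free per-observable gain absorbs the translation rates exactly
and would make them unidentifiable even at zero noise.

## Synthetic data

`ground_truth()` + `generate_dataset()` define the generating model for
recovery studies: the control rates and initial state, samples every
600 s across the 4.5 h window (28 points, a plate-reader-like cadence),
independent multiplicative Gaussian noise `y (1 + sigma z)` clipped at
zero (fluorescence error scales with signal), and linear per-observable
gains standing in for arbitrary fluorescence units. The generator is
seeded and returns the truth alongside the dataset for scoring; the
truth is never an input to the fitter. `generate_ssa_dataset()`
produces population-averaged stochastic data whose only noise source is
molecule-number fluctuation; on linear sub-networks its mean converges
to the ODE prediction, which the test suite uses as a cross-engine
oracle.

## Perturbation studies

* `pi_regime_scan()` emulates external Pi levels as fold factors 1,
  0.5, 0.2, 0.1 on r1/r2 and reports steady-state `DiPhoBpp`,
  steady-state `pPhoAa` and the PhoA AUC per regime; expression falls
  monotonically as Pi rises.
* `promoter_design_scan()` scans synthetic promoter designs as a
  10 x 10 grid of fold factors (0.25 to 2.5 in 0.25 steps) on the
  binding (r10/r11) and unbinding (r10r/r11r) rates — 100 full-horizon
  ODE runs per regime — and attaches the control PhoA AUC as the
  normalisation reference. `find_starvation_equivalent_designs()`
  returns the cells whose yield matches the starvation control within
  tolerance, or flags the nearest cell when none do: the promoter
  designs predicted to restore a starvation-level response under
  repression.
* `range_sensitivity()` reproduces the literature-range analysis: for
  each of the 12 rates with a finite physiological range (r1, r2, r4,
  r6, r12-r19), the species-wise AUC difference between the range
  maximum and minimum, normalised by the control AUC. On the PhoA
  readout each protein's translation rate outweighs its degradation
  rate by one to three orders of magnitude.
* `sweep_sensitivity()` is the hypothesis-free version: every rate times
  fold factors 1e-3 to 1e3, AUC ratios against control, integration
  failures recorded per cell without aborting the sweep.

## Command line

`cli_simulate()`, `cli_fit()`, `cli_scan()` and `cli_sensitivity()`
(installed as the `phoregulon` script under `inst/scripts`) wrap the
above into a reproducible pipeline: YAML/JSON configs validated against
known keys, one global seed expanded by a documented splitting rule,
results as CSV/JSON with 17-significant-digit floats, and a
`run_metadata.json` (config copy, seed, package version) in every
output directory. Progress goes to stderr; stdout carries a single
summary line. Heatmap PNGs are opt-in (`--plots`, requires ggplot2).

## Limitations

* External Pi is a lumped fold factor on autophosphorylation, not an
  explicit transporter module.
* Promoters are two-state; no cooperative or multi-site binding.
* The SSA treats the cell as well mixed at constant volume; growth and
  division enter only through first-order dilution terms.
* Individual transcription/translation rates of a reporter module are
  structurally near-degenerate (only their product is strongly
  identified); calibration results for those splits should be read
  with the identifiability section in mind.
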