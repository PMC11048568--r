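---
title: "Hole-transfer kinetics along the cryptochrome tryptophan tetrad: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hole-transfer kinetics along the cryptochrome tryptophan tetrad: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trphop)
```

## The system and the model

Cryptochrome 4 (Cry4) is the blue-light photoreceptor at the centre of the
radical-pair hypothesis of animal magnetoreception. After photoexcitation of
the flavin (FAD) cofactor, an electron hops towards the flavin along a
conserved chain of four tryptophan residues — in Atlantic herring Cry4
(ChCry4) residues 396, 373, 319 and 370, labelled TrpA through TrpD.
Equivalently, an electron *hole* migrates away from the flavin,
A → B → C → D, and the hole's site occupation identifies the instantaneous
radical-pair state [FAD·⁻ TrpX·⁺].

`trphop` models this migration as a reversible first-order chain,

$$\mathrm{A} \underset{k_{b,AB}}{\overset{k_{f,AB}}{\rightleftharpoons}}
  \mathrm{B} \underset{k_{b,BC}}{\overset{k_{f,BC}}{\rightleftharpoons}}
  \mathrm{C} \underset{k_{b,CD}}{\overset{k_{f,CD}}{\rightleftharpoons}}
  \mathrm{D},$$

whose master equation for the occupations $p = (A, B, C, D)$ is
$\dot p = M p$ with the tridiagonal generator returned by
`build_generator()`. Each column of $M$ sums to zero (total occupation is
conserved) and only nearest-neighbour entries are non-zero: the electronic
coupling between non-adjacent tryptophans vanishes, so direct A–C, A–D and
B–D transfer is excluded from the model.

Assumptions worth keeping in mind:

* **First-order, memoryless kinetics.** Conformational gating, vibronic
  effects and solvent reorganisation are subsumed into six effective rate
  constants; there is no temperature dependence.
* **Initial condition.** The first electron transfer (FAD ← TrpA) is taken
  as already completed, so propagation starts from $p_0 = (1, 0, 0, 0)$ by
  default (overridable in `propagate()` and `fit_rates()`).
* **Units.** Time is picoseconds everywhere; rates are stored in 1/ps, and
  every rate set has a reciprocal time-constant view (`tau()`), which is
  the form usually quoted (e.g. the published ChCry4 values of
  `chcry4_rates()`: forward 23, 149, 57 ps; backward 141, 82, 240 ps).

## Propagation and the equilibrium

`propagate()` evaluates the exact solution
$p(t) = V e^{\Lambda t} V^{-1} p_0$ by eigendecomposition. For strictly
positive off-diagonal rates the generator is similar to a symmetric
tridiagonal matrix, so the eigensystem is real and well conditioned. Two
fallbacks cover degenerate inputs (zero rates can make the generator
defective): exact matrix-exponential stepping (`Matrix::expm`, one cached
exponential per distinct grid increment) and, as a last resort, a stiff
dense integrator (`deSolve::lsoda`, rtol 1e-10, atol 1e-12). Occupations
are clamped only within 1e-9 of the [0, 1] boundary; conservation holds to
1e-9 at every grid point, which the test suite asserts on randomized
chains.

For a fully reversible chain the equilibrium has the closed form
$(1, K_1, K_1K_2, K_1K_2K_3)/Z$ with $K_i$ the successive
forward/backward ratios; `steady_state()` uses it directly and refuses
irreversible chains (an absorbing end has no detailed-balance equilibrium
— propagate to large $t$ instead).

## Rate-constant extraction

`fit_rates()` recovers the six rates from occupation data by minimising
the unweighted sum of squared residuals between the data and the
master-equation solution across all four sites and all time points.
Choices we made where the procedure was genuinely open:

* **Parameterisation.** Optimisation runs in log time-constant space,
  which enforces positivity by construction and equalises scale across
  rates spanning an order of magnitude. Iterates are confined to
  $\tau \in [10^{-3}, 10^{7}]$ ps, a window far wider than any physical
  value, purely to keep intermediate generators well behaved.
* **Optimiser.** Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol = ptol =
  1e-12, 200 iterations) — the standard choice for small dense
  least-squares problems.
* **Multi-start.** 16 seeded log-uniform initialisations with time
  constants in [1, 1000] ps by default. The landscape has local optima
  (a single bad start can invert the role of two transfer steps), and the
  published work does not describe its optimiser or starts, so a seeded
  multi-start with a deterministic tie-break (lowest residual norm, then
  lexicographically smallest parameter vector) makes every fit
  reproducible.
* **Weighting.** Residuals are equally weighted; no weighting scheme is
  stated for the original fit.
* **Diagnostics.** The returned `kinetic_fit` keeps every start's optimum;
  the per-parameter standard deviation across converged starts is reported
  as a dispersion proxy, and `converged = FALSE` (never an exception) marks
  an entirely failed multi-start.

Noiseless round trips (integrate → refit) recover all six constants to
well below 1% on a 1 ps, 1 ns grid — this identifiability check runs in
the test suite for the published constants and for randomized rate sets.

## The synthetic-trajectory generator

No trajectory data are deposited with the study ("available upon
request"), so the package ships a generator whose ground truth is known by
construction; every downstream stage is validated against it.

* `simulate_kmc()` draws continuous-time Markov jump trajectories
  (Gillespie algorithm) on {A, B, C, D}, started at A, and samples them on
  a regular grid as indicator occupations. Defaults mirror the study
  conditions: 51 trajectories of 1 ns at 1 ps sampling. The ensemble mean
  converges to the master-equation solution (asserted at 3 binomial
  standard errors against `propagate()`), which is what makes the mean of
  a few hundred trajectories fittable. Each trajectory uses its own RNG
  substream derived from the master seed, so enlarging the ensemble never
  reshuffles existing trajectories.
* **Indicator vs fractional occupations.** The QM/MM populations the model
  emulates are continuous quantum populations, while raw KMC occupations
  are 0/1 indicators. A sliding-window mode (`smooth_window`, default off;
  25 ps is a reasonable width) mimics fractional per-trace occupations; no
  per-trace noise model is published, so the smoothing width and the
  optional clipped-Gaussian observation noise (`add_observation_noise()`,
  renormalised per time point) are free parameters.
* `make_heterogeneous_ensemble()` emulates the observed split of the QM/MM
  ensemble — 23 trajectories that complete the transfer and 28 with the
  hole stuck on TrpB — as a labelled two-population mixture. The stuck
  population is modelled by setting $k_{f,BC} = 0$ (hole confined to
  {A, B}): the simplest mechanism that reproduces the phenotype, chosen as
  a modelling device rather than a claim about the physical cause.
  Because the published split is defined by the observed phenotype (not by
  latent rates), "completed" trajectories are sampled *conditional on the
  transfer actually completing*: a nominal-rates realisation that happens
  never to leave {A, B} within 1 ns (probability below 1%) is redrawn from
  a fresh substream. This keeps the ground-truth labels coherent with what
  they claim, and makes noiseless label recovery exact by construction.
* `simulate_site_series()` produces stationary Ornstein–Uhlenbeck series
  shaped like per-frame site energies and neighbouring-pair electronic
  couplings (eV), via the exact discrete-time recursion. Requesting a
  non-neighbour coupling (e.g. A–C) errors: the chain topology sets those
  to zero identically.
* `make_toy_frames()` writes miniature PDB fixtures — four idealised
  tryptophan side chains plus waters — in which the quantities the
  structural module measures are *exact by construction*: consecutive
  side-chain separations and minimum water distances are solved to 1e-9 by
  root finding, extra frames are rigid motions of the same scene, and a
  sidecar JSON records ground truth recomputed by brute force on the
  rounded coordinates actually written (PDB stores 0.001 Å). The fixtures
  are labelled synthetic; they carry exact geometry, not realistic
  chemistry.

What passing these tests shows — and does not show. The generator
reproduces the *kinetic scheme* assumed by the analysis, so green tests
demonstrate that the estimator, classifier and structural metrics are
correct and well calibrated on data of the assumed form. They cannot show
that real QM/MM populations follow first-order kinetics, and they say
nothing about the electronic-structure level of the original study.

## Trajectory classification and summaries

`classify_completion()` labels a trace "completed" when the occupation on
TrpC *or* TrpD reaches at least 0.3 at any sampled time instant. The
boundary is closed (≥ 0.3): the source prose says "at least 0.3" while a
figure caption says "greater than" — we follow the prose and expose the
threshold and the comparison sites as arguments. The criterion scans every
sampled time point, not only the final state; whether the original
threshold applied to instantaneous or time-averaged occupation is not
fully explicit, and instantaneous is assumed.

`summarize_series()` reduces any per-simulation series collection to
pointwise mean and standard deviation. The *population* standard
deviation (divisor $n$) is the default because the band describes the
ensemble itself rather than estimating a wider population; `sd_type =
"sample"` switches convention. `compare_subsets()` produces the
all/completed/stuck triptych on one grid and flags an absent quantity
(e.g. couplings that were never loaded) instead of erroring.

## Structural descriptors

* **Water shells.** `count_waters_near()` counts distinct water molecules
  with *any* atom (hydrogens included) within the cutoff (default 5 Å,
  closed boundary) of *any heavy atom* of the residue. The original
  criterion is stated only as "within 5 Å"; the any-atom/heavy-atom rule
  is the most inclusive reading and is pinned down by the tests. No
  periodic images are considered — frames are assumed wrapped around the
  protein.
* **Edge-to-edge distance.** Undefined in the source; we adopt the
  standard electron-transfer usage: the minimum distance between
  *side-chain heavy atoms* of the two residues (backbone N, CA, C, O, OXT
  excluded), with `mode = "all_heavy"` available. Both metrics are
  asserted to agree exactly with brute-force all-pairs oracles and to be
  invariant under rigid motion.
* **Distance distributions.** `fit_distance_distribution()` bins samples
  into a normalised density histogram (Freedman–Diaconis bin count by
  default; the original binning is unstated) and fits a single Gaussian
  $a\,e^{-(x-m)^2/2s^2}$ to the bin centres by least squares, reporting
  the fitted mean as the distribution maximum. Moment-based starting
  values make the fit effectively deterministic; zero-variance samples
  yield `fit_ok = FALSE` rather than an error.

## Pipeline and configuration

The `run_*` functions chain the stages the way the original workflow did —
generate → average → classify → fit → structural metrics → report — with
all file formats documented on the writers (occupation CSV
`sim_id,time_ps,occ_A..occ_D`; labels, fit and distribution JSON; YAML
configuration that round-trips losslessly). `inst/cli/trphop.R` is a thin
Rscript wrapper with subcommands `simulate`, `fit`, `classify`,
`structure`, `report` (exit codes: 0 success, 2 validation error, 3
non-convergence). Every stage logs its seed and subset sizes and is
deterministic given its configuration.

## Problem sizes and numerical tolerances

The shipped defaults are the study conditions: 51 trajectories (23 + 28),
1 ns, 1 ps sampling, threshold 0.3, 5 Å cutoff, 16 fit starts. The test
suite runs the full-scale deterministic round trip (1001 points), a
500-trajectory stochastic recovery, a 2000-trajectory law-of-large-numbers
check, 100-rate-set comparisons against a dt = 0.01 ps RK4 oracle (1e-6
absolute), and 50 randomized structure fixtures against brute-force
oracles; identifiability sweeps use 12 random rate sets at 16 starts.
Random-seed policy: every stochastic component takes an explicit seed and
derives per-unit substreams, so all reported numbers are exactly
reproducible.

## Known limitations

* Rates are effective fit parameters; nothing is predicted from structure
  (no Marcus or Moser–Dutton analysis), and no temperature dependence is
  modelled.
* The KMC generator cannot emulate genuinely quantum population dynamics
  (coherences, non-exponential dwell times); it realises the kinetic
  scheme, not the electronic structure.
* The backward C–D rate is the most weakly identified parameter when
  fitting ensemble means of a few hundred stochastic trajectories; expect
  tens-of-percent dispersion at that scale.
* PDB is the only structure format read; coordinates are taken as-is
  (no periodic-image handling, no SASA).
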