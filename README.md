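# trphop

Electron-hole transfer kinetics along the cryptochrome tryptophan tetrad.

Cryptochrome 4 is the photoreceptor protein at the heart of the
radical-pair hypothesis of animal magnetoreception. On photoexcitation of
its FAD cofactor, an electron hops to the flavin along a conserved chain
of four tryptophans (in Atlantic herring Cry4: residues 396, 373, 319,
370, labelled TrpA–TrpD); equivalently, an electron hole migrates
A → B → C → D, and the hole's site defines the instantaneous radical-pair
state [FAD·⁻ TrpX·⁺]. `trphop` is for computational biophysicists who
have per-trajectory hole-occupation time series (e.g. from QM/MM
simulation) or coordinate frames, and want the standard analyses of that
system in reproducible, testable form.

The core is the reversible four-state kinetic model

    A <=(kfAB/kbAB)=> B <=(kfBC/kbBC)=> C <=(kfCD/kbCD)=> D

with master equation dp/dt = M·p on the occupations p = (A, B, C, D).
The package provides:

* **kinetics** — exact propagation of the master equation
  (`propagate()`), the generator matrix (`build_generator()`), the
  closed-form chain equilibrium (`steady_state()`), and multi-start
  Levenberg–Marquardt extraction of the six rate constants from
  occupation data (`fit_rates()`, log time-constant parameterisation,
  broom-style `tidy()`/`glance()`, `autoplot()`).
* **synthetic data** — a kinetic Monte-Carlo (Gillespie) trajectory
  generator with per-trajectory seed substreams (`simulate_kmc()`), a
  labelled completed/stuck mixture emulating the observed 23/28 ensemble
  split (`make_heterogeneous_ensemble()`), clipped-Gaussian observation
  noise, Ornstein–Uhlenbeck site-energy/coupling series, and exact-geometry
  toy PDB fixtures (`make_toy_frames()`).
* **trajectory analysis** — completed/stuck classification at the 0.3
  occupation threshold on TrpC/TrpD (`classify_completion()`,
  `classify_ensemble()`), pointwise mean ± sd series summaries
  (`summarize_series()`), and all/completed/stuck comparisons
  (`compare_subsets()`).
* **structure metrics** — solvent-shell water counts within 5 Å of a
  residue (`count_waters_near()`), minimum side-chain heavy-atom
  edge-to-edge distances (`edge_to_edge()`), and Gaussian fits to distance
  distributions (`fit_distance_distribution()`), all PDB-driven
  (`read_frames()`).
* **pipeline** — `run_simulate()` → `run_fit()` → `run_classify()` →
  `run_structure()` → `run_report()` over documented CSV/JSON/YAML
  formats, plus a thin CLI (`inst/cli/trphop.R`) with subcommands
  `simulate`, `fit`, `classify`, `structure`, `report`.

All user-facing functions take data frames first and return tibbles, so
everything chains with the pipe.

## Worked example

Published ChCry4 time constants, a stochastic ensemble, and recovery of
the rate constants from its mean:

```r
library(trphop)

chcry4_rates()
#> <rate_constants> six-rate reversible chain A <-> B <-> C <-> D
#>      transition rate_per_ps tau_ps
#> kfAB       A->B    0.043478     23
#> kbAB       B->A    0.007092    141
#> kfBC       B->C    0.006711    149
#> kbBC       C->B    0.012195     82
#> kfCD       C->D    0.017544     57
#> kbCD       D->C    0.004167    240

# 500 hole-hopping trajectories of 1 ns, sampled every ps
ens <- simulate_kmc(chcry4_rates(), t_max = 1000, n_traj = 500, seed = 42)
fit <- fit_rates(ensemble_mean(ens), n_starts = 16, seed = 42)
round(fit$tau_ps, 1)
#> tau_fAB tau_bAB tau_fBC tau_bBC tau_fCD tau_bCD
#>    21.9   125.9   170.4   100.9    54.7   221.6
```

The six fitted time constants (ps) land within a few tens of percent of
the generating values (23, 141, 149, 82, 57, 240 ps) — the dispersion is
the finite-ensemble sampling error of averaging 500 jump trajectories,
and shrinks as the ensemble grows. On a noiseless master-equation curve
the same fit returns the generating constants to machine precision.

Classification of a labelled completed/stuck mixture at the study's
ensemble size:

```r
ens51 <- make_heterogeneous_ensemble(seed = 42)  # 23 completed + 28 stuck
classify_ensemble(ens51)
#> <classification_result> 23 completed / 28 stuck (threshold 0.30 on C/D)
#>   agreement with ground truth: 100.0%
```

Structural descriptors on a toy fixture with exactly known geometry:

```r
toy <- make_toy_frames(tempfile(fileext = ".pdb"), min_separation = 4.2,
                       water_placements = data.frame(residue = 373,
                                                     distance = 3, count = 2))
edge_to_edge(toy$frames, 373, 319)$distance_A   # 4.2 (exact)
count_waters_near(toy$frames, 373)$water_count  # 2
```

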