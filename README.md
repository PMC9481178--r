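# kaiabc

Simulation of the KaiABC post-translational circadian oscillator: an
ensemble of KaiC hexamers in which chemical reactions and a two-state
allosteric structure feed back on each other inside every molecule, and the
molecules synchronize through sequestration of KaiA into KaiC-KaiB-KaiA
complexes. The package is for chronobiologists and systems biologists who
want to probe, in silico, how the reaction-structure coupling shapes the
oscillation period, its temperature compensation, and its phase responses.

## The model in brief

Each of `N` KaiC hexamers carries a phosphorylation level `D` in [0, 1], a
structural order parameter `X` in [0, 1] held in quasi-equilibrium,

```
X = (1 + tanh(beta R))/2
R = d0 + d1 pA - d2 B - d3 (2D - 1) - d4 [qbar X - (1 - qbar)(1 - X)]
```

mean-field probabilities `pA` (KaiA dimer on the CII ring) and `pB[i]`
(i KaiB monomers on the CI ring), and six stochastic nucleotide bits
`q(i)` (ADP vs ATP in the CI domains; hydrolysis frequency `f_hyd`, ADP
release hazard `1/Delta_ADP(X)`). `d1, d2 > 0` are positive feedback,
`d3 > 0` the slow negative feedback through phosphorylation
(`dD/dt = kp H+ (1-D) - kdp H- D`, `H+ = z/(1+z)`, `z = pA/P0`), and `d4`
lets the stochastic ATPase trigger the structural transitions. Free KaiA
is the root of a strictly monotone conservation equation over the whole
ensemble — the coupling that synchronizes the molecules. Temperature acts
through Arrhenius factors `s(dE; T, T0)` plus three optional rules:
thermal attenuation of `d3, d4` (Rule 1), a thermally activated KaiB fold
switch (Rule 2), and a temperature-insensitive ATPase (Rule 3); the
combinations `kai_case("A")`-`kai_case("D")` are the canonical cases for
Q10 analysis, `Q10 = period(T0-5C)/period(T0+5C)`.

The integrator is an Rcpp kernel (explicit Euler at `dt = 1e-3` h, the
structural fixed point solved self-consistently each step) that is exactly
reproducible from a seed.

## Worked example

```r
library(kaiabc)

params <- kai_params(N = 200)            # reduced ensemble, standard ratios
traj   <- simulate_ensemble(params, duration = 240, seed = 42)
period_amplitude(traj)
#> <kai_summary> oscillatory: period 15.43 h (se 0.129), amplitude 0.186, 14 cycles

kai_concentrations(params)
#> # A tibble: 6 x 3
#>   quantity   value_uM basis
#> 1 KaiC_total   3.32   monomer
#> 2 KaiA_total   1.11   monomer
#> 3 KaiB_total   3.32   monomer
#> 4 Kd_C:A       1.11   KaiA dimer on CII
#> 5 Kd_C:B      22.1    KaiB monomer on CI
#> 6 Kd_CB:A      0.0923 KaiA dimer on CI-bound KaiB
```

The summary says the ensemble-mean phosphorylation rhythm is
self-sustained with a 15.4 h period and peak-to-trough amplitude 0.19 at
the reference temperature; the concentration table confirms the standard
condition (3.3 uM KaiC, 1:3:3 monomer stoichiometry, the three
dissociation constants in micromolar). `autoplot(traj)` draws the four
ensemble observables; `molecule_traces()` (with `n_track > 0`) exposes
single molecules. Protocol drivers — `scan_feedback()`,
`scan_temperature()` / `kai_q10()`, `tstep_prc()`, `adp_pulse_prc()`,
`scan_atpase()`, `atpase_activity()`, `desync_assay()` — return tidy
tibbles that chain with dplyr and plot with `autoplot()`. A thin CLI over
the same functions ships at `inst/cli/kaiabc`
(`kaiabc simulate --config cfg.yaml --seed 1 --out results/`).

Note on scale: with all published rate and coupling constants as printed,
this implementation's standard-condition period is ~15.5 h; the
temperature-compensation machinery and all qualitative behaviors
reproduce, and the methods vignette discusses the offset.

## Package layout

* `R/params.R`, `R/thermo.R` — parameter sets, Arrhenius scaling, rules.
* `R/model_core.R` — the per-hexamer rate laws as testable R functions.
* `src/kernel.cpp` — the ensemble integrator.
* `R/simulate.R` — trajectories, perturbation events, per-molecule traces.
* `R/analysis.R` — period/amplitude, circadian time, phase shifts,
  synchrony.
* `R/protocols.R` — the in-silico experiments.
* `R/io.R`, `inst/cli/kaiabc` — YAML configs, writers, command line.
* `vignettes/kai-oscillator-model.Rmd` — the model, assumptions, numerical
  choices, and limitations.
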