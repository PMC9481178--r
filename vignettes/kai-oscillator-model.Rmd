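---
title: "The coupled reaction-structure model of the KaiABC oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled reaction-structure model of the KaiABC oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the model

The cyanobacterial proteins KaiA, KaiB and KaiC, incubated with ATP,
produce a self-sustained ~24 h rhythm in the phosphorylation level of KaiC,
and the period is nearly independent of temperature (Q10 close to 1).
`kaiabc` simulates an ensemble of `N` KaiC hexamers in which each molecule
is an autonomous oscillator built from feedback between chemical reactions
and a two-state allosteric structure, and the molecules synchronize only
through the shared pool of free KaiA.

Each hexamer `k` carries:

* `D` — the phosphorylation level of the twelve CII sites, a continuous
  variable in [0, 1] (the two serine/threonine sites per subunit are not
  distinguished);
* `X` — a structural order parameter in [0, 1]; `X ~ 1` is the
  conformation of the phosphorylating (P) phase, `X ~ 0` that of the
  dephosphorylating (dP) phase;
* `pA` — the probability that a KaiA dimer occupies the CII ring;
* `pB[0..6]` — the probability distribution of the number of KaiB monomers
  bound on the CI ring;
* `q[1..6]` — binary nucleotide states of the six CI domains
  (1 = ADP bound, 0 = ATP bound), the only *stochastically* simulated
  variables.

Structural relaxation is far faster than every reaction, so `X` is in
quasi-equilibrium with a drive field `R` (in units of `kB*T0`):

```
R = d0 + d1*pA - d2*B - d3*(2D - 1) - d4*F(q, X)
X = (1 + tanh(beta * R)) / 2,         beta*R = R * T0[K]/T[K]
F = qbar*X - (1 - qbar)*(1 - X) = X - (1 - qbar)
```

where `B` is the probability that at least one KaiB monomer is bound.
`d1, d2 > 0` are positive feedback (KaiA on the CII stabilizes `X ~ 1`,
KaiB on the CI stabilizes `X ~ 0`); `d3 > 0` is the slow, time-delayed
negative feedback through phosphorylation that drives the cycle; `d4`
couples the stochastic nucleotide state to the structure and triggers the
transitions. KaiA binding/unbinding on the CII is fast and treated in
equilibrium; KaiB binding is a 7-state birth-death chain with
structure-dependent rates; phosphorylation follows
`dD/dt = kp*H+*(1-D) - kdp*H-*D` with `H+ = z/(1+z)`, `z = pA/P0`.
Hexamers interact only through two conservation laws: free KaiB is the
total minus what is bound, and free KaiA solves a strictly monotone scalar
equation that accounts for dimers on the CII and dimers sequestered into
KaiC-KaiB-KaiA complexes (each bound KaiB can hold one dimer, with
occupancy `alpha = xA*g/(1 + xA*g)`, `g = hAB/fAB`). This sequestration is
the synchronizer: molecules entering the dP phase soak up KaiA and pull
the others after them.

### Why the structure update is a fixed point

Because `F(q, X) = X - (1 - qbar)`, the quasi-equilibrium relation is
algebraic in `X`:

```
X = (1 + tanh(beta*(c - d4*X))) / 2
```

with `c` collecting every term that does not contain `X`. This equation
has exactly one solution because the right-hand side is decreasing in `X`,
and the package solves it by safeguarded Newton iteration at every step
(`x_scheme = "fixed_point"`). The alternative of inserting the previous
step's `X` looks like a harmless explicit scheme but is not one: the
relation contains no `dt`, so the lagged update is an iterated map whose
stability is independent of the step size. Its local slope is
`-d4*beta/2 * sech^2`, which reaches magnitude 1 at the standard
`d4 = 2 kB*T0` and exceeds 1 whenever the thermal-attenuation rule
strengthens `d4` below the reference temperature. The map then chatters in
a spurious period-2 cycle precisely in the transition region, which
injects artificial noise into the low-temperature simulations and biases
the temperature dependence of the period. The lagged variant is kept
(`kai_params(x_scheme = "lagged")`) for comparison; all shipped results
use the fixed point.

### The stochastic ATPase

Each ATP-bound CI domain hydrolyzes with probability `f_hyd*dt` per step.
An ADP-bound domain releases its ADP with hazard `dt / Delta_ADP(X)`,
`Delta_ADP = dADP0*(1 - tanh((2X-1)/C_X))`: release is fast in the `X ~ 1`
structure and slow in `X ~ 0`, which makes the measured ADP release rate
peak in the P phase while the ADP *occupancy* peaks in the dP phase. The
hazard form gives exponentially distributed lifetimes whose mean tracks
the structure continuously; an alternative "aging" scheme
(`adp_scheme = "aging"`, a deterministic clock advancing at rate
`1/Delta_ADP(X(t))`) gives sharply peaked lifetimes with the same mean.
The two schemes give indistinguishable periods and very similar ensemble
statistics; the hazard scheme is the default.

## Temperature model

All six generic rate constants (`hA0, fA0, hAB, fAB, kp, kdp`) share one
activation energy `dE0` through the Arrhenius factor
`s(dE; T, T0) = exp(-dE/kBT + dE/kBT0)` (energies in `kB*T0` units,
`T0 = 30` C). Three optional rules shape the rest:

* **Rule 1**: `d3` and `d4` are *divided* by `s(dEf; T, T0)` — growing
  thermal fluctuations at the CI-CII interface loosen the
  reaction-structure coupling as temperature rises. Weaker negative
  feedback means longer period, opposing the Arrhenius acceleration; this
  is the core compensation mechanism.
* **Rule 2**: KaiB binds through a thermally excited fold switch, so
  `hB0` carries `s(dE0)*s(dE_gs_fs)` and `fB0` carries
  `s(dE0)*s(dE_fs_gs_p)`.
* **Rule 3**: the ATPase pair (`f_hyd`, `1/dADP0`) is temperature
  *insensitive*, as observed experimentally. Mutant-style overrides
  `dEa`/`dEb` give the two rates their own activation energies instead.

`kai_case("A")` to `kai_case("D")` bundle the combinations used in the
temperature-compensation analysis. Temperature additionally enters the
structure update through `beta`.

## Units, sizes and defaults

Concentrations are counts per simulation volume, with the volume defined
so that 1000 hexamers occupy `V = 1` (3e-15 l); `kai_params()` therefore
sets `V = N/1000` and the dynamics are independent of `N` except for
finite-ensemble fluctuations. Defaults follow the standard condition:
monomer ratio `AT:BT:CT = 1:3:3` (`AT/2 = N` KaiA dimers, `BT = 6N` KaiB
monomers, KaiC 3.3 uM), rate constants as in `kai_params()`'s signature,
and integration step `dt = 1e-3` h with explicit Euler for the continuous
variables. A 100 h warm-up from randomized initial conditions
(`D ~ U(0,1)`, fair-coin nucleotides, KaiB-free) is discarded before
anything is measured; the attractor does not depend on these choices.

Analysis choices: the period is the mean inter-peak interval of the
ensemble phosphorylation level after smoothing with a 1 h moving average;
peaks must clear a prominence of 0.02 and a rhythm needs at least three
peaks and amplitude 0.02 to count as oscillatory. The amplitude is the
mean peak-to-following-trough drop. Circadian time pins the peak at CT 16
with the cycle normalized to 24 h; for same-temperature perturbations
(ADP pulses) phase shifts are matched post-onset peak-time differences in
CT hours, advance positive, wrapped to (-12, 12]. Temperature steps leave
the rhythm running at the target temperature's own period, so peak
matching against the original-temperature reference would drift by the
period mismatch each cycle; there the post-step peak grids of both runs
are projected back to the onset with their own periods and the shift is
the wrapped phase difference — the same per-temperature cycle
normalization that defines CT. Note that with the shorter
dephosphorylation phase of this implementation's cycle, the trough sits
near CT 0-1 rather than CT 4, so phase-response features tied to the
trough (the delay region and the abrupt delay-to-advance jump of the ADP
pulse response) appear a few CT hours earlier than with a symmetric
waveform. The synchrony index is the ratio of the ensemble-mean
amplitude to the mean single-molecule amplitude, both measured as robust
(5th-95th percentile) ranges so the index stays defined when the ensemble
mean is flat.

Problem sizes: shipped tests and the acceptance script use reduced
ensembles (N = 150-300 hexamers, 280 h of recorded rhythm, at least ten
cycles per condition, replicate seeds), which leaves Q10 estimates with a
standard error of roughly 0.01-0.02; the model itself is routinely run at
N = 1000-2000.

## What the simulations do and do not show

The generator emulates the in-vitro reconstituted system: fixed totals of
the three proteins in a well-stirred volume, abundant ATP, temperature
either constant, stepped, or (through the ADP-lifetime multiplier) an
ADP-concentration pulse. It does not model monomer shuffling between
hexamers, explicit KaiB fold-switch kinetics, the distinction between the
two phosphorylation sites, or transcription-translation coupling — so
agreement here says nothing about those mechanisms.

A known quantitative limitation: with every published parameter value
implemented as printed, the standard-condition ensemble period in this
implementation is about 15.5 h rather than ~24 h, i.e. the model behaves
as if the reaction-structure couplings were ~25% stronger than intended
(scaling `d3, d4` by ~0.8 reproduces a 23 h period and the large
amplitude). Every qualitative result is insensitive to this offset — the
feedback-scaling trends, the arrest at `X ~ 1` under weak negative
feedback, the ATPase scaling constraint, the PRC signs, the
desynchronization phenomenology, and the rule-dependence ranking of Q10
all reproduce — but Q10 values in the strongly overcompensated regime
(Case B, large `dEf`, elevated KaiA) saturate nearer to 1 than the
reference values because the period's response to couplings strengthened
beyond the standard point flattens near its floor. The discrepancy is
documented rather than patched: no parameter was moved from its printed
value.

## Numerical details worth knowing

* The free-KaiA equation is solved to a relative tolerance of 1e-10 by
  Newton iteration safeguarded with bisection; the left side is strictly
  increasing, so the root is unique. The integrator tracks its worst
  residual and the trajectory aborts if the solve fails.
* The KaiB-ring Euler update conserves probability exactly; negative
  excursions below -1e-9 abort as a step-size error, smaller ones are
  clipped and renormalized.
* All randomness flows from one seed: R's RNG seeds a fast internal
  generator for the per-domain nucleotide draws, so a (seed, config) pair
  reproduces a trajectory bit for bit. Scan points and replicates derive
  their seeds from the master seed and the scanned value, making scans
  independent of evaluation order.
* Perturbation onsets are snapped to the recording grid (0.1 h default);
  a temperature step re-enters the kernel with re-scaled parameters and
  the same random stream, so perturbed and reference runs coincide
  exactly until the onset.

## A worked run

```{r example}
library(kaiabc)

params <- kai_params(N = 300)
traj <- simulate_ensemble(params, duration = 280, seed = 1)
summary <- period_amplitude(traj)
glance(summary)
autoplot(traj)

# temperature compensation under the full rule set
kai_q10(params, kai_case("A"), seed = 1)$q10
```
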