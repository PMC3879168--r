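---
title: "The mitotic Cdk1-Greatwall-PP2A/B55 switch: model, methods and design notes"
author: "mitoswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mitotic Cdk1-Greatwall-PP2A/B55 switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoswitch)
```

## The model

Entry into mitosis is driven by the abrupt activation of Cdk1/Cyclin B
("MPF") and exit by its inactivation together with dephosphorylation of
its substrates. The package implements a six-variable mass-action model
of the switch controlling this transition:

* **MPF** — active (Tyr15-dephosphorylated) Cdk1/CycB. Since Cdk1 is in
  excess over Cyclin B, all Cyclin B is assumed complexed, so total
  Cyclin B (`CycT`) splits into active `MPF` and Tyr15-phosphorylated
  `preMPF = CycT - MPF`.
* **Cdc25** — phosphorylated (active) fraction of the Tyr15 phosphatase.
* **Wee1** — unphosphorylated (active) fraction of the Tyr15 kinase.
* **Gwl** — phosphorylated (active) Greatwall kinase.
* **ENSAPt** — total phosphorylated ENSA/ARPP19 (free plus PP2A-bound).
* **PP2** — free, active PP2A/B55.

The rate laws (all mass action, dimensionless units):

$$
\begin{aligned}
\mathrm{MPF}' &= k_{25}\,(\mathrm{CycT}-\mathrm{MPF})
                - k_{wee}\,\mathrm{MPF}\\
\mathrm{Cdc25}' &= V_{a25}\,\mathrm{MPF}_a\,(\mathrm{Cdc25_T}-\mathrm{Cdc25})
                - V_{i25}\,\mathrm{PP2}_a\,\mathrm{Cdc25}\\
\mathrm{Wee1}' &= V_{awee}\,\mathrm{PP2}_a\,(\mathrm{Wee1_T}-\mathrm{Wee1})
                - V_{iwee}\,\mathrm{MPF}_a\,\mathrm{Wee1}\\
\mathrm{Gwl}' &= k_{agwl}\,\mathrm{MPF}_a\,(\mathrm{Gwl_T}-\mathrm{Gwl})
  - \bigl(k_{igwl}' + k_{igwl}''\,\tfrac{\mathrm{PP2_T}}{1+\mathrm{OA}}
  + k_{igwl}\,\mathrm{PP2}_a\bigr)\,\mathrm{Gwl}\\
\mathrm{ENSAPt}' &= k_{aensa}\,\mathrm{Gwl}\,(\mathrm{ENSA_T}-\mathrm{ENSAPt})
                - k_{iensa}\,\mathrm{ENSAPt}\\
\mathrm{PP2}' &= -k_{as}\,\bigl(\mathrm{ENSAPt}-(\mathrm{PP2_T}-\mathrm{PP2})\bigr)\,
  \mathrm{PP2} + (k_{dis}+k_{iensa})\,(\mathrm{PP2_T}-\mathrm{PP2})
\end{aligned}
$$

with the lumped Tyr15 modification rates
$k_{25} = k_{25}'(\mathrm{Cdc25_T}-\mathrm{Cdc25}) + k_{25}''\,\mathrm{Cdc25}$ and
$k_{wee} = k_{wee}'(\mathrm{Wee1_T}-\mathrm{Wee1}) + k_{wee}''\,\mathrm{Wee1}$.
Primed symbols are spelled `k25_p`/`k25_pp`, `kigwl_p`/`kigwl_pp`,
`kwee_p`/`kwee_pp` in code.

Chemical inhibition of Cdk1 (dose `RO`) and of PP2A by okadaic acid
(dose `OA`) is modelled as fast reversible binding, so only the free
fractions act: $\mathrm{MPF}_a = \mathrm{MPF}/(1+\mathrm{RO})$ and
$\mathrm{PP2}_a = \mathrm{PP2}/(1+\mathrm{OA})$. Doses are effective,
dimensionless quantities; no mapping to molar drug concentrations is
attempted. Dose switches in the protocols are instantaneous step
changes, consistent with the algebraic dose correction.

The network couples three positive circuits: the Cdk1/Wee1
double-negative loop, the Cdk1/Cdc25 positive loop, and Cdk1's
inhibition of its counteracting phosphatase PP2A/B55 through
Gwl-activated ENSA/ARPP19, which sequesters PP2A/B55 stoichiometrically
(`kas`/`kdis` association/dissociation; dephosphorylation of bound ENSA
at rate `kiensa` also releases the phosphatase). PP2A/B55
(`PP2T = 0.5`) is kept substoichiometric to ENSA (`ENSAT = 1`) so full
sequestration is possible; this is enforced as a parameter invariant.

### The three Gwl-phosphatase variants

The phosphatase acting on the activating Gwl site is not established.
Three variants share the full default parameter set and differ only in
the route of Gwl inactivation:

| label | overrides | meaning |
|---|---|---|
| `pp2a_b55` | none (default: `kigwl = 2`) | PP2A/B55 itself; adds a Gwl ⊣ PP2A/B55 ⊣ Gwl loop |
| `oa_insensitive` | `kigwl_p = 2, kigwl = 0` | constitutive, OA-insensitive phosphatase |
| `oa_sensitive` | `kigwl_pp = 2, kigwl = 0` | OA-sensitive PP2A pool outside the B55 feedback |

The `kigwl_pp` route deliberately scales with *total* PP2A
(`PP2T/(1+OA)`) rather than free `PP2`: it represents an OA-sensitive
activity that is not subject to ENSA sequestration. The rate law is
implemented exactly as written, without reinterpretation.

## Parameters

All defaults are the reference values of the printed model:
totals 1 except `PP2T = 0.5`; `Va25 = Vi25 = Vawee = Viwee = 2`;
`kagwl = 10`, `kigwl_p = 0.02`, `kigwl_pp = 0`, `kigwl = 2`,
`kaensa = 2`, `kiensa = 0.6`; `kas = 100`, `kdis = 1`; basal/shifted
Tyr15 catalytic constants `0.01`/`1`; `RO = OA = 0`. Units are inverse
model time for rate constants and dimensionless concentrations for
totals; no physical time calibration is provided by the model, so all
timing comparisons in this package are relative (orderings and ratios),
never minutes.

## Protocols

Three inhibitor protocols mirror the perturbation experiments:

* `entry_release` — relax to the Cdk1-inhibited steady state
  (`RO = 25`), then drop the inhibitor (`RO = 0`).
* `entry_oa` — from the same inhibited state, add okadaic acid on top
  (`RO = 25`, `OA = 100`).
* `exit` — from the metaphase state, inhibit Cdk1 strongly
  (`RO = 100`).

The duration of the original pre-incubation under Cdk1 inhibition is
not specified; the package relaxes to steady state (right-hand-side
max-norm below `1e-9`, at most 500 time units) because a converged
state is the only reproducible choice. The default horizon after the
dose switch is 30 time units, matching the simulated panels. Note that
OA-driven entry is intrinsically slow in this model — at horizon 30 the
Tyr15 pool has completed only a few percent of its transition and full
entry takes roughly 120 time units — so analyses that need the complete
transition (the pseudo-immunoblot demonstrations below) integrate to
horizon 120.

Timing is quantified by `t_cross()`: the excursion of a variable is
measured between its value at the dose switch and at the horizon, and
the reported time is the linearly interpolated first crossing of a
stated fraction (default one half, "t50") of that excursion. Excursions
below `min_excursion` (default `1e-3`) and excursions running against
the stated direction return `NA` — this is how "no transition" is
encoded. Measuring against the realized excursion rather than
theoretical totals keeps the metric meaningful for partial transitions.

Under the reference parameters the protocols reproduce the qualitative
predictions: Tyr15 dephosphorylation is fast after release
(t50 ≈ 6) and slow after OA addition; Gwl activation precedes Tyr15
dephosphorylation during OA entry; OA cannot activate Gwl when its
phosphatase is OA-insensitive (Gwl stays below 20% of total); and at
exit, Gwl inactivation is strongly delayed only under the PP2A/B55
variant (t50 ≈ 13.2 versus ≈ 0.4 and ≈ 0.7 for the constitutive and
OA-sensitive variants).

## Numerical integration

`integrate_model()` wraps `deSolve::ode` (lsoda) with the analytic
Jacobian, `rtol = 1e-8`, `atol = 1e-10`. The original computation used
a stiff solver with output step 0.5; here that step is treated purely
as an output sampling choice (default `output_step = 0.05` for smooth
t50 interpolation) while accuracy is governed by the tolerances, which
are tight enough that results are insensitive to further tightening.
The adaptive solution is cross-checked in the test suite against a
fixed-step explicit Euler integrator at `dt = 1e-5` built on an
independently typed second transcription of the rate laws (agreement
within `1e-3` max-norm over a 5-unit horizon), and the right-hand side
itself agrees with that second transcription to `1e-12` at random valid
states.

States live in the box `0 ≤ X ≤ X_T` for each pool, with the
bookkeeping constraint `ENSAPt ≥ PP2T − PP2` (the bound complex is part
of total phospho-ENSA). Validation is hard-fail by default; an explicit
`clamp` mode projects onto the box with a warning. Silent clamping is
not offered because out-of-box states usually indicate solver
pathologies rather than harmless roundoff; roundoff-level violations
(below `1e-6`) at protocol restarts are absorbed.

## Steady states, balance curves, bistability

At steady state, four of the six balances are linear in their own
variable, so Cdc25, Wee1, Gwl and ENSAPt have closed-form expressions
in `MPF` and `PP2` alone. Equilibrium enumeration therefore reduces to
two residuals in two unknowns: a multi-start Newton iteration on the
reduced pair (starts on a uniform grid over `[0, CycT] × [0, PP2T]`,
all starts iterated in lockstep as vector operations), followed by full
six-dimensional Newton polishing with the analytic Jacobian (residual
max-norm below `1e-10`), duplicate merging at `1e-6` state max-norm,
and eigenvalue classification. Stability uses a `±1e-9` band on
eigenvalue real parts: strictly negative is stable, anything within the
band is flagged marginal rather than silently classified. The analytic
Jacobian is validated against central finite differences (step `1e-7`)
in the test suite.

`balance_curve()` sweeps a control parameter (by default total Cyclin
B, the natural control because the switch does not consume it) and
locates saddle-node folds by bisection on each interval where the
equilibrium count changes, to a parameter tolerance of `1e-4`. This
parameter-stepping continuation with multi-start seeding replaces
pseudo-arclength continuation; the system is six-dimensional and
well-conditioned at this scale, and fold localization by count change
is robust here. Limit cycles and Hopf points are out of scope (the
switch exhibits only saddle-node structure in these regimes).

Under the reference parameters the default variant is bistable for
CycT between about 0.050 and 0.199; the windows of the OA-insensitive
and OA-sensitive variants are narrower ([0.17, 0.28] and [0.13, 0.23]
approximately), reflecting the extra Gwl ⊣ PP2A/B55 ⊣ Gwl loop of the
default variant. Note that CycT = 1 lies above every window: the
uninhibited model at full Cyclin B is monostable-mitotic, and the G2
initial state simply transits to mitosis there. Under combined Cdk1 and
PP2A inhibition (`RO = 25`, `OA = 100`) the OA-insensitive variant
becomes monostable for all CycT in [0, 1] while the OA-sensitive
variant retains a narrow bistable window — the qualitative discriminator
between the variants at steady state.

### The printed metaphase state

The published metaphase state (MPF = 0.96, Cdc25 = 0.97, Wee1 = 0.03,
Gwl = 0.9, ENSAPt = 0.75, PP2 = 0.027), used as the exit protocol's
initial condition, coincides to its printed precision with the mitotic
steady state of the **OA-sensitive** variant
(0.9632, 0.9725, 0.0275, 0.9042, 0.7509, 0.0272). The default
(PP2A/B55) variant's mitotic state shares the MPF/Cdc25/Wee1
coordinates to two decimals but has Gwl ≈ 0.993 and PP2 ≈ 0.0258 —
with Gwl inactivation routed through sequestration-depleted PP2A/B55,
almost no active Gwl phosphatase remains in mitosis, pinning Gwl near
its total. The package therefore reports the OA-sensitive variant's
equilibrium as the reproduction of the printed values
(`scripts/acceptance.R`), and uses the printed state verbatim as the
exit initial condition for all three variants, as in the original
figures.

### Kinetic ranges of bistability

`bistability_region()` and the `bistability_ranges` experiment map
where the switch is bistable as Gwl/ENSA-module rates vary. A cell is
bistable when two distinct stable equilibria coexist at some CycT
(probed at 0.01 resolution over [0.02, 1] by a single batched
reduced-Newton solve across the grid); solver failures mark a cell
unknown, never monostable.

Varying any single rate across its documented range with the others at
their defaults — `kagwl` 1.5–10, `kigwl_p` 0–10, `kaensa` 1.5–5,
`kiensa` 0.05–2.5 — preserves bistability at every sampled value. Two
boundary behaviours deserve note. First, `kiensa = 0` exactly is
degenerate: with no ENSA dephosphorylation, any nonzero Gwl eventually
drives phospho-ENSA to saturation, the interphase state ceases to be a
steady state at any positive CycT, and the system is monostable; the
documented "0–2.5" range is meaningful as a limit, and small positive
values (0.05) are bistable. Second, the *joint* four-parameter product
grid swept by the `bistability_ranges` experiment contains monostable
cells: combinations of weakened activation (`kagwl` or `kaensa` at the
low end) with constitutive Gwl inactivation raised 250–500-fold above
its default (`kigwl_p` 5–10) lose the switch even with the B55 feedback
intact, as do all `kiensa = 0` cells. The experiment writes the full
320-cell table so these corners are visible; the headline claim that
the switch is robust should be read, as computed, about one-parameter
excursions around the reference set.

## Synthetic pseudo-immunoblot readouts

`generate_readout()` emulates quantified immunoblot band intensities:
trajectory values at sparse sampling times, multiplied by log-normal
noise `exp(N(0, σ²))` (positive, heteroscedastic, default σ = 0.1),
plus an additive background, divided by a loading-control normalization
constant (default 1, i.e. a perfectly behaved α-tubulin analogue). The
default channel map is pTyr15 → `preMPF`, pThr194 → `Gwl`,
pSer67 → `ENSAPt`, and phospho-SP substrate signal → `MPFa`. All
randomness is drawn from a private seeded generator; the global RNG
state is untouched, and identical seeds give identical series.

What the generator does **not** emulate: band saturation and limited
dynamic range, nonlinear film/detector response, loading-control
variability, lane-to-lane transfer artefacts, and biological
heterogeneity between replicate cultures. Passing recovery tests
therefore show that the estimators are consistent under the stated
noise model, not that real blots of this design would reach the same
precision.

`estimate_t50()` fits the sampled channel by monotone (isotonic)
regression in the stated direction and interpolates the mid-excursion
crossing; uncertainty comes from resampling residuals around the
monotone fit. At least four sampling times are required, and the
sampling grid must span the transition — t50 of a transition that the
grid does not bracket is meaningless, which is why the OA-entry
demonstrations sample a 120-unit horizon. With σ = 0.05 and ≥ 16
samples spanning the transition, t50 is recovered within 10% of the
trajectory truth in ≥ 95% of replicates for channels whose transition
occupies a resolvable fraction of the window (entry pTyr15 and
pThr194, exit pSer67). The exit Gwl decline under the PP2A/B55 variant
is too gradual for that precision at this noise level (about 91% of
replicates); its timing enters the analysis through the more robust
`ordering_test()`, which bootstraps the probability that one transition
precedes another (paired residual resampling; ties count one half, and
the two channels are drawn in a canonical order so swapping arguments
exactly complements the fraction).

## Experiments and problem sizes

`run_experiment()` packages the standard analyses: the three protocol
panels across all variants (`fig1_*`), the balance-curve sweeps per
variant under no inhibitor / Cdk1 inhibitor / combined inhibitors
(`figS1_balance`), the 320-cell kinetic sweep (`bistability_ranges`)
and a noisy readout demonstration (`readout_demo`). Each run writes
tidy CSVs, a `summary.json` of scalar results and a manifest with MD5
hashes; reruns with the same spec and seed are byte-identical (plots
excluded). Balance curves default to 101 grid points over CycT ∈ [0, 1]
(0.005 resolution is used where the narrow post-inhibition window of
the OA-sensitive variant must be resolved); the bistability sweep
probes CycT at 0.01 resolution. These sizes resolve every feature
discussed above while keeping a full reproduction run in the minutes
range on a single core.

## Known limitations

* The model is deterministic and well-mixed: no molecular noise, no
  compartments, no spatial gradients.
* Cyclin B synthesis/degradation is outside the model; CycT is a
  parameter, so APC/C-driven exit is not represented.
* The ENSA phosphatase is constitutive by assumption; regulation of
  ENSA dephosphorylation (and any Cdk1-dependent phosphatase control
  beyond PP2A/B55) is not modelled, and no equations for such
  extensions are provided here.
* Inhibitor doses are effective dimensionless parameters; quantitative
  dose-response comparisons to experiments require a calibration the
  model does not supply.
* Model time is uncalibrated; only orderings and relative delays are
  comparable to experimental time courses.
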