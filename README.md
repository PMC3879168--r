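# mitoswitch

Dynamics and bistability of the mitotic Cdk1–Greatwall–PP2A/B55 switch.

The G2/M transition is driven by abrupt activation of Cdk1/Cyclin B
("MPF") and mitotic exit by its inactivation. This package implements a
six-variable mass-action ODE model of the switch for systems biologists
studying mitotic control: Cdk1/CycB under inhibitory Tyr15
phosphorylation by Wee1 and activating dephosphorylation by Cdc25 —
both themselves substrates of Cdk1 and of the counteracting phosphatase
PP2A/B55 — plus the Greatwall (Gwl) → ENSA/ARPP19 pathway through which
Cdk1 inhibits PP2A/B55 by stoichiometric sequestration. The interlocked
feedback loops

```
Cdk1 ⊣ Wee1 ⊣ Cdk1        Cdk1 → Cdc25 → Cdk1
Cdk1 → Gwl → ENSA-P ⊣ PP2A/B55 ⊣ {Wee1, Cdc25, Gwl, substrates}
```

make the transition bistable in total Cyclin B: between two saddle-node
folds an interphase state (low Cdk1, active PP2A/B55) coexists with a
mitotic state (high Cdk1, sequestered PP2A/B55).

The state variables are `MPF`, `Cdc25`, `Wee1`, `Gwl`, `ENSAPt` (total
phospho-ENSA) and `PP2` (free PP2A/B55); for example

```
MPF'  = [k25'(Cdc25T−Cdc25) + k25''·Cdc25](CycT − MPF) − [kwee'(Wee1T−Wee1) + kwee''·Wee1]·MPF
PP2'  = −kas(ENSAPt − (PP2T−PP2))·PP2 + (kdis + kiensa)(PP2T − PP2)
```

with reversible Cdk1 and PP2A inhibitors entering through the active
fractions `MPFa = MPF/(1+RO)` and `PP2a = PP2/(1+OA)`. Because the
phosphatase reversing Gwl activation is not established, three model
variants are provided: Gwl dephosphorylated by an OA-insensitive
phosphatase, by an OA-sensitive phosphatase outside the B55 feedback,
or by PP2A/B55 itself (which closes one more double-negative loop).
See the methods vignette (`vignettes/mitotic-switch-model.Rmd`) for the
full equations, parameters and design notes.

The package provides

- stiff integration of the network and the three chemical-perturbation
  protocols (mitotic entry by Cdk1-inhibitor release, entry by okadaic
  acid, exit by Cdk1 inhibition), with event-timing metrics,
- steady states, linear stability, balance curves in total Cyclin B
  with saddle-node fold location, and bistability maps over kinetic
  parameters,
- a synthetic pseudo-immunoblot readout layer (noisy sparse sampling of
  trajectories) with t50 estimation and bootstrap ordering tests,
- one-command, seeded, manifest-logged reproduction experiments and a
  thin CLI (`inst/cli/mitoswitch.R`).

## Worked example

Mitotic exit under strong Cdk1 inhibition, comparing the three
Gwl-phosphatase variants:

```r
library(mitoswitch)

t50 <- sapply(c("pp2a_b55", "oa_insensitive", "oa_sensitive"), function(sc)
  t_cross(run_protocol(sc, "exit"), "Gwl", direction = "down"))
round(t50, 2)
#>       pp2a_b55 oa_insensitive   oa_sensitive
#>          13.24           0.36           0.72
```

Gwl inactivation is near-instantaneous when its phosphatase is
constitutive (t50 ≈ 0.4 time units) but delayed ~40-fold when Gwl is
dephosphorylated by PP2A/B55 itself, because the phosphatase must first
be released from ENSA-P sequestration — the model's key discriminating
prediction for mitotic exit.

The bistable window in total Cyclin B, and the stable mitotic state:

```r
br <- balance_curve("pp2a_b55", n = 101)
attr(br, "folds")
#> [1] 0.04964844 0.19949219          # saddle-node folds: bistable window

eq <- find_steady_state(scenario_parameters("oa_sensitive"), metaphase_state())
round(as.numeric(eq$state), 4)
#> [1] 0.9632 0.9725 0.0275 0.9042 0.7509 0.0272   # MPF ... PP2, stable
```

A noisy pseudo-immunoblot of OA-driven mitotic entry recovers the
prediction that Gwl phosphorylation precedes Cdk1 Tyr15
dephosphorylation:

```r
traj <- run_protocol("pp2a_b55", "entry_oa", horizon = 120)
rd <- generate_readout(traj, times = seq(0, 120, 8), sigma = 0.05, seed = 17)
ordering_test(rd, "pThr194", "pTyr15", c("up", "down"))
#> [1] 1
```

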