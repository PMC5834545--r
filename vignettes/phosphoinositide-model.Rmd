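---
title: "A power-law kinetic model of the plasma-membrane phosphoinositide pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A power-law kinetic model of the plasma-membrane phosphoinositide pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipkin)
```

## The system and the model

Phosphatidylinositol (PI) can be phosphorylated on positions 3, 4 and 5 of
its inositol ring, producing seven phosphoinositide species that, despite
their low abundance, mark membrane identity and control trafficking, ion
channels (notably the epithelial sodium channel ENaC, activated by
PI(4,5)P2), and growth signalling. `pipkin` models this interconversion
network in a single, spatially homogeneous 1 um^2 patch of plasma membrane:
8 lipid pools, 21 kinase/phosphatase-catalysed interconversions, 3 transport
influxes (PI from the ER, PI(4)P from the Golgi, PI(3)P from endosomes) and
one first-order efflux per pool.

The dynamics follow Biochemical Systems Theory in generalized mass action
(GMA) form. Every interconversion flux is a power law

$$ v_{i \to j} \;=\; \gamma_{i \to j} \, E_{i \to j} \, X_i^{\,f_{i \to j}}, $$

with rate constant $\gamma$, enzyme-group activity $E$ (mg/um^2) and the
substrate abundance $X_i$ (molecules/um^2) raised to its kinetic order $f$.
Each pool obeys $\dot X_i = \sum_s v_{s\to i} - \sum_p v_{i\to p}$, all
stoichiometries are 1:1, and ATP/ADP/water/phosphate are treated as
saturating and not modelled. Time is in minutes. Effluxes are first order
with one shared rate constant $k_e$; since effluxes are the only route out
of the patch, at steady state the total influx equals $k_e$ times the total
pool, so the constraint that 4.5% of the membrane phosphoinositides recycle
per minute pins $k_e = 0.045\,\mathrm{min}^{-1}$ exactly.

```{r network}
model <- load_network()
model
```

The network file is the single source of truth for the topology. Fifteen of
the 21 interconversions are named directly in the primary descriptions of
this pathway; the remainder follow standard phosphoinositide biochemistry
(SAC1 for PI(4)P to PI, INPP4 for PI(3,4)P2 to PI(3)P, FIG4 for PI(3,5)P2
to PI(3)P, myotubularins for PI(3)P to PI). One arrow is deliberately
anonymous: the PI(5)P phosphatase returning PI(5)P to PI is not firmly
identified in the literature, so its enzyme group is labelled `PI5P_PASE`
rather than guessing a gene. Two fluxes deserve comment because they are
not universally accepted mechanisms: the direct channelling of PI to
PI(4,5)P2 by a PI4K + PIP5KI + DVL ternary complex (`v0->45`) and its
synaptojanin-mediated reverse (`v45->0`). Both are required to keep the
PI(4,5)P2 pool stable when PI(4)P is depleted, which is the central
behaviour this model exists to capture.

## The reference parameterization

No machine-readable parameter table is distributed with the primary
literature, so the package ships a committed reference set
(`reference_params()`), fitted in-house under the documented constraints
and exposed behind the same interface a transcribed table would use:

* the shared efflux constant is 0.045/min (the recycling constraint above);
* the slow PI(3,4,5)P3 to PI(3,4)P2 rate law uses the documented constants
  $\gamma = 10^{11}$, $f = 0.9982$ with a SHIP activity of $10^{-15}$
  mg/um^2 (the fast alternative, $\gamma = 6\times 10^{13}$, $f = 0.9998$,
  is available as the preset `v345_34_fast`);
* apical and basolateral membrane configurations impose the reported PTEN
  and PI3KI activities (2.3e-15 / 6.1e-16 and 3.9e-17 / 1.5e-14 mg/um^2);
  the reference activities lie between the two, on the apical side;
* the PI(3)P influx is kept at 1/25 of the PI(4)P influx, so scaling it
  25-fold makes the two transport routes comparable;
* steady-state pools must sit inside literature-derived intervals
  (`steady_state_targets()`), with PI(4,5)P2 and PI(4)P near 10,000
  molecules/um^2 and PI the dominant reservoir (~500,000 molecules/um^2 —
  the value is not free: for a 98% PI-supply shutdown to leave half the
  basal PI(4,5)P2, the conservation relation total pool = influx/$k_e$
  requires the basal PI reservoir to dwarf the signalling pools).

The remaining degrees of freedom (the basal flux distribution and the
kinetic orders of the kinase-catalysed fluxes) were fitted against the
documented perturbation outcomes themselves: the knockout panel
percentages, the PI(4,5)P2 source decomposition, the PI-supply shutdown
series and the membrane-polarity states. Two features of the fitted set
carry the mechanism:

* `v0->45` supplies roughly half the basal PI(4,5)P2 production and has a
  strongly sublinear kinetic order, so the channel keeps producing when PI
  falls — this is what buffers PI(4,5)P2 against PI loss (an 11% drop when
  PI halves) while still letting a PI4K knockout bite (the complex is
  removed with it);
* `v45->4` (the SIOSS 5-phosphatases) carries about half of the PI(4,5)P2
  consumption, which is what makes a doubling of SIOSS activity remove a
  third of the pool.

```{r params}
params <- reference_params()
params
ss <- find_steady_state(model, params)
round(ss$abundances, 1)
```

## Numerical choices

Steady states are found by long LSODA integration (the system is stiff:
pool sizes and rate constants span five orders of magnitude) followed by a
damped-Newton refinement of the right-hand side; a Newton solve from the
supplied start is tried first and accepted only if the root is locally
attracting (all Jacobian eigenvalues with negative real part). The
convergence criterion is $\max_i |\dot X_i| / \max(X_i, 1) < 10^{-9}$ per
minute. Integration tolerances default to rtol 1e-8 / atol 1e-10
molecules/um^2; states are floored at zero for flux evaluation and a
negative excursion beyond ten times the absolute tolerance is an error
rather than silently clipped. These are package decisions — the primary
descriptions of the pathway do not state integrator settings.

Monte-Carlo screening uses a deliberately bounded steady-state search
(Newton from three starts, one fixed-horizon integration, one refinement);
a candidate whose steady state is not located within that budget is
rejected as inadmissible. This trades a minuscule false-rejection rate for
a hard bound on screening cost.

Local sensitivities are central finite differences of the steady state with
a 1% parameter step, reported as dimensionless relative (logarithmic)
sensitivities — the convention of the field, chosen here because the
underlying analytic convention is not published. Entries are recomputed at
half the step and flagged when they move more than 20%.

## Perturbations and their conventions

Knockouts set an enzyme activity to zero, which by linearity of the rate
law in $E$ is equivalent to zeroing the rate constants of every flux the
enzyme catalyses. Knocking out PI4K or PIP5KI also removes the ternary
complex (its activity is scaled by the same factor); knocking out only the
complex leaves the single-enzyme fluxes intact. In the source-decomposition
experiment all external inputs into the PI(4)P/PI(4,5)P2 pair are stopped
while their mutual exchange (`v4->45`, `v45->4`) stays active — this is the
reading under which re-activating the Golgi PI(4)P influx can raise
PI(4,5)P2 at all — and `v0->4` is kept at 20% of its rate constant to avoid
numerically degenerate PI(4)P levels. Because the documented baseline of
the "9% increase" readout for that influx is ambiguous, the experiment
reports the readout against both the basal and the all-blocked baseline.
For the siRNA panel, phosphatase upregulations default to a factor of 2
(the documented SIOSS case); the factor is an exposed argument because the
literature does not fix it for the other phosphatases.

## Calibration, fitting and identifiability

The calibration surface is a set of pool intervals plus a registry of 13
dynamic phenomena (`phenomena_registry()`), each a preset perturbation with
a machine-checkable expectation. The adjustment score is a sum of squared
relative distances to the interval bounds and expectation bands: zero
exactly when everything is met. The exact functional form of the published
score is not available, so the convention is declared here and isolated
behind `adjustment_score()` where it can be swapped without touching the
fitting code. The reference set reproduces 11 of the 13 phenomena; the two
failures are themselves documented behaviour of the model being
reproduced: a 50% PI drop lowers PI(4,5)P2 by only ~11% instead of the
reported ~50%, and reducing MTMR to 65% leaves PI(5)P essentially basal
(98.97%) instead of dropping it to 20%.

`fit_ga()` implements the estimation machinery: a seeded genetic algorithm
(population 100, 300 generations, tournament selection k = 3, uniform
crossover 0.7, log-space Gaussian mutation of 0.1 decades at rate 0.15,
elitism 2 — declared defaults, as the published settings are not in the
main text) with an optional Nelder-Mead polish. `monte_carlo_search()`
samples parameter space log-uniformly (default 1.5 decades around the
reference, kinetic orders uniform in [0.5, 1.2]) and filters by the four
admissibility conditions: pools inside their intervals, the coarse pool
ordering, influxes below 25% of the receiving pool, effluxes below 7%.
Candidate draws are seeded per index from the master seed, so results are
independent of evaluation order and worker count. At these default ranges
the admissible fraction is far below 5% — the parameterization is tightly
constrained by the steady-state surface alone, mirroring the scarcity of
admissible sets reported for this pathway (the published absolute counts
depend on sampling ranges that are not available, so they are not targeted).

## What the synthetic scenarios do and do not show

`generate_scenario()` builds ground-truth parameter sets by jittering
reference rate constants, then derives pool targets (multiplicative
lognormal noise — abundances are positive and span orders of magnitude) and
phenomenon outcomes by simulating the truth. This makes parameter-recovery
claims testable without any external data: with three free parameters and
zero noise, the GA recovers the truth within a few percent. What passing
such tests does *not* show is that the biological parameters are right —
recovery harnesses validate the estimation machinery on data generated by
the model's own equations, with none of the structural mismatch,
measurement bias or cross-compartment leakage of real lipidomics data.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run every reproduction at the
scale the package is meant to be used: single steady states (seconds), the
13-phenomenon suite, sensitivity matrices over all 84 parameters, a
Monte-Carlo screen of 5,000 candidate sets, and GA recoveries over 2-3 free
parameters with small populations. These sizes were chosen so a complete
verification runs on a laptop in minutes while still exercising every code
path at meaningful scale.

## Known limitations

* One homogeneous membrane patch: no compartments, no spatial gradients,
  no organelle exchange beyond the three influx terms.
* Deterministic ODEs over molecule counts; pools of a few molecules per
  um^2 (apical PI(3,4,5)P3) are treated as continuous.
* No regulatory feedbacks (product activation of PTEN/PI3KI, PI(5)P
  inhibition of SHIP) and no substrate competition among the
  multi-substrate phosphatases; step-change perturbations only.
* The committed parameter set is a constrained refit, not a transcription;
  if the original tables become available they can replace the fixture
  behind `reference_params()` and every test applies unchanged.
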