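# pipkin — power-law kinetics of the plasma-membrane phosphoinositide pathway

Phosphoinositides — phosphatidylinositol (PI) and its seven derivatives
phosphorylated on positions 3, 4 and 5 of the inositol ring — form a dense
interconversion network that marks membrane identity and controls
trafficking, growth signalling and ion channels. PI(4,5)P2 in particular
activates the epithelial sodium channel ENaC, which makes the control of
its pool size a therapeutic question in cystic fibrosis. `pipkin` is an R
package for simulating and interrogating this network in a 1 µm² patch of
plasma membrane: who supplies PI(4,5)P2, which enzyme knockdowns deplete it
(and with what side effects on the other lipids), and how tightly the
parameters are constrained by the observable steady states.

## The model

The pathway is a generalized mass action (GMA) system in the tradition of
Biochemical Systems Theory. Eight lipid pools `X_i` (molecules/µm²,
indexed by phosphorylated positions: `0` = PI, …, `345` = PI(3,4,5)P3) are
coupled by 21 enzyme-catalysed interconversions, three transport influxes
and one first-order efflux per pool:

```
dX_i/dt = Σ_s v_{s→i} − Σ_p v_{i→p},      v_{i→j} = γ_{i→j} · E_{i→j} · X_i^{f_{i→j}}
```

where `γ` is a rate constant, `E` the catalysing enzyme-group activity
(mg/µm²) and `f` the kinetic order of the substrate. Effluxes share a
single rate constant of 0.045/min, which makes 4.5% of the membrane
phosphoinositides recycle per minute. The package bundles the network
definition (YAML), a committed reference parameterization (CSV), a
perturbation preset registry, a calibration registry of 13 literature
phenomena, and modules for stiff ODE simulation, steady-state location,
local sensitivity analysis, genetic-algorithm fitting and Monte-Carlo
identifiability analysis.

## A worked example

```r
library(pipkin)

model  <- load_network()
params <- reference_params()
basal  <- find_steady_state(model, params)
round(basal$abundances)
#>      0      3      4      5     34     35     45    345
#> 500000    500  10000    300    150     50  10000     20
```

The basal patch holds ~10,000 PI(4,5)P2 molecules/µm² on a PI reservoir of
~500,000. Knocking out the kinase PIP5KI (which also removes the
PI4K+PIP5KI+DVL complex it is part of) collapses PI(4,5)P2:

```r
ko  <- apply_perturbation(params, knockout_preset("pip5ki_ko"), model)
ss  <- find_steady_state(model, ko, x0 = basal$abundances)
round(100 * ss$abundances["45"] / basal$abundances["45"], 1)
#>   45
#> 12.4
```

PI(4,5)P2 falls to ~13% of basal — the strongest single intervention in
the siRNA panel (`run_sirna_panel()`), which also predicts the direction
of ENaC activity for each screened enzyme. The source decomposition asks
which inputs can sustain the pool on their own:

```r
dec <- run_source_decomposition(model, params)
subset(dec$readouts, species == "45", c(perturbation, pct_of_basal))
#>          perturbation pct_of_basal
#>   unperturbed control       100.00
#>    all inputs blocked        20.87
#>           only v0->45        78.67
#>           only v5->45        35.86
#>         only v345->45        21.22
#>             only v->4        26.65
```

The direct PI → PI(4,5)P2 channel `v0->45` alone maintains ~80% of the
pool; the PI(5)P route `v5->45` ~34%. The apical/basolateral membrane
states differ only in PTEN and PI3KI activities yet move PI(3,4,5)P3 from
~2 to ~760 molecules/µm² (`run_membrane_polarity()`). The calibration
suite (`run_phenomena_suite()`) checks all 13 registry phenomena; the
reference set reproduces 11, failing exactly the two documented
shortcomings (PI-drop propagation to PI(4,5)P2, and the MTMR2 effect on
PI(5)P).

## Package layout

| Path | Contents |
| --- | --- |
| `R/network.R`, `R/parameters.R` | pathway definition, validation, parameter tables |
| `R/dynamics.R` | GMA fluxes, LSODA simulation, steady-state search |
| `R/perturbation.R` | composable knockout/knockdown specifications, presets |
| `R/calibration.R` | pool intervals, phenomena registry, adjustment score |
| `R/estimation.R` | genetic algorithm, Monte-Carlo identifiability |
| `R/sensitivity.R` | relative steady-state sensitivities, high-|S| network |
| `R/experiments.R` | scripted reproductions of the reference experiments |
| `R/synthetic.R` | ground-truth scenarios for estimation benchmarks |
| `inst/extdata/` | network YAML, reference parameters CSV, registries |
| `vignettes/phosphoinositide-model.Rmd` | the model, assumptions, and design decisions |
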