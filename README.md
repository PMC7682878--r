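# splitFPquant

Quantitative analysis of split fluorescent protein (split-FP)
complementation from flow cytometry and microscopy.

Split-FP systems divide a fluorescent protein between beta-strands 10 and
11: the large FP<sub>1-10</sub> fragment and the 16-residue FP<sub>11</sub>
peptide reassemble into a fluorophore only when bound, so a tagged cell's
brightness depends on the *complementation efficiency* — how completely
the binding equilibrium runs to the complex — not just on expression.
This package is for protein engineers and imaging groups who compare
split-FP variants: it implements the binding model that turns a log-log
slope into a readout of the effective dissociation constant, the
flow-cytometry pipeline that measures that slope from single-cell data,
the microscopy pipeline that quantifies signal amplification from tandem
FP<sub>11</sub> tags, and synthetic-data generators with retained ground
truth so every estimator is testable end to end.

## The model in brief

At equilibrium, with total fragment concentrations $A$ and $B$ and
effective dissociation constant $K_D$, the complemented concentration $C$
is the smaller root of

$$(A - C)(B - C) = K_D\,C .$$

When expression is proportional ($A = rB$, arranged experimentally by
co-transfection with a P2A-coupled blue reporter measuring $B$):

* $K_D \gg A,B$ gives $C \approx rB^2/K_D$ — **slope 2** of
  $\log_{10}(\text{green})$ on $\log_{10}(\text{blue})$;
* $K_D \ll A,B$ gives $C = \min(A,B)$ — **slope 1** (saturated
  complementation).

A fitted slope between 1 and 2, rescaled by a full-length (unsplit)
control so that strict proportionality reads exactly 1, therefore places
a variant's effective $K_D$ on the scale of cellular concentrations. For
tandem tags, $n$ FP<sub>11</sub> copies per target compete for a shared
free FP<sub>1-10</sub> pool ($n$ independent identical sites), which caps
the per-molecule amplification strictly below $n$ for any finite pool —
the model's account of sub-linear 5x amplification. A one-sided Welch
test on per-field median intensities decides whether a 5x construct
out-shines its 1x counterpart.

## Worked example

Simulate a co-transfection at intermediate binding strength
($K_D = 10\times$ the median fragment concentration), together with its
two controls, and run the full pipeline:

```r
library(splitFPquant)

cfg <- flow_sim_config(n_events = 20000, kd = 10, seed = 1, rho = 1,
                       doublet_fraction = 0.05)
ucfg <- cfg; ucfg$transfected_fraction <- 0

samples <- list(untransfected = simulate_untransfected(ucfg),
                full_length   = simulate_full_length_control(cfg),
                split         = simulate_flow_experiment(cfg))
run_flow_analysis(samples)
#> <flow_report>
#> thresholds (log10): green 2.162, blue 2.085
#> control raw slope: 0.9974
#>   split            rescaled slope 1.536 (raw 1.532, n = 4833)
```

Reading the output: the fluorescence thresholds are the 0.999 quantile of
the gated untransfected control on the log10 axis; the full-length P2A
control fits a raw slope of 0.9974 (proportional production, as it
should); and the split sample's slope, rescaled by the control, is 1.536
— between the saturated (1) and weak-binding (2) limits, diagnosing an
effective $K_D$ near the tested expression levels. 4,833 events survived
saturation filtering, the density scatter gate, the singlet gate and
thresholding to enter the fit.

The imaging side works the same way from `simulate_imaging_experiment()`
through `run_image_analysis()`, ending in a fold change and one-sided
Welch $p$-value; `analysis/04_tandem_amplification.R` is a complete
worked run.

## Analysis scripts

The `analysis/` directory holds the narrative drivers, each writing its
tables and figures under `results/`:

1. `01_slope_theory.R` — closed-form slope versus $K_D$ (the kd-to-slope
   table spanning limits 1 and 2).
2. `02_flow_pipeline.R` — gating chain and rescaled slopes for three
   simulated variants ordered by $K_D$.
3. `03_slope_recovery.R` — pipeline slope versus closed-form prediction
   across four decades of $K_D$ (agreement within ~0.03).
4. `04_tandem_amplification.R` — shared-pool model curves and the
   simulated 1x-vs-5x microscopy comparison.

`run_end_to_end()` chains simulation and both analyses under one master
seed and writes JSON reports, figures and an md5 manifest;
`inst/extdata/example_config.yaml` shows the full configuration surface.

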