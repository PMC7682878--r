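---
title: "Quantifying split-FP complementation: models, pipelines and simulation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying split-FP complementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitFPquant)
```

## The measurement problem

Split fluorescent proteins divide an FP between beta-strands 10 and 11: a
large FP$_{1\text{-}10}$ fragment and a 16-residue FP$_{11}$ peptide that
self-associate to reconstitute the fluorophore. Only the bound complex
fluoresces, so the brightness of a tagged cell depends not just on
expression but on how completely the two fragments find each other — the
complementation efficiency, governed by the effective dissociation
constant $K_D$ of the fragment pair relative to their cellular
concentrations. This package implements the quantitative machinery for
measuring that efficiency from single-cell data: an equilibrium binding
model, a flow-cytometry slope assay, a microscopy assay for tandem-tag
signal amplification, and synthetic-data generators that stand in for the
wet-lab inputs.

## The equilibrium model and the slope readout

With total concentrations $A$ (FP$_{1\text{-}10}$) and $B$ (FP$_{11}$),
the complemented concentration $C$ is the smaller root of

$$(A - C)(B - C) = K_D\,C,$$

computed in the cancellation-free form $C = 2AB / (A + B + K_D + s)$ with
$s = \sqrt{(A+B+K_D)^2 - 4AB}$, and verified in the test suite against
bracketed root-finding to $10^{-9}$ relative error. Two limits matter:

* $K_D \gg A, B$: $C \approx AB/K_D$. If expression is proportional
  ($A = rB$), $C \propto B^2$ — slope 2 on log-log axes against an
  expression reporter.
* $K_D \ll A, B$: $C = \min(A, B)$ — slope 1; complementation is
  saturated.

`predicted_slope()` evaluates the transition between the limits as an
ordinary-least-squares fit of $\log_{10} C$ on $\log_{10} B$ over a
log-spaced grid (default 50 points), mirroring how the slope is estimated
from scattered cells rather than as a point derivative. A fitted slope
therefore places the effective $K_D$ on the scale of cellular
concentrations: the assay behind comparing split-FP variants.

The experimental design couples the FP$_{11}$ fusion to a blue reference
protein through a self-cleaving P2A site, so the blue channel reports $B$.
A full-length (unsplit) control — where green is produced in strict
proportion to blue — calibrates away channel-specific gains and laser
settings: sample slopes are divided by the control slope so that a 1:1
relationship reads exactly 1.

## Flow-cytometry pipeline

`run_flow_analysis()` applies, in fixed order: saturation filtering
(any channel at its ADC ceiling), a kernel-density scatter gate on
(log FSC-A, log SSC-A) retaining the highest-density fraction of events
(default 0.5, Scott's-rule bandwidth — deterministic, unlike a hand-drawn
gate), an FSC-A/FSC-H singlet gate (band 0.8–1.3; a two-cell droplet
roughly doubles pulse area but not height), autofluorescence background
subtraction, the log$_{10}$ transform (non-positive values dropped and
counted, never imputed), per-channel thresholds at the 0.999 quantile of
the gated untransfected control, and OLS fits with control rescaling.
Every stage records its survivor mask, so retention is auditable and
provably monotone.

Two pipeline choices deserve explanation:

* **Background subtraction.** The median autofluorescence of the gated
  untransfected control is subtracted from both fluorescence channels
  before the log transform (`subtract_autofluorescence = TRUE`). Without
  it, the additive autofluorescence floor lifts the low-expression end of
  every log-log fit and flattens the slope well below its limiting value
  (≈1.7 instead of 2.0 at weak binding in our simulations); with it, the
  fitted axes measure signal above background.
* **Minimum events.** Fits with fewer than 100 events are flagged
  unreliable rather than refused: a regression on a handful of cells is
  reported, but marked.

## What the flow simulator emulates

`simulate_flow_experiment()` draws transiently co-transfected cells with
log-normal FP$_{11}$ expression (default spread 1 decade of standard
deviation — a ~4-decade population, as transient transfection produces),
FP$_{1\text{-}10}$ at a median ratio of 2 (the transfected plasmid mass
ratio) with correlation `rho` between the log-expressions, Gaussian
autofluorescence on both fluorescence channels, correlated log-normal
scatter channels, doublets formed by summing two singlets' area-type
channels (FSC-H takes the larger of the pair — pulse height does not
add), an untransfected subpopulation, and clipping at an 18-bit ADC
ceiling. Ground truth (per-event $A$, $B$, $C$, population label,
saturation flag) rides along as an attribute for recovery tests.

Detector gains default to auto-scaling: the 90th percentile of the
noiseless signal is placed at 25% of the ceiling, as an operator does
when setting PMT voltages for a sample spanning decades. The top few
percent of events then saturate and are removed by the saturation filter
— which is why that filter exists as the first processing stage. Log-log
slopes are invariant to gain, so this choice affects which events are
fitted, not the quantity being measured.

**The role of `rho`.** The slope model assumes the two fragments are
produced in strict proportion, $A = rB$. In a real co-transfection the
coupling is imperfect; the simulator exposes it as the correlation `rho`
of log $A$ and log $B$ (default 0.7). This matters quantitatively: in the
weak-binding regime $\log C = \log A + \log B - \log K_D$, so the
population slope of $\log C$ on $\log B$ is $1 + \rho$, not 2. Slopes
near 2 observed in real data therefore imply tight co-uptake
($\rho \gtrsim 0.9$), and the package's slope-recovery and limiting-case
validations run at $\rho = 1$, the regime where the closed-form
prediction is the correct reference. Lower `rho` lets users explore how
transfection-efficiency variation attenuates the estimated gradient.

At those conditions (20,000 events, low autofluorescence, no doublets)
the pipeline's rescaled slope tracks `predicted_slope()` evaluated over
the actually-fitted expression window to within ~0.03 across
$K_D \in [10^{-2}, 10^{2}]$ times the median concentration, and reaches
the limits 2 and 1 within 0.02 (see `analysis/03_slope_recovery.R` and
the acceptance suite). What passing these tests does *not* show: real
cytometry data carry spectral spillover, instrument drift, and
non-Gaussian autofluorescence that the generator deliberately omits
(spectral compensation is out of scope), so agreement here validates the
estimator, not any particular instrument.

## Tandem tags and the shared-pool model

Fusing $n$ FP$_{11}$ copies in tandem to one target offers up to
$n$-fold signal per molecule. `tandem_free_fragment()` models the $n$
sites as independent and identical, competing for one free
FP$_{1\text{-}10}$ pool: the free concentration $a$ solves
$a + n\,b_{\text{tags}}\,a/(a + K_D) = A$ (a stable quadratic root;
conservation holds to $10^{-9}$). Per-molecule signal is $n\,\theta$ with
occupancy $\theta = a/(a+K_D)$, and `amplification_fold()` is the ratio
of the 5x to 1x signal at identical conditions. The fold is strictly
below $n$ for any finite pool — the model's explanation of sub-linear
amplification — and approaches $n$ either as the pool grows unbounded or
as binding weakens (a barely-depleted pool serves five sites as easily as
one). No cooperativity or steric penalty is modelled; that is the
simplest structure consistent with sub-linear gain, and a cooperativity
hook is deliberately absent rather than half-implemented.

## Microscopy pipeline

`run_image_analysis()` quantifies per-cell brightness in fields of tagged
nuclei: rolling-ball background subtraction (radius 20 px, implemented as
grayscale opening with a hemispherical ball element in compiled code),
a difference-of-Gaussians bandpass (sigmas `small_px/2` = 1.5 and
`large_px/2` = 20 by default; the mask is invariant to constant offsets),
Otsu thresholding with hole filling, 8-connected components, and particle
filters of 80–2000 µm² area and 0.1–1.0 circularity, both bounds
inclusive. Circularity is $4\pi A / P^2$ with a Crofton four-direction
perimeter estimator, capped at 1 (a rasterized disk measures ≈0.97).
Each cell's intensity is the median of the background-subtracted pixels
in its particle — medians, not means, exactly as the assay prescribes.
Per condition, replicate fields are summarized by the median of per-cell
medians and by bin-wise averaged normalized histograms (shared edges from
the pooled 1st–99th percentile range, 50 bins) with a standard-deviation
band.

The 1x-versus-5x comparison is Welch's unequal-variance $t$-test on the
per-field medians, one-sided with the alternative that the 1x mean minus
the 5x mean is below zero, alongside the fold change (ratio of condition
means of field medians). Both variances zero with equal means returns
$p = 0.5$, flagged as degenerate.

`render_field()` supplies the synthetic fields: non-overlapping elliptical
nuclei (default radius 12 ± 1.5 px at 0.65 µm/px — a 6.5 µm camera pixel
at 10× — giving areas near 200 µm², comfortably inside the size filter),
per-cell log-normal intensities with CV 0.35 around
`intensity_scale × condition_fold`, a background plane plus lateral
gradient, Poisson photon noise and Gaussian read noise, quantized to 16
bits. Replicate fields jitter `intensity_scale` with CV 0.1, emulating
day-to-day variation; seeds derive deterministically from the master
seed. On these fields the pipeline matches ≥90% of ground-truth cells at
IoU ≥ 0.5 and recovers per-cell intensities at $r \ge 0.95$; a simulated
2.3-fold condition difference is recovered within 15% with a significant
one-sided test, and 200 null simulations hold the type-I error at the
nominal 5% within binomial error. The generator omits point-spread
blurring, spectral bleed-through and photobleaching; segmentation
performance on real images, particularly touching nuclei, is not
certified by these tests.

## Numerical and interface choices

* Problem sizes in the validation suites — 20,000 events × 5 seeds for
  slope recovery, 200 null imaging seeds on 128×128 fields, a 1,000-point
  parameter grid for the root-finding cross-check — were chosen to make
  Monte-Carlo error small against the tolerances being asserted while
  keeping a full run in minutes on one core.
* All randomness flows from explicit seeds; identical configuration and
  seed reproduce every generator bit-for-bit, and `run_end_to_end()`
  writes a manifest with md5 hashes of every output.
* Event tables read from FCS 3.0/3.1 (a minimal reader covering float and
  integer list-mode data, with `$PnR` as the channel ceiling) or from the
  CSV dialect the simulator writes; unknown channels and missing ceilings
  are errors, never guesses.
* Degenerate inputs have documented behavior: zero events is an empty
  table; a flat image yields an empty mask with a warning; cells that
  cannot be placed without overlap reduce the count with a warning;
  non-positive values at the log step are dropped and counted.

## Known limitations

The equilibrium model ignores kinetics — association rates, fluorophore
maturation, degradation — so it speaks to steady-state brightness only.
The scatter/singlet gates are standard constructions, not replicas of any
instrument's hand-drawn regions. The slope assay's absolute calibration
depends on the proportional-expression assumption discussed above;
reported slopes from populations with loose fragment coupling
under-estimate the weak-binding limit. And the tandem model's
independent-site assumption cannot produce the complete absence of
amplification seen for some fragment pairs; explaining that requires
structure (steric exclusion) outside this package's scope.
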