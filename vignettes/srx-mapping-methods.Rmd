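---
title: "Mapping myosin SRX/DRX populations along the cardiac thick filament: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping myosin SRX/DRX populations along the cardiac thick filament}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srxmap)
```

## The measurement and the model

Cardiac myosin heads in a relaxed sarcomere populate two biochemical
states: a disordered-relaxed state (DRX) that turns over ATP with a
lifetime of roughly ten seconds, and a super-relaxed state (SRX) whose
turnover is slowed to hundreds of seconds. Because a fluorescently
labelled ATP (e.g. Cy3-ATP) stays bound to a head for one turnover time,
the dwell time of a single fluorescent spot on a myofibril reports the
state of the head that bound it, and the spot's super-localized position
reports *where* along the thick filament that head sits. Binning events by
axial distance from the M-line into the P-zone (0–159 nm), the
cMyBP-C-containing C-zone (160–500 nm) and the D-zone (501–800 nm) turns a
dwell-time experiment into a spatial map of thick-filament regulation.

`srxmap` implements this analysis end to end:

1. **Events.** Detected spots are linked into binding events (or TrackMate
   exports are ingested), drift-corrected against Z-disk fiducials.
2. **Geometry.** Z-disks are paired into sarcomeres; sarcomeres shorter
   than 1.7 µm are discarded as not clearly relaxed; each event is folded
   about the nearest M-line and binned into a zone.
3. **Kinetics.** Dwell times are accumulated into a cumulative
   residence-time histogram (CRTH) — the number of events lasting at least
   $t$ — and fitted by least squares with a sum of exponentials
   $A(t) = \sum_i A_i e^{-k_i t}$. Three components are required: fast
   nonspecific nucleotide association (~1.4 s), DRX turnover (~11.9 s) and
   SRX turnover (~284 s). Phases are identified by rate order, never by
   fit order.
4. **Corrections.** Fitted rates are photobleach-corrected by subtracting
   the bleach rate scaled by the illuminated duty cycle. Amplitudes count
   *events*, and a faster-cycling head produces proportionally more events
   per unit time, so amplitudes are converted to molecule fractions by
   weighting each specific phase by the DRX/SRX rate ratio:
   $\%SRX = 100\,A_3 (k_2/k_3) / (A_2 + A_3 (k_2/k_3))$. The nonspecific
   phase never enters this number.
5. **Uncertainty.** Event durations are resampled with replacement, the
   constrained fit is repeated per replicate, and the 2.5th/97.5th
   percentiles give the 95% CI. Group differences are called significant
   when CIs do not overlap (touching endpoints count as overlap).

## Zonal constraints

A single zone contains too few slow events to determine six parameters
freely, so zonal fits are anchored to the all-zones fit: each zonal rate
may vary within ±20% of the corresponding all-zones rate, and the summed
zonal amplitudes within ±20% of that zone's own event total. The
constraint is implemented as box bounds in a reparameterised optimiser
(log-rates; amplitudes as a total times a softmax composition, which makes
the amplitude-sum constraint a box bound too) with analytic gradients,
multi-start from log-spaced rate initialisations, and ties broken toward
the smallest slow rate. We interpret "within 20% of the all-zones data"
for amplitudes on each zone's own scale (1.0 for normalized curves): zones
are fitted independently, so a cross-zone amplitude coupling would have no
operational meaning.

## The synthetic-data generator

No public raw dataset exists for this experiment, so the package ships a
generator whose defaults *are* the study conditions: lifetimes
1.4/11.9/284.3 s; molecule-level zonal SRX fractions P 56.7%, C 53.7%,
D 44.1%; sarcomere length 1.82 µm; localization SDs 28.1/38 nm
(nucleotide) and 68.2/135.4 nm (Z-disks); a stroboscopic six-frame cycle
of five 200-ms nucleotide frames plus one Z-disk frame; 3,638 events per
experiment. Molecules are the sampling unit: each event's state is drawn
with probability proportional to molecule fraction × turnover rate, which
is exactly the observation bias the rate-ratio correction later removes.
Two stated acquisition figures (1,000 frames; 30 minutes) are mutually
inconsistent with a literal 2.8-s cycle, so the default spreads 166 cycles
over 30 minutes; the schedule is an explicit input for anything else.

The generator reproduces the features the analysis depends on —
exponential dwell mixtures, rate-biased event sampling, mirrored uniform
axial placement, frame censoring, photobleach truncation over illuminated
time, drift, localization noise — and deliberately omits camera-specific
noise, thin-filament regulation, and spatially structured nonspecific
binding (assumed uniform, as nothing better is known). The fraction of
events that are nonspecific is not reported for the original experiment;
the default of 0.5 reflects the visually dominant fast phase in published
cumulative curves of this assay family. Passing tests on these data
validate the pipeline's arithmetic and statistical behaviour, not the
instrument model.

Two observation modes matter. The faithful stroboscopic schedule censors
dwell times onto a coarse lattice (five 0.2-s frames, then a long gap):
short nonspecific events are mostly missed and observed durations are
grid-discretised, so a smooth three-exponential necessarily misfits the
lattice structure. Dwell-time-level validation therefore uses an
idealised continuous schedule (`continuous_schedule()`, `censor = FALSE`),
isolating the kinetics from acquisition artifacts; acquisition effects are
tested separately.

## Numerical and statistical choices

* **Fit points.** One point per unique observed duration; duplicates
  contribute multiplicity to the counts. The objective is unweighted
  squared error on the cumulative curve — chosen for fidelity to the
  original spreadsheet-solver analysis, not for efficiency. A
  maximum-likelihood cross-check appears in the tests only.
* **Model-count selection.** Models with 1–4 components are fitted in
  sequence; the smallest model whose maximum |residual| is below 0.5% of
  events *and* whose residuals show no systematic structure is selected.
  The structure test is a Wald–Wolfowitz runs test applied to increments
  of the residual between ~21 probe points (bin-count residuals):
  cumulative-curve residuals are strongly serially correlated, and the
  increments are close to independent, which keeps the test calibrated
  (~95% pass rate under a correct model).
* **Degenerate fits.** Unconstrained fits whose adjacent rates collapse
  within 5% are refitted with one fewer component (warning). Constrained
  fits inherit phase identities from their reference and are exempt.
* **Bleach correction.** Default bleach rate is zero — stroboscopic
  imaging suppresses bleaching and no correction magnitude is published;
  the linear form $k_{corr} = k_{fit} - k_{bleach}\,d$ (duty cycle $d$) is
  exact for bleaching that accrues only during illumination.
* **Zone boundaries.** The printed integer bounds (159/160, 500/501 nm)
  are realised as half-open intervals cut at 159.5 and 500.5 nm so no
  nanometre gap exists. Events projecting beyond 800.5 nm, outside every
  sarcomere, or more than 500 nm off-axis are excluded with an itemised
  reason. The bare-zone (~0–80 nm) is not excluded from the P-zone.
* **Drift.** Pure translation, median of matched fiducial displacements,
  linearly interpolated between Z-disk frames; frames with fewer than
  three fiducials hold the last estimate.
* **Linking.** Greedy nearest-neighbour with a 100-nm cap and 5-frame gap
  closing. Single-molecule densities here are sparse enough that greedy
  assignment agrees with optimal assignment; TrackMate ingestion is the
  fidelity path for real data.
* **Determinism.** Every stochastic stage takes a seed; the pipeline fans
  per-stage seeds out from one master seed, and a rerun of the same
  configuration is byte-identical on disk.

## What the method can and cannot resolve

Two quantitative limitations emerge from the package's own simulations and
are worth stating plainly, because they bound what per-zone %SRX values
from data of this size can mean.

**The sampling floor.** Under rate-biased observation, SRX events are only
$f k_{SRX} / (f k_{SRX} + (1-f) k_{DRX}) \approx 4\text{–}5\%$ of specific
events. An experiment of 3,638 events therefore contains only ~20–80 SRX
events per zone, and *any* estimator of the corrected zonal %SRX carries a
sampling SD of several percentage points; the least-squares CRTH estimator
measures at an SD of roughly 10–17 points per zone at this size. Per-zone
differences of a few points at n ≈ 3,600 are below this noise floor;
recovery tests in this package assert tight tolerances only at event
counts (tens of thousands) where the floor permits them.

**Anchored-bootstrap optimism.** Because replicate refits inherit ±20%
rate bands anchored to the original fit, the percentile CI cannot express
rate uncertainty beyond the band: measured coverage of a true 50% SRX zone
at n = 1,200 is ~72% rather than the nominal 95%. Bootstrap CIs produced
by this procedure (in this package as in the original analysis) should be
read as lower bounds on the real uncertainty.

The same floor applies to the published residual criterion: at n = 3,638
the empirical survival curve deviates from the true mixture by ~0.8–1.4%
of events (multinomial noise), so a maximum-residual bound of 0.5% is only
attainable at event counts several times larger; the package's selection
routine behaves accordingly (returns the cap with a warning at small n,
selects the generating model reliably at n ≈ 30,000).

## Problem sizes used in the shipped validation

The test suite simulates experiments of 1,200–60,000 events: study-size
(3,638-event) runs for the acceptance properties, 30,000–60,000-event runs
where an assertion needs to sit above the sampling floor, and B = 10–200
bootstrap replicates (the analysis default is B = 1,000). The acceptance
script regenerates its inputs from the package defaults at the study size.
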