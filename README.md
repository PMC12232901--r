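# srxmap

Subsarcomeric mapping of myosin SRX/DRX populations from single-molecule
fluorescent-ATP dwell times.

## What this package is for

In relaxed striated muscle, myosin heads divide between a
disordered-relaxed state (DRX, basal ATP turnover, lifetime ~12 s) and a
super-relaxed state (SRX, strongly inhibited turnover, lifetime ~280 s) —
the "cardiac reserve". Single-molecule imaging of fluorescent ATP
(Cy3-ATP) on permeabilized myofibrils measures both *how long* each
nucleotide stays bound (reporting the head's state) and *where* on the
thick filament it bound. Referencing positions to Z-disk fiducials and
folding about the M-line assigns each event to a zone of the thick
filament: P-zone (0–159 nm from the M-line), cMyBP-C-containing C-zone
(160–500 nm) or D-zone (501–800 nm).

`srxmap` is an R implementation of the full analysis for researchers doing
this kind of experiment: spot detection and linking (or TrackMate export
ingestion), star-map drift correction, sarcomere segmentation and zone
assignment, constrained multi-exponential dwell-time fitting, photobleach
and rate-bias corrections, and bootstrap uncertainty. Because no public
raw dataset exists, it also ships a ground-truthed synthetic-data
generator whose defaults reproduce the porcine ventricular study
conditions, so every stage is testable offline.

## The model

Dwell times are summarised as a cumulative residence-time histogram
(events lasting at least *t*) and fitted by least squares to

> A(t) = A₁·e^(−k₁t) + A₂·e^(−k₂t) + A₃·e^(−k₃t)

with phases identified by rate order: nonspecific association (~1.4 s),
DRX (~11.9 s), SRX (~284.3 s). Zonal fits are constrained within ±20% of
the all-zones rates and amplitude total. Because a faster-cycling head
produces proportionally more binding events, fitted amplitudes are
event-biased; the corrected SRX population weights the specific phases by
the rate ratio:

> %SRX = 100 · A₃(k₂/k₃) / (A₂ + A₃(k₂/k₃))

with the nonspecific phase excluded. 95% CIs come from a 1,000-replicate
bootstrap with the same constraints; significance is CI non-overlap.

## Worked example

Simulate a study-sized experiment (3,638 events, untreated zonal SRX
fractions as ground truth) under idealised continuous observation and run
the whole pipeline:

```r
library(srxmap)
cfg <- list(seed = 42,
            simulate = list(schedule = list(type = "continuous", duration_s = 3600),
                            censor = FALSE),
            bootstrap = list(enabled = TRUE, B = 200),
            fit = list(n_starts = 15, normalized = TRUE))
rep <- run_pipeline(cfg)
print(rep)
#> SRX mapping pipeline report
#>   events: 3638 analysed, 3589 zoned
#>   sarcomere length: 1820 +/- 0 nm (n=8)
#> Per-zone SRX summary (corrected %SRX of specific myosin heads):
#>  zone    n srx_percent lifetime_drx_s lifetime_srx_s   constraints
#>     P  776        63.7           12.2            293 rate_1;rate_3
#>     C 1494        57.0           13.6            354
#>     D 1319        43.0           12.5            440        rate_3
#>   all 3589        56.0           12.6            352
#>   zone comparisons (95% CI non-overlap):
#>  group_a group_b significant
#>        P       C       FALSE
#>        P       D       FALSE
#>        C       D       FALSE
```

Reading this: of 3,638 simulated events, 3,589 fell inside the segmented
A-band zones. The fitted DRX/SRX lifetimes bracket their true values
(11.9 s / 284.3 s), and the corrected per-zone %SRX estimates scatter
around the simulation truth (P 56.7, C 53.7, D 44.1) with the several-point
sampling noise that ~20–80 SRX events per zone necessarily carry — see the
methods vignette (`vignettes/srx-mapping-methods.Rmd`) for why that noise
floor matters when interpreting zonal differences. `constraints` lists
which ±20% bounds the zonal fit hit. With an output directory
(`run_pipeline(cfg, out_dir = "results")`) every stage writes its
intermediate CSV plus `report.json` and `report.md`.

Individual stages are exported — `simulate_events()`, `detect_spots()`,
`link_spots()`, `read_trackmate()`, `estimate_drift()`,
`build_sarcomeres()`, `assign_zones()`, `build_crth()`, `fit_mixture()`,
`select_n_components()`, `corrected_srx_percent()`, `zonal_pipeline()`,
`bootstrap_srx()` — so partial workflows (e.g. refitting someone's
exported dwell times) are one-liners.

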