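# nucmorph

Quantification of nuclear shape, nuclear envelope integrity, and DNA
damage markers in fluorescence microscopy.

Dysmorphic nuclei are a hallmark of cancer cells, and unrestrained
actomyosin contractility can deform the nucleus to the point of nuclear
envelope rupture: chromatin bulges out of the lamina, the
nucleocytoplasmic barrier transiently collapses, and DNA damage follows.
`nucmorph` is an R package for the image and time-series quantification
that underlies this kind of cell-biological study. It is aimed at
microscopists and computational biologists who need reproducible,
scriptable versions of measurements that are often done by hand in Fiji:

* **Nuclear morphometry** — per-nucleus area, perimeter, circularity
  `4πA/P²` (1 for a disk), and moment-ellipse aspect ratio, with a
  sub-pixel perimeter estimator so a rasterized circle actually scores 1.
* **Deformed / ruptured classification** — nuclei are segmented from the
  DNA channel; envelope-marker coverage of each nuclear boundary is
  measured, and nuclei are flagged *deformed* (low circularity) or
  *ruptured* (a contiguous envelope gap), then aggregated into cohort
  fractions.
* **Rupture-event detection** — in dual-reporter time series (NLS-tagged
  reporter marking the nucleoplasm, NES-tagged reporter marking the
  cytoplasm), rupture events appear as a sudden efflux of the NLS
  reporter with simultaneous NES influx. The detector works on the
  nuclear/cytoplasmic ratio R(t): event start = sudden drop below
  `B·(1−d_min)` of the per-cell baseline B; event end = the frame where
  nuclear re-accumulation begins; durations, depths, rates and
  NES cross-validation are reported per cohort.
* **Shape dynamics** — per-nucleus mean and sample variance of
  perimeter, circularity and aspect ratio over traced timepoints; high
  variance = dynamically deforming nuclei.
* **Damage markers** — background-subtracted per-nucleus γ-H2AX
  intensity normalized to the control mean; 53BP1 focus counting by
  scale-normalized Laplacian-of-Gaussian detection (cells with more than
  five foci scored positive); cytoplasmic aggregate counting.
* **Synthetic data with ground truth** — generators for imaging fields
  (normal / deformed / fragmented nuclei with envelope-free lobes),
  two-compartment reporter traces with injected Poisson rupture events,
  shape trajectories, and marker channels with injected foci. Every
  analysis stage is validated against this ground truth.

## Worked example: the nuclear envelope barrier assay

Simulate a depleted-cohort barrier assay (292 cells recorded for 4 h
every 2 min, rupture rate calibrated so ~56 events are expected), detect
events, and summarize:

```r
library(nucmorph)

sim <- simulate_reporter_traces(trace_spec_depleted(seed = 1))
events <- detect_rupture_events(sim$traces)
cohort_event_summary(sim$traces, events)
#>   n_cells observation_time_h n_events n_truncated events_per_cell_hour
#> 1     292                  4       50           2           0.04280822
#>   mean_duration_min
#> 1            14.875
```

50 rupture events were detected in 292 cells over 4 h (the injected
truth for this seed is 50 events; the expectation across seeds is 56),
at 0.043 events per cell-hour, with a mean open-to-resealing duration of
14.9 min among events not cut off by the recording window. A control
cohort (`trace_spec_control()`, 83 cells, rate 0) yields 0 events.

Image-based scoring works the same way:

```r
field <- simulate_nucleus_image(image_spec(
  n_nuclei = 30, width = 768, height = 768,
  phenotype_mix = c(normal = 0.6, deformed = 0.2, fragmented = 0.2),
  snr = 10, seed = 3))
seg <- segment_nuclei(field$image[, , 1], pixel_size = 0.2)
cov <- assess_envelope_coverage(seg$label, field$image[, , 2], 0.2)
rec <- classify_phenotype(merge(seg$records, cov, by = "nucleus_id"))
score_cohort(rec, "mixed")
#>   group_label n_cells fraction_deformed fraction_ruptured fraction_normal
#> 1       mixed      30         0.1666667               0.2       0.6333333
```

## Analysis workflow

The `analysis/` directory is a numbered workflow over the package that
reproduces the full study-style analysis on simulated cohorts, writing
its tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohorts.R` | simulate imaging fields, reporter traces, trajectories |
| `02_segment_and_classify.R` | segmentation, coverage, phenotype fractions, χ² |
| `03_rupture_detection.R` | event detection and cohort rate/duration summary |
| `04_shape_dynamics.R` | trajectory variance, Welch t between groups |
| `05_dna_damage.R` | γ-H2AX normalization, 53BP1 positivity, aggregates |

Run them in order with `Rscript analysis/01_simulate_cohorts.R`, etc.

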