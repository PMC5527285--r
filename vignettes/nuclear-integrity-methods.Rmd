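---
title: "Quantifying nuclear shape, envelope rupture, and DNA damage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear shape, envelope rupture, and DNA damage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

# Scope

`nucmorph` quantifies nuclear integrity phenotypes in fluorescence
microscopy: per-nucleus shape descriptors, classification of deformed and
ruptured nuclei from a nuclear-envelope-marker channel, detection of
transient nuclear envelope rupture events in dual-reporter (NLS/NES) time
series, per-nucleus shape-trajectory variance for time-lapse data, and
DNA-damage marker quantification (pan-nuclear intensity, focus counts,
cytoplasmic aggregates). Because the assays it emulates deposit no public
raw data, the package ships a synthetic-data generator with exact ground
truth; every analysis stage is validated against that ground truth, and
the headline cohort statistics are recomputed end-to-end by
`scripts/acceptance.R`.

# Shape metrics

Circularity is defined as $4\pi A / P^2$: 1 for a perfect disk,
decreasing with irregularity. The definition makes the perimeter
estimator the critical numerical choice. Counting boundary pixels
overestimates the perimeter of a digitized disk by roughly 27%, which
would cap circularity near 0.79 for a perfect circle and defeat the
measure's intent. `contour_metrics()` therefore extracts a sub-pixel
contour: the binary mask is smoothed with a Gaussian (sigma 1 px) and
traced with marching squares (`grDevices::contourLines`) at level 0.5;
the perimeter is the polygon length. A rasterized disk of radius 50 px
scores circularity 0.99. Area is the pixel count times `pixel_size^2`
(smoothing affects only the contour, not the area). Aspect ratio is the
major/minor axis ratio of the second-moment equivalent ellipse, with the
1/12 variance of the unit-square pixel footprint added to the moments so
thin regions remain well-conditioned. Circularity values above 1
(digitization overshoot) are clamped to 1; the raw value is kept in a
`circularity_raw` column.

Trajectory statistics (`trajectory_stats()`) compute, per nucleus traced
over $k$ timepoints (default 5), the mean and the *sample* variance
(divisor $k-1$) of perimeter, circularity and aspect ratio. With $k = 5$
the divisor choice changes variances by 25%, so the divisor is recorded
in the output attributes. The sample variance was chosen because the
traced timepoints are a sample from a continuous deformation process,
not the full population of states.

# Synthetic imaging fields

`simulate_nucleus_image()` renders two channels, DNA and envelope marker,
for three phenotypes:

* **normal** — ellipses (axis ratio 1–1.35) with negligible contour
  perturbation; noise-free circularity is at least 0.95.
* **deformed** — the ellipse contour is modulated by low-order Fourier
  terms (orders 2–5, relative amplitudes 0.15–0.28, random phases). The
  amplitude range was chosen once so the class's noise-free circularity
  lies around 0.35–0.55, clearly below normal nuclei; this emulates
  dysmorphic, lobulated nuclei rather than mild elongation.
* **fragmented** — a main body plus an extruded chromatin lobe
  (radius 0.38–0.5 of the body) joined by a 2–4 px bridge, mimicking thin
  chromatin bridges; the envelope rim is omitted over the lobe and the
  distal bridge, so the lobe is chromatin uncovered by envelope marker.

The envelope channel is a rim (morphological gradient, 2–3 px) along each
nucleus boundary. The noise model is signal-dependent Poisson (camera
gain 5 photons per intensity unit) plus additive Gaussian read noise of
sd 1, after a 1 px Gaussian optical blur. `snr` is defined as the mean
in-nucleus signal divided by the background noise sd; the default 10 is
typical for well-exposed fixed-cell imaging. The default pixel size is
0.2 µm/px and nucleus radii default to 16–24 px; both are configurable
(`radius_px_range`), and focus-counting examples use 26–32 px nuclei so
that up to 15 well-separated foci fit.

Ground truth records, per object, the phenotype, the noise-free shape
metrics (computed with the same `contour_metrics()` the analysis uses —
the cross-module agreement is itself a test), and the truly uncovered
boundary fraction. The "covered" notion in the ground truth uses the same
3 px rim-sampling band as the measurement, so generator truth and
detector output are commensurate at the band's resolution.

Nuclei are placed by rejection sampling with non-overlap enforced on
bounding circles; an impossible density fails with an explicit error
rather than degrading silently. All generators draw from a single seeded
stream (`set.seed` at entry), so identical spec + seed gives bit-identical
output.

# Reporter traces and the two-compartment exchange model

`simulate_reporter_traces()` models each cell as two compartments with
volumes $V_n = 1$ and $V_c = 2$ and a conserved reporter amount. The
nuclear amount fraction $a(t)$ relaxes exponentially toward a
state-dependent target: the closed state holds the NLS reporter's
nuclear/cytoplasmic concentration ratio at the baseline (default 3,
import–leak balance; the emulated assay shows strong nuclear enrichment
but reports no number, so this is a generator parameter, not a claim);
during a rupture the target is the free-diffusion equilibrium
(concentration ratio 1) with time constant 1 min, so the collapse
completes within a single 2-min frame — operationalizing "sudden". After
resealing, re-import pulls the ratio back with a 3-min time constant. The
NES reporter mirrors inversely (closed-state nuclear exclusion at ratio
$1/3$). Integration is piecewise-exponential in closed form, so amount
conservation is exact to machine precision, and overlapping open windows
(e.g. a mitosis decoy colliding with an event) are merged before
integration.

Event arrivals are Poisson at `event_rate` per cell-hour. Durations are
Gamma with shape 3 and mean `mean_event_duration` (default 15 min),
resampled when shorter than 2 frames; the shape parameter is a design
choice — only the mean is an assay-level quantity. Events are kept
non-overlapping; a rate so high that more than 5% of draws would overlap
is rejected with an error. Measurement noise is multiplicative Gaussian
with CV `noise_cv` (default 0.03, matching quiet spinning-disk ratio
traces). Mitosis decoys open the barrier exactly like ruptures but are
flagged, so the detector must rely on the flag, not on trace shape.

The `trace_spec_control()` and `trace_spec_depleted()` presets encode the
emulated study's cohorts: 83 cells / 4 h / rate 0, and 292 cells / 4 h /
rate $56/(292 \times 4)$ events per cell-hour with 15-min mean duration,
sampled every 2 min.

# Rupture event detection

`detect_rupture_events()` works entirely on the per-cell N/C ratio
$R(t)$ = nuclear / cytoplasmic NLS intensity (after 3-frame median
smoothing of each channel), with a two-pass baseline $B$: a first-pass
median flags candidate event frames, and the baseline is the median of
the remaining frames. All thresholds are relative to $B$, which makes
detection invariant to global intensity scaling — arbitrary-unit
fluorescence cannot be compared across cells otherwise.

An event starts at the first frame with $R < B(1 - d_\min)$
(default $d_\min = 0.4$) that was reached by a *sudden* drop: at least
$0.25\,B$ within 2 frames. It ends when the reporter begins to
re-accumulate: the first rising frame after the event minimum, where a
rise only counts if it exceeds $0.05\,B$ per frame and must be confirmed
by 2 consecutive such rises. Two interpretations of the recovery rule
were possible — dating the end at the first rise versus after the
confirmation window; the first matches the assay's definition (duration
runs *until re-accumulation begins*) and is unbiased against injected
recovery onsets (median error within one frame), whereas the latter adds
about one frame of systematic overestimation, so the first was adopted.
The per-frame rise floor exists because on the open-state plateau
($R \approx 1$) noise produces consecutive small increases by chance;
requiring a meaningful rise prevents premature event termination without
touching genuine recoveries, whose per-frame rises are an order of
magnitude larger.

Events overlapping a mitosis flag (padded by 2 frames) are discarded;
events separated by at most 2 frames are merged; events still open at the
end of the recording are reported with `truncated = TRUE` and excluded
from mean-duration summaries (whether the emulated assay's 15-min average
included window-truncated events is unstated; excluding them is the
conservative choice and the count is reported). Cross-validation marks
events in which the NES reporter's nuclear signal rises at least 1.5-fold
over its own baseline inside the event window.

# Segmentation and phenotype classification

`segment_nuclei()` is deliberately plain: Gaussian smoothing (sigma 1 px),
a global Otsu threshold (a fixed threshold can be configured;
reproducibility was preferred over per-image tuning), hole filling,
8-connected labelling, and removal of objects under 20 µm² or touching
the border (incomplete shapes corrupt circularity). Connectivity is
8-connected specifically so thin chromatin bridges keep extruded lobes
attached to the main body; a detached fragment becomes its own object and
is scored independently. The underlying 4-connected labeller is merged
across diagonal adjacencies with a union-find pass.

`assess_envelope_coverage()` samples the ordered boundary of each nucleus;
a boundary pixel is covered when the envelope channel exceeds a rim
threshold anywhere within a 3 px Chebyshev band. The rim threshold is
Otsu on the rim-band pixels of the whole image, so coverage is invariant
to uniform intensity rescaling. The longest contiguous uncovered arc is
measured along the ordered contour (circularly), and the
`uncovered_dna_fraction` assigns each nucleus pixel to its nearest
covered or uncovered boundary arc.

Classification: *deformed* = circularity below `c_min` (default 0.65);
*ruptured* = coverage below $1 - g_\min$ (default $g_\min = 0.05$) with a
contiguous gap of at least 1 µm. The thresholds are this package's
operationalization, calibrated once on the synthetic generator — the
emulated study scored these phenotypes by visual inspection and reports
no numeric cutoffs — and they are configuration, reported alongside
results, never attributed to the source assay. The two flags are
independent; for cohort fractions `score_cohort()` uses the exclusive
precedence ruptured > deformed > normal, matching how stacked category
quantifications are usually reported and making fractions comparable to
a generator mix. Cohorts under 100 cells trigger a warning.

# Damage quantification

`nuclear_intensity()` subtracts the background estimated as the intensity
*mode* of all non-nucleus pixels — robust when a large area fraction is
marker-positive, unlike the mean or median. Whether the emulated assay
background-subtracted is unstated; subtraction is on by default and
switchable. `normalize_to_control()` divides by the control mean, so the
control group's normalized mean is exactly 1 by construction.

`detect_foci()` counts blobs with a scale-normalized Laplacian-of-Gaussian
filter bank over a physical diameter window (default 0.3–1.2 µm, four
log-spaced scales; pixel size is mandatory because the window is
physical). Three numerical choices matter:

* **Boundary step suppression.** The LoG responds strongly to the nuclear
  boundary (in-nucleus base level vs background), producing spurious
  peaks along the rim. Detection therefore runs per nucleus on a
  bounding-box crop whose exterior is filled with the in-nucleus median,
  removing the step without touching in-nucleus structure.
* **Null-calibrated threshold.** The peak threshold is
  `k_mad` (default 6) times the null response sd, propagated as (pixel
  noise sd) x (kernel L2 norm) per scale; pixel noise is estimated from
  horizontal pixel differences inside the region, which is robust to a
  high blob area fraction and invariant to offsets. Recovery is flat
  across `k_mad` 5–7, so the default sits mid-plateau rather than on a
  cliff.
* **Scale-space maxima with scale-aware suppression.** Maxima are taken
  per scale (3x3 spatially, dominating neighbouring scales at the same
  pixel) — maxima on a max-over-scales projection merge nearby spots —
  and duplicate detections across scales plus secondary LoG ring maxima
  are removed by greedy non-maximum suppression with radius
  $2.5\,\max(\sigma_i, \sigma_j)$.

Positivity is strict: a cell is focus-positive when its count exceeds
five (at least six foci). `cytoplasmic_aggregates()` applies the same
blob detector with a 0.1–1 µm window to the cell-minus-nucleus region,
after verifying mask containment; one aggregate suffices for a positive
call.

The focus generator's "well-separated" contract places spot centres at
least $5.5\sigma$ apart (about 1.4 µm for 0.6 µm foci): closer pairs stop
being distinct maxima anywhere in the scale space of the configured
diameter window, for any detector of this family — countable foci in the
emulated assays are similarly resolved.

# Group statistics

`compare_groups()` offers the uncorrected chi-square statistic
$\sum (O-E)^2/E$ on count tables (all expected counts must be positive;
no continuity correction, matching the textbook statistic) and Welch's
unequal-variance t for numeric samples. Welch replaces the emulated
study's paired t / ANOVA because the simulated cohorts are unpaired and
two-group; a paired t is available behind a flag, and ANOVA with Tukey
post-hoc is deliberately out of scope (pairwise Welch with Bonferroni is
the offered substitute and is labelled as such in reports).

# Problem sizes, determinism, reproduction

The test suite and the analysis scripts use cohorts of 300 nuclei (three
1150x1150 px fields of 100) for classification recovery, 10 seeds x 292
cells for the barrier-assay statistics, 40 cells per group for trajectory
variance, and 16-nucleus fields for focus counting — sizes at which every
recovery criterion is stable seed-to-seed while a full run stays
comfortably interactive. All stochastic stages consume explicit seeds;
`run_pipeline()` records the seed and a config hash in every report, and
identical configuration yields byte-identical CSV outputs.
`scripts/acceptance.R` recomputes the two headline cohort statistics
(total event count and mean event duration on the depleted preset) from
scratch at any seed.

# What the generator does and does not emulate

The generator reproduces the *structure* of the assays: phenotype
geometry with envelope gaps, ratio-trace dynamics with sudden efflux and
re-accumulation, Poisson event arrivals, quiescent versus dynamic shape
trajectories, focus and aggregate countability, and realistic
Poisson-Gaussian camera noise. It does not emulate chromatin texture,
photobleaching, z-projection artifacts, touching or overlapping nuclei,
segmentation-hostile debris, or intravital backgrounds (collagen,
second-harmonic channels). Passing recovery tests therefore demonstrates
that the algorithms are correct and well-calibrated on data matching
their stated assumptions — not that they are robust to every artifact of
real microscopy. On real data the weakest links are the global threshold
(touching nuclei are not split beyond seeding) and the visual-inspection
thresholds `c_min`/`g_min`, which should be re-calibrated per marker and
magnification.

# Known limitations

* 2D only; "sphericity" of time-lapse data is treated as 2D circularity.
* Whether aspect ratio in the emulated intravital analysis came from an
  ellipse fit or a bounding box is unstated; the moment-ellipse
  convention is used and flagged here.
* The detector's duration is quantized to the 2-min frame grid; durations
  below two frames are not representable (the generator resamples them).
* `run_pipeline()`'s analyze mode expects the package's own file layout;
  arbitrary external formats need manual staging.
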