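---
title: "Lineage analysis and fate prediction in regenerating neuromasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage analysis and fate prediction in regenerating neuromasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmregen)
```

## The biological problem

Zebrafish lateral-line neuromasts are small mechanosensory organs — a
circular epithelium of roughly 60–70 cells — that regenerate after severe
injury. When laser ablation leaves only 4–10 surviving cells (2–3 mantle
cells of the outer rim and 2–7 sustentacular supporting cells), those
founder cells rebuild a functional organ within days. Long-term
videomicroscopy of this process yields, after manual tracking, a record of
every cell's position, class, and divisions over 65–100 hours of recording
starting 4 hours post injury (hpi), at one frame per 15 minutes.

`nmregen` implements the analysis of such track tables end to end:

1. **I/O and validation** of the track-table dialect (`read_tracks()`,
   `write_tracks()`, `track_table()`).
2. **Lineage reconstruction** from heap-encoded identities
   (`build_forest()`): founders are node 1, the daughters of node *n* are
   nodes *2n* and *2n + 1*, and a cell's generation is
   `floor(log2(n))`.
3. **Clone and division classification** (`clone_type()`,
   `categorize_division()`, `division_summary()`).
4. **Spatial statistics** in the organ-centered frame (`center_tracks()`,
   `quadrant_of()`, `progeny_laterality()`, `division_location_map()`).
5. **Division kinetics**: wave detection and two-segment (change-point)
   regression of cell-cycle length (`division_histogram()`,
   `detect_wave_peaks()`, `two_segment_fit()`).
6. **Feature extraction**: 32 spatial, neighbourhood and lineage
   predictors per cell and timepoint (`extract_features()`,
   `build_feature_table()`).
7. **Fate prediction**: bagged-tree random forests evaluated by
   leave-one-experiment-out cross-validation, scored with the Matthews
   correlation coefficient (MCC) and a bootstrap over test sets
   (`round_robin_evaluate()`, `mcc()`, `bootstrap_mcc()`).
8. A **synthetic-data generator**: an agent-based simulator of
   neuromast regeneration (`simulation_config()`, `generate_cohort()`)
   that emits track tables with ground truth, so every stage of the
   pipeline is testable without microscopy data.

## Conventions and definitions

**Cell classes.** S (sustentacular), M (mantle), H (hair), U
(unassigned). Hair cells are postmitotic: the validator rejects any track
in which an H cell changes class or divides. Allowed class changes for a
single cell over time are S→M, S→H and U→{S, M, H}.

**Organ frame.** All spatial analysis happens after `center_tracks()`,
which subtracts the centroid of the cells present at the first recorded
frame and orients axes so +x points posterior and +y dorsal. The origin is
fixed for the whole recording; an instantaneous per-frame centroid is
available through `feature_config(center = "frame_centroid")` for the
center-relative features.

**Quadrants.** The four 90° sectors whose bisectors are the compass axes:
dorsal is polar angle [45°, 135°), anterior [135°, 225°), ventral
[225°, 315°), posterior the remainder. Sectors are half-open, so a point
at exactly 45° is dorsal.

**Division time.** A division is timed and located at the parent's last
recorded frame; the daughters appear at the next frame. Cycle lengths are
`division time − birth time` for non-founders and
`division time − recording start` for founders. Times are kept in hpi
throughout, matching how founder first-division times are reported.

**Clone types and division categories.** A clone is typed by the set of
classes among its leaf cells at the last recorded frame: S, SM, SH, SHM
for sustentacular founders, M for mantle founders; any other composition
is kept and flagged `OTHER` rather than discarded, so anomalies in real
data stay visible. A division is categorized by both daughters' fates at
the time of their own next division, or at the end of the recording for
daughters that never divide: SS, HH, MM, SM, else OTHER. A daughter that
divides exactly at the final frame is assessed at that division.

## The two-segment regression

Cell-cycle length is roughly constant early in regeneration and lengthens
later. To locate the transition, `two_segment_fit()` fits the continuous
broken-stick model

y = a + b₁·x (x ≤ c);  y = a + b₁·c + b₂·(x − c) (x > c)

by exhaustive search over candidate change points c, minimizing total
squared error. Continuity at c is enforced: it is the standard segmented-
regression convention and the "slowly increases, then increases more
rapidly" shape is exactly a continuous slope break. The candidate set is
the sorted unique x values plus the midpoints between consecutive unique
x values, restricted to candidates leaving at least `min_points` (default
5) observations per segment; including the observations themselves lets a
noiseless break located at a data point be recovered exactly, which
midpoints alone cannot do. Because the straight line is nested in the
model (b₂ = b₁), the two-segment SSE never exceeds the single-line SSE;
when it does not improve on the line the fit is flagged `degenerate` and
the change point should not be interpreted. The two covariates used in
the organ analysis are produced by `cycle_covariates()`: each completed
cycle is paired either with its division time (hpi) or with the total
cell count at the cycle's start (the instant the spec of the analysis
leaves open; cycle start is the natural choice because that is when the
cell commits to its cycle).

## The 32 features

`extract_features()` computes, for one cell at one frame: absolute time;
distance to the organ center (absolute and normalized by the currently
furthest cell's radius); average and minimum distance to each class
(excluding the subject); counts of each class in total and within 10, 20
and 30 µm; total cell and founder counts; polar angle; generation and
founder class; and three movement features relative to the cell's last
division site (its birth division, or the recording start for founders):
distance moved, signed radial movement (positive toward the center), and
the angle at the organ center between the current and the last-division
location (a vertex-at-division alternative sits behind
`feature_config(angle_vertex = "last_division")`).

All geometry is two-dimensional: the neuromast epithelium is
approximately planar, and the feature list uses only x and y. The z
column is accepted and preserved by the I/O layer but ignored by
analysis. When a class is absent from the organ (no hair cells early in
regeneration) its distance features are set to a finite sentinel
(default 100 µm, configurable) and the row is flagged — tree learners
need finite inputs, and a flagged sentinel keeps the imputation visible.

## Fate prediction

Six binary tasks are predefined in `standard_tasks()`: SH vs SM, S vs SH
and S vs SM at the clone level; HH vs SM/MM, SS vs HH and SS vs SM/MM at
the division level (SM and MM merged, as is conventional for
mantle-producing divisions). Division-level examples are sustentacular
divisions: mantle divisions are invariably self-renewing and carry no
decision to predict.

Row policies: clone-level tasks use the founder's coordinates from
recording start until its first division; division-level tasks use the
dividing cell's coordinates in a window of `window` frames ending at its
division (default 1). Rows are predicted individually by a bagged
ensemble of 200 decision trees (√32 ≈ 5 candidate features per split,
unlimited depth, fixed seed; fitted by `ranger`), then aggregated to
entities — one clone or one division — by majority vote; exact ties are
scored as incorrect, a conservative choice. Validation is round-robin:
each experiment is held out once, the forest is trained on the others,
and the held-out entities are pooled into a single confusion matrix.

The score is the Matthews correlation coefficient,

MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

+1 for perfect, 0 for random, −1 for perfectly inverted prediction, with
the standard convention that a zero factor in the denominator yields 0.
Its variance is estimated by resampling 15 experiment-level test sets
with replacement 15 times and recomputing the entity-level MCC per
replicate (`bootstrap_mcc()`); resampling whole experiments rather than
individual predictions respects the clustering of cells within organs.
Feature importance is out-of-bag permutation importance on a forest
trained on all experiments.

## The synthetic-data generator

`generate_experiment()` runs an agent-based model on the recording grid.
Its defaults are the study conditions: 15 experiments per cohort,
recordings of 65–100 h starting 4 hpi at 15-min frames, 2–3 mantle plus
2–7 sustentacular founders placed in a disc of radius 20 µm (mantle
founders near the rim). Division timing:

* Sustentacular founders divide at times with marginal mean 19 h and sd
  6 h, drawn from a two-component mixture: a synchronized "wave core"
  (80%, normal with mean 18 h, sd 2.5 h) plus late stragglers whose mean
  and sd are derived so the mixture's marginal moments are exactly
  (19, 6). The tight core is what produces the first division wave: with
  a single sd-6 normal, the founder and first-generation division times
  (11 h apart) overlap so broadly that no wave is detectable as a density
  mode, which contradicts the observed sharply peaked waves. Division
  waves are *emergent* in the simulator — nothing imposes them beyond
  synchronous onset and a narrow cycle distribution.
* Mantle founders skip division entirely with probability 14/30,
  otherwise divide around 27 ± 5 h; mantle daughters rarely (p = 0.07)
  divide once more, and mantle lineages only ever divide MM.
* Later cycles draw from a truncated normal (11 ± 3 h, minimum 4 h) plus
  a lengthening term of 1 h per hour past 47 hpi and 1.5 h per cell above
  24 cells (evaluated at the cell's birth), with extra noise proportional
  to the lengthening. This reproduces the early short, late long and
  variable cycle structure and is what ultimately slows organ growth.

Division fates are drawn per division from base probabilities
(SS, HH, MM, SM) = (0.78, 0.16, 0.03, 0.03), spatially modulated into
exclusive territories measured in normalized radius r̂ (the dividing
cell's radial distance over the currently furthest cell's):

* HH only for t ≥ 48 hpi and r̂ ≤ 0.55, with weight ∝ (1 − r̂)²; after
  60 hpi the HH weight is redistributed 5:1 toward the dorsal/ventral
  sectors (normalized so the HH marginal is unchanged).
* MM and SM only for r̂ ≥ 0.6, with weight ∝ r̂², damped by the local
  mantle-cell count within 20 µm — mantle production is routed to
  perimeter sectors that lack mantle cells.
* SS takes the remaining weight everywhere.

The territory gains (4.6 for HH, 40 for the perimeter) were calibrated
once, on pilot cohorts, so that a default cohort's *realized* category
marginals match the base probabilities (about 79 / 15.5 / 3 / 2.5
percent), and then frozen. Daughters appear at the parent's position plus
isotropic noise (sd 3 µm per axis) and are emitted with their fated class
from their first frame, so categories recomputed from the tracks equal
the generator's ground truth exactly — the end-to-end consistency oracle
used by the tests. Cells perform a per-frame random walk (sd 0.4 µm per
axis); mantle cells drift toward 85% of the organ radius, hair cells
toward 35%; everything is contained within radius R(t) = 20·√(N/N₀) µm,
which keeps areal density constant as the organ grows. There is no cell
death and no immigration.

`null_variant()` toggles all spatial and temporal fate modulation off,
leaving the marginal fate probabilities identical: the null cohort is the
negative control for the fate predictors (round-robin MCC compatible with
zero).

### What the simulator does and does not emulate

It reproduces: the founder composition and timing statistics; division
waves; generation-resolved cycle lengthening with change points near 47
hpi and 24 cells; clone cohesion (ipsilateral progeny fractions around
0.75 at 60 hpi, within the observed 60–74% range); hair-cell onset around
48 hpi; central HH / peripheral SM-MM / ring-like SS division geometry;
and the late dorsoventral proliferation bias. It does not emulate: cell
death, intercalation or immigration; 3-D epithelial mechanics or
apicobasal structure; planar polarity; signaling; tracking errors,
gaps or misassignments; or regeneration beyond the recording horizon.
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers known structure of this kind from track tables — not
that real neuromasts obey the generator's mechanisms, and real tracking
data would additionally stress the validator's error paths.

## Numerical choices

* Peak detection: Gaussian-kernel density (bandwidth 1 h) with a
  topographic-prominence filter at 10% of the global maximum; both
  configurable. Division histograms default to 1-h bins.
* Wave location is assessed per experiment (waves are organ-level events;
  pooling experiments with different onsets blurs them), summarized by
  the median of per-experiment first peaks.
* Daughters are expected within 15 µm of the parent's last position;
  violations only warn (real tracking data may jitter), with the radius
  configurable.
* MCC with a zero denominator factor returns 0; entity-vote ties count
  as errors; folds whose training data collapse to one class are skipped
  with a warning and recorded in the evaluation report.
* Heap indices are scoped per lineage — (lineage, node) pairs — because a
  single global heap numbering collides across founders.
* Test and acceptance problem sizes: module tests run on 3–4 simulated
  experiments; the acceptance suite uses a 40-experiment cohort (≥ 1000
  sustentacular divisions, ≥ 100 sustentacular founders) and a
  24-experiment null cohort. These sizes give sampling errors comfortably
  inside the tolerances being checked (e.g. ±3 percentage points on
  category fractions, ±1 h on the founder mean).

## Known limitations

* The organ frame assumes upstream registration; `center_tracks()` only
  translates and flips axes, it does not correct drift over time.
* Geometry is 2-D; neuromasts are shallow but not flat, so distances are
  slightly underestimated for apically displaced hair cells in real data.
* `two_segment_fit()` provides point estimates only — no confidence
  interval on the change point.
* The clone-level tasks inherit whatever class imbalance the cohort has;
  no resampling or class weighting is applied during training, so tasks
  with a rare class (SS vs SM/MM) have weak minority-class recall, which
  is visible in their MCC.
* With fewer than three experiments, round-robin evaluation refuses to
  run rather than silently degrade.

## A minimal walk-through

```{r example, eval = FALSE}
library(nmregen)

# simulate a cohort under the study conditions
cohort <- generate_cohort(simulation_config(), master_seed = 1)
forests <- cohort_forests(cohort)

# clone composition and division categories
clone_table(forests)
division_summary(forests)

# kinetics: waves and the time change point
d <- division_table(forests)
peaks <- detect_wave_peaks(
  division_histogram(d$time_hpi[d$parent_class == "S"]))
ct <- cycle_covariates(forests, against = "time",
                       founder_class_filter = "S")
two_segment_fit(ct$x, ct$y)

# fate prediction, division level
ft <- build_feature_table(forests, task = "division")
round_robin_evaluate(ft, standard_tasks()$HH_vs_SMMM, seed = 7)
```
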