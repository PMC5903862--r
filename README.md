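# nmregen

Lineage reconstruction and cell-fate prediction for regenerating
zebrafish neuromasts.

Neuromasts — the small mechanosensory organs of the fish lateral line —
regenerate completely from as few as 4–10 surviving cells after severe
injury. Long-term videomicroscopy of this process, followed by manual
cell tracking, produces *track tables*: one row per cell per 15-minute
frame, with a heap-encoded identity (founder cells are node 1, the
daughters of node *n* become nodes *2n* and *2n + 1*), a position in µm,
and a cell class — S (sustentacular), M (mantle), H (hair), U
(unassigned). `nmregen` is an R package for analysing such data end to
end, for researchers studying organ regeneration and clonal dynamics:

* validated track-table and manifest I/O;
* lineage-forest reconstruction, divisions, generations
  (`generation(n) = floor(log2 n)`), cycle lengths, Newick export;
* clone typing (S / SM / SH / SHM / M) by final composition, and division
  categorization (SS / HH / MM / SM) by both daughters' fates at their
  next division or at recording end;
* organ-frame spatial statistics: quadrant anisotropy of divisions,
  ipsilateral clone cohesion, per-category division radii;
* division kinetics: wave detection in the division-time density, and a
  continuous two-segment (change-point) regression of cell-cycle length
  `y = a + b₁x` for `x ≤ c`, `y = a + b₁c + b₂(x − c)` for `x > c`,
  with the change point found by exhaustive search;
* the 32 spatial/neighbourhood/lineage features per cell and timepoint
  used for fate prediction;
* bagged-tree random-forest fate predictors with leave-one-experiment-out
  (round-robin) cross-validation, entity-level majority voting, Matthews
  correlation `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
  a bootstrap over experiment-level test sets, and permutation feature
  importance;
* an agent-based simulator of neuromast regeneration that emits track
  tables with ground truth, calibrated to the study's statistics, so the
  whole pipeline is testable without microscopy data.

The methods vignette
(`vignettes/neuromast-regeneration-analysis.Rmd`) documents the models,
conventions, generator design and numerical choices.

## Worked example

Simulate a 15-experiment cohort under the study conditions, rebuild the
lineages from the emitted tracks, and run the analysis:

```r
library(nmregen)

cohort  <- generate_cohort(simulation_config(), master_seed = 1)
forests <- cohort_forests(cohort)

division_summary(forests)        # category fractions per dividing class
#>  parent_class category   n   fraction
#>             S       SS 696 0.80836237
#>             S       HH 121 0.14053426
#>             S       MM  20 0.02322880
#>             S       SM  24 0.02787456
#>             S    OTHER   0 0.00000000
#>  symmetric fraction (S): 0.972
```

About 81% of sustentacular divisions in this cohort are self-renewing
(SS), 14% make a hair-cell pair (HH), and 97% are symmetric overall —
the hallmark of a tri-potent progenitor pool dividing mostly
symmetrically.

```r
d <- division_table(forests)
detect_wave_peaks(division_histogram(d$time_hpi[d$parent_class == "S"]))
#> 20.3 37.3 46.1 53.6 59.6 68.4
```

The first pooled division wave peaks at 20.3 hpi (the founder wave);
later peaks are the successive generations, progressively blurred by
cycle-length variability.

```r
ct <- cycle_covariates(forests, against = "time",
                       founder_class_filter = "S")
two_segment_fit(ct$x, ct$y)
#> <nm_two_segment> change point 43.500, slopes -0.040 -> 0.535,
#>                  sse 17340.816 (line 24207.766)
```

Cell-cycle length is flat (slope ≈ 0) until a change point in the
mid-40s hpi, then lengthens — the kinetic signature of the organ
approaching homeostasis.

```r
ft <- build_feature_table(forests, task = "division")
round_robin_evaluate(ft, standard_tasks()$HH_vs_SMMM, seed = 7)
#> <nm_evaluation> HH vs SM/MM (division level): MCC 0.922
#>                 (bootstrap 0.916 +/- 0.031), 160/165 entities correct
```

Hair-cell-producing divisions are almost perfectly separable from
mantle-producing ones; the top-ranked features are the cell's absolute
time, its normalized distance to the organ center and its distance to
the nearest mantle cell — position in the organ predicts fate.

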