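# stresspanel

Analysis of custom RT-qPCR stress-marker arrays: from raw amplification
traces to efficiency-validated Cq values, multi-reference-normalized log2
expression ratios, majority-rule selection of direction-consistent marker
genes, a per-genotype stress matrix, and tolerant/sensitive calls against
reference genotypes.

## Who this is for

Groups that phenotype crop genotypes (the motivating case is grapevine
varieties in the field) with a small custom qPCR panel of abiotic-stress
markers — water (WS), heat (HS), excess-light (LS) and combined field
(FIELD) stress — rather than genome-wide profiling, and need the whole
chain from instrument-style exports to tolerance classifications to be
reproducible and testable. Because raw plate data for such studies are
rarely deposited, the package includes a seeded synthetic-experiment
generator with planted effects, so the entire pipeline can be validated
against known ground truth.

## The model in brief

* **Cq calling** — least-squares baseline over cycles 5–17, subtracted
  from the trace; Cq is the first fractional cycle where ΔRn crosses the
  0.2 threshold (linear interpolation between bracketing cycles).
* **Efficiency** — from the dilution-series slope *a* of Cq on
  log10(input): `E = 10^(-1/a) - 1`; QC pass when 100·E ∈ [90, 110]
  (|slope| = 3.3 ± 0.33).
* **Normalization** — Pfaffl-style efficiency-corrected ratio per
  biological replicate, divided by the geometric mean of the reference
  genes' fold changes, against the mean of the control genotype's
  replicates; results in log2 units, computed against both the tolerant
  and the sensitive control genotype.
* **Screening** — per gene × location one-way ANOVA across varieties,
  Tukey HSD when p < 0.05; a variety is significant when its
  variety-vs-control adjusted p < 0.05.
* **Marker selection** — a marker is kept only if, in *every* location,
  the varieties showing the wrong regulation direction are not more than
  half of those evaluated.
* **Stress matrix** — per variety × location × stress, the mean
  |log2 ratio| of that stress's markers exceeding 1.5 in magnitude with
  the expected sign (undefined when none qualifies).
* **Classification** — Pearson correlation of a variety's marker profile
  with the tolerant and sensitive reference profiles; tolerant when the
  correlation margin exceeds 0.2, sensitive below −0.2, else
  indeterminate.

See `vignettes/stress-marker-panel.Rmd` for assumptions, parameter
defaults and limitations.

## Worked example

```r
library(stresspanel)
library(dplyr)

cfg <- sim_config(seed = 42)      # 65 markers + ACT/TIF/TIF-GTP,
exp <- simulate_experiment(cfg)   # 10 varieties + TN/TR, 2 locations
exp
#> <cq_experiment> 11424 wells | 68 genes x 12 varieties x 2 locations

ratios <- log2_ratio_table(exp$wells, exp$panel, keep_reps = TRUE)
part <- filter_panel(exp$panel, evaluate_panel(ratios, exp$panel))
part$n_retained_markers
#> [1] 65        # no planted direction faults, so nothing is discarded

sm <- build_stress_matrix(ratios, exp$panel)
filter(sm, variety == "V07", location == "Pegoes")
#>   variety location stress score n_qualifying n_assigned
#> 1 V07     Pegoes   FIELD   4.19            9         19
#> 2 V07     Pegoes   HS      4.72           10         20
#> 3 V07     Pegoes   LS      4.35           10         19
#> 4 V07     Pegoes   WS      4.51            9         20

location_stress_summary(sm)   # the harsher site scores higher
#>   location   mean_score n_defined
#> 1 DoisPortos       3.19        48
#> 2 Pegoes           4.40        48

calls <- classify_tolerance(ratios, exp$panel, reference_profiles(ratios),
                            exclude_varieties = c("TN", "TR"))
filter(calls, location == "Pegoes", stress == "WS") |> head(6)
#>   variety location stress sim_tolerant sim_sensitive margin label     n_common
#> 1 V01     Pegoes   WS            0.998         0.324  0.674 tolerant        20
#> 2 V02     Pegoes   WS            0.999         0.347  0.652 tolerant        20
#> 3 V03     Pegoes   WS            0.998         0.336  0.662 tolerant        20
#> 4 V04     Pegoes   WS            0.998         0.353  0.645 tolerant        20
#> 5 V05     Pegoes   WS            0.998         0.340  0.657 tolerant        20
#> 6 V06     Pegoes   WS            0.336         0.997 -0.661 sensitive       20
```

A stress-matrix cell of 4.5 means the qualifying WS markers moved on
average 4.5 log2 units (≈ 23-fold) in the expected direction; the
tolerance calls recover the planted variety archetypes (V01–V05 tolerant,
V06–V10 sensitive). Standard curves work the same way on measured
dilution series:

```r
glance(fit_standard_curve(simulate_dilution_series(0.95, noise_sd = 0.05,
                                                   seed = 42)))
#>   slope intercept    r2 efficiency_pct qc_pass     n
#> 1 -3.44      20.0 1.000           95.2 TRUE        5
```

`autoplot()` methods exist for standard curves and stress matrices, plus
`plot_expression_distribution()` and `plot_bin_relevance()` for the
distribution and functional-bin views.

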