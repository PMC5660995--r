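---
title: "Methods: qPCR stress-marker panels from traces to tolerance calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR stress-marker panels from traces to tolerance calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresspanel)
library(dplyr)
```

## The problem

Breeders and physiologists who want to rank uncharacterized crop genotypes
by abiotic-stress tolerance — drought (WS), heat (HS), excess light (LS)
and combined field stress (FIELD) — can do so with a small custom RT-qPCR
array of marker transcripts instead of genome-wide profiling. `stresspanel`
implements the full analysis chain for such arrays:

1. **Cq calling** from raw fluorescence traces;
2. **efficiency validation** from dilution-series standard curves;
3. **normalization** of target Cq to efficiency-corrected log2 expression
   ratios against a panel of reference genes and two control genotypes;
4. **significance screening** by one-way ANOVA with Tukey's HSD;
5. **marker selection** by a majority-rule direction-consistency vote;
6. **stress scoring and tolerance classification** against well-
   characterized tolerant and sensitive reference genotypes.

Because real plate data for such experiments are rarely published, the
package ships a first-class synthetic-experiment generator that plants
known effects, so every stage of the pipeline can be validated against
ground truth.

## Quantification model

### Cq calling

The raw per-well signal is reporter fluorescence `Rn` over 40 cycles. A
straight line is fitted by least squares to cycles 5–17 (inclusive,
1-based) and subtracted from the whole trace; this absorbs any linear
baseline drift exactly, and reduces to the mean for flat baselines. The
quantification cycle is the first fractional cycle at which the
baseline-subtracted signal ΔRn crosses the threshold of 0.2 from below,
linearly interpolated between the bracketing integer cycles. A trace that
never reaches the threshold is *no amplification* (`NA`, never imputed); a
trace already above threshold at cycle 1 is rejected as invalid.

### Standard curves and efficiency

Per-gene amplification efficiency is estimated from a dilution series
(default: five points, five-fold, i.e. 1, 1:5, 1:25, 1:125, 1:625) by
ordinary least squares of Cq on log10(input):

$$E = 10^{-1/a} - 1,$$

with $a$ the slope. $E = 1$ (100 %) is perfect doubling, with
$|a| = \log_{10}(2)^{-1} \approx 3.32$. A curve passes QC when
$100E \in [90, 110]$, i.e. slope $3.3 \pm 0.33$ in magnitude.

```{r}
glance(fit_standard_curve(simulate_dilution_series(1)))
```

### Relative quantities

Technical replicates (default two) are averaged per biological replicate;
a spread above 0.5 cycles raises a QC flag (common lab practice — wide
duplicates usually mean pipetting trouble), and a bio-rep whose technical
replicates all failed stays missing. Each biological replicate is then
converted to an efficiency-corrected, multi-reference-normalized ratio in
the Pfaffl style:

$$\text{ratio} =
  \frac{(1+E_t)^{\,Cq_{t,\text{control}} - Cq_{t,\text{sample}}}}
  {\text{geomean}_r\,(1+E_r)^{\,Cq_{r,\text{control}} - Cq_{r,\text{sample}}}}$$

with the geometric mean running over the reference genes (ACT, TIF and
TIF-GTP in the default panel). The control Cq per gene is the mean across
the control genotype's biological replicates, and ratios are always
computed against **both** control genotypes (tolerant and sensitive), so
downstream consumers choose the anchor explicitly. Log2 ratios are
averaged across biological replicates; if any reference gene is missing in
a replicate, that replicate's ratios are missing rather than imputed. The
sign convention used everywhere: upregulation by *d* log2 units lowers Cq
by *d* cycles.

## Significance screening

Log2 transformation renders relative quantities approximately normal, so
each gene × location is screened with a classical one-way ANOVA across
varieties (the control genotype's unstressed samples are the control
group), implemented on `stats::aov`. When the ANOVA p-value is below
α = 0.05, Tukey's HSD follows and a variety is flagged significant when
its variety-vs-control adjusted p is below α. No correction is applied
across genes — the screen is per gene, and reports say so. Varieties with
fewer than two informative replicates are never flagged, only marked
insufficient.

A calibration subtlety worth knowing: within one plate, every gene shares
the same reference-normalizer draws, so per-plate false-positive rates are
over-dispersed around α even though the per-gene test is exact. The
package's validation therefore averages the null rate over independent
simulated plates.

## Marker selection

Each candidate marker carries an a-priori expected regulation direction.
A variety *matches* when the sign of its mean log2 ratio equals that
direction (optionally gated on significance or on |log2| exceeding a
threshold; the default gate is sign-only, since a screening array should
not discard markers for effect size alone). A gene passes a location
unless the failing varieties are **more than half** of those evaluated —
a tie at exactly half passes, because the rule only discards on a strict
majority of failures. A gene must pass in **every** location: an array
meant to work across climates cannot keep a marker that points the wrong
way in one of them. Reference genes are exempt and always retained. The
retained markers plus references are assembled into the final array
layout, grouped by stress assignment.

The filter is monotone (raising the match threshold never grows the
retained set) and invariant to variety order; both properties are tested.

## Stress matrix and tolerance calls

For each variety × location × stress, a marker *qualifies* when its
|log2 ratio| exceeds 1.5 **and** has the expected sign; the stress score
is the mean |log2 ratio| over qualifying markers. An empty qualifying set
gives an *undefined* score (`NA`), deliberately distinct from 0: "no
detectable stress response" is not "a weak one". A defined score
necessarily exceeds the threshold (it is a mean of values that each do).
Per-location marginal means are attached so between-site stress-pressure
comparisons are a computed output.

Tolerance classification compares each variety's profile over a stress's
markers with the measured profiles of the tolerant and sensitive reference
genotypes using Pearson correlation — the literal reading of "correlates
closely with" — over their common genes (pairwise-complete). The call is
tolerant when `sim_tolerant − sim_sensitive > δ` with δ = 0.2, sensitive
when below −δ, otherwise indeterminate. The margin prevents over-confident
calls when a variety sits between the anchors; fewer than three common
genes or a zero-variance profile is indeterminate with the reason
recorded. Correlation is scale-free, which makes calls robust to the
overall stress intensity of a site.

Two descriptive summaries mirror the standard figures for such arrays:
functional-bin aggregation (mean log2 ratio per MapMan-style bin, split by
a-priori direction, flagging bins whose observed mean contradicts their
a-priori direction) and per-variety distribution summaries (type-7
quartiles, Tukey 1.5 × IQR whiskers, and the IQR as a stability score —
smaller means more stable expression).

## The synthetic generator

`simulate_experiment()` emulates the study design the pipeline targets: a
65-marker + 3-reference panel measured in 10 test varieties plus the two
reference genotypes, in two field locations, with 3 biological × 2
technical replicates (about 11 400 wells). Its model is

$$Cq = \text{baseline}(g) - \underbrace{\sum_{s \in S(g)}
  \beta(g, s, \text{archetype}(v)) \cdot \lambda(\ell, s)}_{\text{planted
  log2 effect}} + b + t,$$

with `b ~ N(0, sd_bio)` shared across a sample's technical replicates and
`t ~ N(0, sd_tech)` independent per well. Defaults: sd_bio = 0.3 and
sd_tech = 0.15 cycles — conventional magnitudes for plant RT-qPCR, chosen
once as realistic values (inter-replicate variance is rarely reported for
such arrays, so these are conventions, not measurements). Wells above a
Cq of 38 are recorded as no-amplification, exercising the missing-data
paths. Reference genes receive noise only.

Planted effects follow the gene's expected direction in **both**
archetypes (retained markers must be direction-consistent across
genotypes), but magnitudes alternate between strong (3.4 log2) and weak
(0.6 log2) in anti-phase between the tolerant and sensitive archetypes —
different marker subsets dominate in each — which keeps the two reference
profiles distinguishable by correlation (r ≈ 0.35 rather than ≈ 1) while
averaging to the 2 log2 effect used throughout validation. Mixed
archetypes respond with the mean of the two and are correctly
indeterminate. The default location multipliers (1 and 0.7) encode one
harsher and one milder site, so markers slipping below the 1.5 stress-
matrix threshold at the mild site are part of the default data. Ground
truth (the planted effect table) is always returned next to the wells, so
every downstream stage has an oracle.

What the generator does **not** emulate: melting-curve artifacts,
primer-dimer and gDNA contamination, plate-position effects, inter-run
drift, non-Gaussian outliers, and reference genes that are only
approximately stable. Passing the recovery suites therefore shows the
analysis is correct *given* the standard qPCR error model, not that real
plates are this well behaved.

`simulate_trace()` builds a logistic amplification curve on a linear
baseline whose sampled values, read back exactly the way `call_cq()` reads
them, cross the threshold at the requested Cq (the sigmoid centre is
calibrated by root-finding); recovery is within ~0.01 cycles for
Cq ≥ 22 with the default growth rate of 0.9/cycle. `simulate_dilution_series()`
spaces Cq by `log(fold)/log(1+E)` per step, making efficiency estimation
a closed-form round trip.

## Numerical and design choices

* Cycles are 1-based and the baseline window inclusive on both ends.
* Quartiles use linear interpolation between order statistics (type 7);
  stated because quartile conventions differ between tools.
* `sign(0)` matches neither direction: a mean ratio of exactly 0 is never
  a directional match.
* Undefined scores and similarities are `NA`, never silently 0; missing
  wells propagate, never imputed.
* An ANOVA on groups with zero between- **and** zero within-group
  variance reports an undefined F (`NaN`), not an error and not a
  rejection.
* The fully degenerate 0/0 case is detected on relative sums of squares
  (tolerance 1e-24 of the value scale).
* JSON run reports are serialized with sorted keys and fixed precision so
  reruns diff cleanly.

Validation problem sizes were chosen to keep the whole suite fast on a
laptop while leaving the statistical conclusions stable: 50 seeded
replicates for the filtering and classification recovery rates, 20 × 100
genes for the null calibration, 500 genes for power, and noise-free runs
at the full default design for the exactness checks.

## Known limitations

* The ANOVA is one-way per gene × location; no variety × location
  interaction or mixed-effects structure is modelled.
* Classification needs the two reference genotypes measured in the same
  locations as the test varieties; there is no cross-location transfer.
* Efficiency correction assumes one efficiency per gene (from its
  standard curve), constant across samples.
* The consistency vote weights all varieties equally; no allowance is
  made for phylogenetic or pedigree relatedness between genotypes.
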