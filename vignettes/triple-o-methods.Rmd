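---
title: "Triple O: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple O: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripleo)
```

## The model

`tripleo()` fits a *normative reference model* to a cohort of vectorized
connectivity matrices (upper triangle, row-major, diagonal excluded;
`n(n-1)/2` connections for `n` regions). The fitted object holds three
layers of statistics:

1. **Per-connection norms.** Mean and sample SD (denominator `n − 1`) of
   every connection across reference subjects. These define the
   connection-level Z-score of any subject.
2. **Three outlier measures per subject.**
   `m1` — the count of connections with `|Z| > connection_z`;
   `m2` — the mean Euclidean distance from the subject's connection
   vector to every reference subject's vector;
   `m3` — the subject's own SD across all connections.
   The three are deliberately *sign-insensitive*: a subject deviating
   strongly downward counts exactly as much as one deviating upward,
   which is what makes the scheme robust to mixed-sign and
   subgroup-heterogeneous brain–behavior couplings.
3. **Measure norms.** Mean and sample SD of each measure over the
   reference cohort, used to Z-normalize the measures of any scored
   subject. An indicator fires when a measure Z strictly exceeds
   `measure_z` (upper tail only — being unusually *typical* is not an
   outlier), and `min_votes` indicators (default 2 of 3) make a
   brain-outlier call.

The model assumes the reference cohort is an unselected sample of the
population whose "normal" is being estimated, that connectivity values
are on a comparable scale across subjects (hence the Fisher-Z transform
for raw correlations), and that enough reference subjects are available
for stable per-connection and per-measure norms — the package's own
resampling harness (`sweep_reference_size()`) shows prediction
stabilizing once the reference holds a few dozen subjects.

Outcome outliers are defined symmetrically from IQ
(`iq_outlier_status()`): cohort-normalized `Z > 1.645` is a high outlier,
`Z < −1.645` a low one. Evaluation of the unsigned brain-outlier call
against outcome outliers counts either direction as a true positive;
the CDRI-signed call (`signed_prediction()`) is evaluated directionally
through the conditional risk table.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `connection_z` | 1.645 | SD | one-tailed p < .05 per tail at the connection level |
| `connection_sidedness` | two-sided | — | see below |
| `measure_z` | 1.645 | SD | one-tailed p < .05, upper tail, per measure |
| `min_votes` | 2 | votes | 2-of-3 majority over the indicator triple |
| `iq_z` | 1.645 | SD | one-tailed p = .05 outcome-outlier cut |
| `self_exclusion` | TRUE | — | drop a subject's own zero term from its `m2` |
| `zero_variance` | error | — | a zero-variance reference connection is degenerate input |
| `measure_variance` | error | — | a zero-variance reference measure is degenerate input |
| Fisher-Z `clamp` | 1e-7 | — | `atanh` is unbounded at ±1 |

All thresholds are configuration keys (`tripleo_config()`); the defaults
are the framework's standard operating point, not fitted values.

## Design choices where the design was open

**Two-sided connection counting.** The connection-level cut is phrased as
a one-tailed p < .05, but the whole point of the measures is
sign-insensitivity — a subject extreme in either direction is at risk.
`m1` therefore counts `|Z| > 1.645` by default (each tail at its
one-tailed level); `connection_sidedness = "upper"` gives the strictly
upper-tailed variant for sensitivity analyses. The measure-level
indicators, by contrast, are upper-tail only, exactly as the vote rule
demands.

**Self-handling in self-reference designs.** When a cohort is scored
against itself, each subject stays *in* the per-connection norms (no
leave-one-out) but is *excluded* from its own `m2` average: a guaranteed
zero distance term would bias `m2` downward for in-reference subjects
relative to externally scored ones and break comparability between
self-reference and external-reference runs. Reference subjects' own
measures — the measure norms — are computed under the same policy, so
test and reference measures are exchangeable under the null. Both
toggles are exposed.

**A consequence worth knowing (in/out asymmetry of `m1`).** Because
reference subjects contribute to the norms they are scored against,
their connection Z-scores are slightly shrunken (variance ≈ `(n−1)/n`)
relative to an external subject's (≈ `(n+1)/n`), and a subject's own
extreme values inflate the very SD that scores them. Per connection the
effect is a fraction of a percent, but `m1` sums it over *all*
connections: with 24,531 connections and a reference of 200, externally
scored null subjects average visibly higher `m1` than the reference
distribution used to normalize them, and the `m1` indicator becomes
liberal in external-reference designs at full matrix size (the package's
calibration tests quantify this at moderate connection counts, where the
effect is small). The effect shrinks with reference size and does not
arise in self-reference designs, where everyone is scored the same way.
Leave-one-out per-connection norms would remove it but would change the
method's definition, so they are deliberately not applied.

**CDRI.** The index averages the Z-scores of gestational age at birth
(days), birthweight (g) and maternal education (years), normalized
against the reference cohort — the same normalization convention as
every other statistic in the framework. An exact zero CDRI resolves to
POSITIVE with a warning: deterministic behavior for a measure-zero tie.
The component list is configurable. The demographic-only outlier
detector (`demographic_only_outliers()`) exists as a comparison arm, not
a recommended predictor.

**Resampling.** Reference subsamples are drawn *without* replacement
within a replicate (a subsample of a pool, not a bootstrap), with
independent draws across replicates. Each (size, replicate) cell runs on
a seed substream `mix_seed(seed, size, replicate)`, so adding sizes to a
sweep never perturbs existing replicates and every sweep is bit-for-bit
reproducible.

## Numerical choices

* Sample SDs (`n − 1`) everywhere; strict inequalities at every 1.645
  threshold, so ties at the cut resolve deterministically to "not an
  outlier".
* Matrix files are written with 17 significant digits; read → write →
  read round trips reproduce values to better than 1e-12.
* Asymmetry up to 1e-8 is symmetrized by averaging with the transpose;
  beyond that it is an error naming the offending entry.
* Raw correlations are clipped to `±(1 − 1e-7)` before `atanh`; the
  diagonal is zeroed and ignored by everything downstream.
* Cross-distance computation uses the Gram identity
  `‖x − y‖² = ‖x‖² − 2⟨x,y⟩ + ‖y‖²` (clamped at zero before the square
  root) so that `m2` for a 175 × 218 cohort pair is a single BLAS call;
  tests pin it to a direct pairwise loop at 1e-10.
* Degenerate references fail loudly by default: fewer than 2 subjects,
  zero-variance connections, or a measure with zero variance across the
  reference. Each has an explicit tolerate policy (`zero_variance =
  "zero"` zeroes that connection's Z; `measure_variance = "tolerate"`
  disables that indicator) for exploratory work on tiny cohorts.
* Fisher's exact test enumerates the hypergeometric support directly and
  applies the two-sided point-probability rule with a 1e-7 relative tie
  tolerance; a table with a zero margin reports p = 1 with a warning.
* Report percentages round half-up to the table's precision; raw values
  are always retained alongside.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, per subject, a latent cognitive score
`g ~ N(0,1)`; a subgroup sign `s ∈ {+1,−1}` (flipped with probability
`subgroup_flip_fraction`, affecting only the brain side of the coupling,
never the outcome marginals); connection values
`μ_k + β·σ·c_k·g·s + ε` on `n_coupled` randomly chosen connections with
coupling signs `c_k` (a `frac_negative` fraction negative); IQ mixing
`g` with independent noise by `latent_weight`, shifted down by
`risk_iq_shift · iq_sd` for RISK subjects; and Gaussian demographics
correlated with the realized IQ at `demographic_iq_r`. Cohorts generated
from one seed with different `cohort_id`s share one population (baseline
connectivity, coupled set, coupling signs) — the construction needed for
external-reference and sweep designs. The defaults emulate the target
regime: 222 regions, 175 subjects, IQ 106.9 ± 11.8, demographic–outcome
correlations inside .17–.40, a CONTROL fraction of 0.32, and a RISK IQ
deficit of 0.4 SD; the coupling strength default (`effect_size = 1`,
`n_coupled = 200`) is chosen for testability, since no empirical
connection-level effect sizes are available to copy.

It does **not** emulate: fMRI time series, motion or scanner artifacts
(it starts at the connectivity-matrix level, where the method starts);
spatial structure among regions (coupled connections are exchangeable,
so region-topology effects are untested); non-Gaussian connectivity
marginals; or any numeric link between the continuous gestational-age
variable and the categorical preterm label (labels are drawn from the
CONTROL/RISK assignment so that the demographic–IQ correlation
calibration stays exact). Passing tests on these cohorts therefore show
that the pipeline's statistics behave as designed under the assumed
generative structure — not that real infant cohorts satisfy that
structure.

## Problem sizes used by the test suite

The packaged tests run at desk scale, chosen once: oracle checks on
4–12-region cohorts; null calibration with a 200-subject reference and
500 external subjects at 30 regions; power and heterogeneity simulations
at 40–50 regions over 20 seeds; and the reference-size sweep on a
175-test / 218-pool design at 64 regions with sizes
{10, 25, 50, 100, 150} × 100 replicates. The acceptance script adds one
full-scale 222-region self-reference run. Statistical conclusions the
tests assert (calibration bands, monotone power in β, robustness to
subgroup flips, plateau and stability trends) are all seed-averaged
trends, not point predictions.

## Known limitations

* The `m1` in/out asymmetry described above makes external-reference
  calls more liberal than self-reference calls at large connection
  counts and small references.
* The method is a hard classifier at fixed thresholds; there is no score
  sweep, so no ROC machinery is provided or meaningful.
* Demographics enter only as a sign; quantitative incorporation of
  demographic information is out of scope.
* Graph-theoretic abstractions of the connectome and connection-level
  "good vs bad" outlier signatures are out of scope.
* With the small outlier counts typical of these designs
  (≈ 19 in 175), all evaluation statistics carry wide sampling
  uncertainty; Fisher's exact test is reported for that reason.
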