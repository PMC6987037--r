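---
title: "Enumerating viable probiotics: models, simulator and method comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating viable probiotics: models, simulator and method comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropcount)
library(dplyr)
```

## The problem

Probiotic products are labelled by viable cell count, so manufacturers
enumerate every production batch. Three technologies dominate:

* **Plate counting** — serial dilution and pour plating; colonies are
  counted on plates carrying 25–250 colonies and scaled back through the
  dilution chain to CFU per gram. Slow (days) and noisy (replicate CVs
  around 15%, with acceptability limits up to 35%).
* **Flow cytometry** — membrane-integrity staining (e.g. Syto24 /
  propidium iodide) and gating of events into live, dead and total
  populations; counts in hours, CVs of a few percent, but no strain
  resolution.
* **Droplet digital PCR (ddPCR)** — template is partitioned into
  ~20,000 oil droplets, end-point PCR classifies each droplet positive or
  negative for a strain-specific single-copy target, and the template
  concentration follows from Poisson partition statistics. Combining
  ddPCR with a viability dye (PEMAX) that covalently blocks amplification
  of DNA from membrane-compromised cells yields a *viable* strain-specific
  count (`PCR.live`); without the dye the assay counts all cells
  (`PCR.total`).

dropcount implements the quantification models for all three
technologies plus the statistics used to compare them across a
multi-batch study, and a measurement-process simulator that generates
studies with a realistic design so that the entire pipeline can be
exercised, validated and stress-tested without access to proprietary
production data.

## Quantification models

### ddPCR: Poisson occupancy

Copies distribute over droplets at random, so the number of copies in one
droplet is Poisson with mean $\lambda$ (the occupancy) and the chance a
droplet is *negative* is $e^{-\lambda}$. From the observed positive
fraction $\hat p = k/n$ ($k$ positive of $n$ accepted droplets),

$$\hat\lambda = -\ln(1 - \hat p), \qquad
  \text{copies}/\mu L = \hat\lambda / V_d,$$

with $V_d$ the droplet volume. `quantify_well()` applies this transform
and the dilution chain: a fold dilution $D$ of the primary suspension and
the rehydration volume per gram (default 10 mL/g, i.e. $10^4$ µL/g from a
1:10 w/v rehydration of powder) give

$$\text{count}/g = \frac{\hat\lambda}{V_d}\times D \times 10^4
  \big/ \text{copies-per-cell}.$$

Uncertainty comes from the binomial sampling of droplets: a Wilson score
interval on $p$ is mapped through the same monotone transform. Wilson is
preferred over the Wald interval for its behaviour at extreme positive
fractions. When every droplet is positive the transform diverges; the
estimate is censored (`saturated` flag, `NA` point estimate) and only the
lower confidence bound is reported. Wells with fewer than 10,000 accepted
droplets are flagged (`below_min_droplets`) but not discarded.

Replicate wells are pooled (`merge_wells()`): positives and accepted
droplets are summed *before* the Poisson transform. Pooling weights every
droplet equally, conserves the raw counts, and has lower variance than
averaging per-well concentrations; the two agree to first order as
$\lambda \to 0$. The per-well (unpooled) estimates are what enter the
replicate-consistency (CV) analysis, since that analysis measures
well-to-well scatter.

### Assay efficiency

A dilution series at fractions $f_i \in (0,1]$ of a reference sample has
theoretical copies $T_i = \text{reference}\times f_i$, anchored at
fraction 1. `fit_efficiency()` regresses measured on theoretical by
ordinary least squares (intercept included by default; configurable) and
reports $100\times$slope as the efficiency with the fit's $R^2$.
Efficiencies in the 90–105% window are flagged acceptable. With only
unbiased partition sampling in play the refit recovers 100% up to
Monte-Carlo error, which the test suite checks.

### Plate counts

Only plates inside the countable window (25–250 colonies, inclusive at
both ends, configurable) are used. Each countable plate converts as
colonies$/(v\cdot d)\times$ 10 mL/g, with $v$ the plated volume and $d$
the dilution level; the batch point estimate pools across countable
dilution levels as $\sum_i c_i / \sum_i v_i d_i$ (total colonies over
total sample mass examined, the ISO 7218-style weighted mean) rather than
using only the lowest countable dilution. Per-plate values are retained
because the consistency analysis needs replicate scatter, not just the
batch mean. A series with no countable plate is a flagged missing value
with a diagnostic ("too numerous to count" etc.), never a silent zero.

### Flow cytometry

The instrument-specific calibration (beads, fluorescence thresholds) is
abstracted into an analyzed-volume factor: gated events divided by the
analyzed volume, scaled through the dilution chain, give cells per gram
for each of the live/dead/total gates. The total gate is the exact sum of
the live and dead gates, replicate by replicate, and the conversion
preserves that additivity.

## Comparison statistics

All statistics run on the linear counts-per-gram scale. Potencies are
labelled in scientific notation, and log transformation would shrink the
reported CVs; the analysis therefore never log-transforms.

* **Consistency** (`method_cv_summary()`): per batch, the CV of a
  method's replicates ($s/\bar x \times 100$, sample SD); per method, the
  mean ± SD of those per-batch CVs over all batches and within strata
  (all batches, NCFM, non-NCFM, per strain).
* **Correlation and regression** (`compare_methods()`): Pearson $r$ of
  per-batch means, and the OLS line of the second method on the first —
  the first-named method is "Method 1", the abscissa against the $y = x$
  reference.
* **Bland–Altman** (`bland_altman()`): relative differences
  $d_i = (x_i - y_i)/\left(\frac{x_i+y_i}{2}\right)\times 100$, bounded
  in $[-200, 200]$ by construction, summarised by $\bar d$ and the limits
  of agreement $\bar d \pm 1.96\, s_d$. The multiplier is the
  conventional literal 1.96, not `qnorm(0.975)`, so hand calculations
  reproduce the limits exactly. Swapping the methods negates the mean and
  swaps-and-negates the limits, which property tests verify. Pairs whose
  sum is zero are excluded with a warning.
* Comparisons use one value per batch (replicate means; the pooled-well
  ddPCR estimate would pass through unchanged). Batches missing either
  method are dropped pairwise with a logged count. No multiple-testing
  correction is applied anywhere: the analysis is descriptive
  (estimation of agreement), not a family of hypothesis tests.

## What the simulator emulates

`simulate_study()` generates a study shaped like a real multi-strain
production campaign: 50 batches over six strains (20 NCFM, 9 Bi-07, 8
Lp-115, 8 HN019, 3 Bl-04, 2 La-14), 17 plates per dilution level,
triplicate ddPCR wells per treatment arm, triplicate flow replicates.
Seventeen plate replicates is the default even though triplicate pour
plating is the more common bench protocol; both are one
`study_design(plate_replicates=)` away.

Per batch, a true live concentration is drawn log-uniformly over
$[10^{10}, 10^{12}]$ cells/g — the range where freeze-dried concentrates
live — and a dead fraction from a Beta distribution with mean 0.15
(concentration 20). Each measurement then follows its own error law:

| parameter | default | meaning |
|---|---|---|
| `plate_rel_sd` | 0.15 | lognormal replicate error of plating (literature-typical ~15% CV) |
| `flow_rel_sd` | 0.03 | lognormal replicate error per flow gate (3–7% is typical) |
| `ddpcr_extra_rel_sd` | 0.01 | well-to-well error on top of partition sampling |
| `pemax_dead_carryover` | 0.2 | dead-cell template surviving viability treatment |
| `flow_live_misgate` | 0.02 | cross-gating fraction between live and dead gates |
| `dead_fraction_mean` | 0.15 | mean dead:live ratio across batches |

Replicate error is multiplicative lognormal: counts are positive and
spreads are naturally relative; no error law is canonical here, and the
lognormal is the standard positive-support choice. The carryover and
dead-fraction defaults are calibration knobs of the simulator, not
measured quantities; they are set so the viable-ddPCR arm reads
systematically above plate counts (carryover × dead fraction ≈ 3%
offset) and the CV ordering Plate ≫ Flow.live > PCR.live emerges, the
qualitative structure one sees when these technologies are compared.
Colony counts are Poisson about their (noise-multiplied) means; droplet
positives are binomial with success probability $1-e^{-m}$; flow events
are rounded gated concentrations.

The analyst's dilution choices are emulated with decade dilutions
targeting each instrument's working range: plates at the decade level
whose expected count is nearest the geometric centre of the countable
window (~79 colonies) plus one level either side, ddPCR at an occupancy
near 0.8 copies/droplet, flow near $10^4$ events/µL. Counts are reported
at *every* simulated dilution level; the countable window is applied
downstream, where it belongs.

Randomness is reproducible and order-independent: one seed governs a
study, and each batch × stage draws from a sub-stream whose seed is a
stable hash of the batch id, so simulating a batch alone reproduces its
slice of the full study.

**What the simulator does not emulate** — and what passing tests
therefore do not establish about real data: droplet "rain" (intermediate
fluorescence amplitudes) and thresholding, PCR inhibition and DNA
liberation efficiency, plate crowding/merging beyond the hard window,
viable-but-not-culturable physiology (the simulator's "live" is one
number; plating and dye-based viability genuinely measure different
things), day/operator/instrument effects, and any between-method bias
beyond the dead-cell carryover. Real studies show larger
between-method disagreement (mean relative differences of −15% and
beyond) than the default simulation produces, precisely because these
unmodelled effects exist.

## Numerical choices and edge cases

* Droplet volume defaults to 8.5e-4 µL (QX200 nominal); configurable per
  record.
* The efficiency regression keeps an intercept by default; forcing
  through the origin is a flag, and the reference point is anchored at
  dilution fraction 1.
* `p = 0` gives $\lambda = 0$ exactly (and a zero lower bound);
  `p = 1` is censored rather than clamped.
* CVs need at least two non-missing replicates and a non-zero mean;
  otherwise `NA`, never 0.
* Weighted-mean CFU pooling makes equal-dilution plates reduce exactly to
  the simple mean.
* Schema validation on CSV input rejects malformed values outright;
  droplet records violating $0 \le k \le n$ are dropped with a warning
  and a count, never silently fixed.

## Validation problem sizes

The test suite validates estimator recovery with 3 × 20,000-droplet
pooled wells over occupancies 0.05–3 (500 replicates each; bias < 2%,
interval coverage checked both empirically and exactly by binomial
enumeration), plate unbiasedness with 600 noise-free simulated batches,
and the study-level CV ordering over 20 independently seeded 50-batch
studies. These sizes keep the full suite around a minute on one core
while leaving Monte-Carlo error well below the tolerances checked.

## Limitations

The package consumes summarised instrument output (droplet counts, colony
counts, gated events), not raw fluorescence or FCS files. Bland–Altman
limits assume approximately normal relative differences; with only a few
batches the limits are themselves noisy. The simulator's agreement
between methods is optimistic (see above), so it is a test harness and a
teaching tool, not a substitute for method validation on real batches.
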