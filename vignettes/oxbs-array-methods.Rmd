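---
title: "Quantifying 5hmC from paired BS/oxBS arrays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 5hmC from paired BS/oxBS arrays: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxbsarray)
```

## The measurement model

Bisulfite (BS) conversion deaminates unmodified cytosine to uracil but
leaves both 5-methylcytosine (5mC) and 5-hydroxymethylcytosine (5hmC)
unconverted, so a BS methylation array reads the *sum* of the two marks.
Oxidative bisulfite (oxBS) first oxidizes 5hmC to 5-formylcytosine, which
then converts like unmodified C; only 5mC survives. Splitting one DNA
sample over paired BS and oxBS arrays therefore gives, at each CpG probe,

* `beta_BS  ~ 5mC + 5hmC`
* `beta_oxBS ~ 5mC`

and the subtraction estimator

```
5mC  = mean(beta_oxBS),   5hmC = mean(beta_BS) - mean(beta_oxBS),
C    = 1 - mean(beta_BS),
```

where arm means are simple averages over replicate arrays. The three
estimates sum to one by construction. The estimated 5hmC is **signed**:
at probes with little or no 5hmC, measurement noise makes the difference
negative about half the time, and the package deliberately reports those
negatives rather than clamping them — the rate and symmetry of negative
calls is the main internal diagnostic that significant positive calls are
genuine. Constrained (sum-to-one-aware) joint estimation is intentionally
out of scope.

Because the difference of two noisy betas is itself noisy, a per-probe
significance test decides which probes have *reliable* positive 5hmC. The
package uses a moderated F-test (below) at a Benjamini–Hochberg FDR
threshold of 0.01, and headline summaries (median level among significant
positives, detection floor, regional proportions) are computed over the
significant positive set.

## From intensities to betas

Each probe/array cell carries methylated (M) and unmethylated (U) channel
intensities, and `beta = M / (M + U + alpha)` with `alpha = 100` intensity
units by default — the platform's stabilizing offset. `alpha` bounds betas
away from 1 and damps ratio noise at dim probes, at the cost of a small
multiplicative compression (`~ T/(T + alpha)` with `T` the total
intensity, about 2% at the simulator's default brightness). Pass
`alpha = 0` to `compute_beta()` for uncompressed measurement-model betas;
the parameter-recovery tests do exactly that, because they measure the
subtraction estimator rather than the offset.

**Detection p-values.** For each array a Gaussian background is fitted to
the negative-control probes (`mu_bg` = sum of channel means, `sigma_bg` =
sum of channel SDs, the conservative convention), and each probe's
detection p is the upper tail of `M + U` under that background. Probes
undetected (`p >= 0.01`) in **more than one** array are excluded. Texts
sometimes state this filter as "detection p < 0.01 in more than one array
excluded", which taken literally would discard the *best* probes, since
low detection p means signal clearly above background; the package
implements the standard reading (fail when `p >= threshold`) and exposes
`fail_when = "lt"` for strict comparability with the literal one.
Detection is assessed on **raw** intensities because the background model
comes from raw controls; normalization happens independently.

**SWAN normalization.** Infinium Type I and Type II probes have different
intensity distributions. Subset-quantile within-array normalization draws,
per CpG-content stratum (1, 2, 3+ CpGs in the probe body), equal numbers
of Type I and Type II probes; the reference distribution is the pointwise
mean of the two subsets' sorted intensities; subset probes map to it by
rank, all other probes by linear interpolation between flanking subset
quantiles, with a constant offset beyond the extremes. The subset draw is
seeded (`swan_seed`) and shared across arrays and channels of one run, so
reruns are byte-identical. The pipeline order is: normalize intensities,
filter failed probes, then compute betas — keeping the normalization
independent of the filter.

## The moderated F-test

With `n1` BS and `n2` oxBS replicates (4 + 4 by default), each probe has
pooled within-arm variance `s^2` on `d = n1 + n2 - 2` degrees of freedom —
far too few to test each probe on its own. The empirical-Bayes hierarchy
assumes `s^2 ~ s0^2 * chisq_d / d` with a scaled-inverse-chi-square prior
(`d0`, `s0^2`) on true variances, fitted by moment matching on
`e = log s^2 - digamma(d/2) + log(d/2)`: the excess of `var(e)` over
`trigamma(d/2)` estimates `trigamma(d0/2)` (inverted by Newton iteration,
tolerance 1e-10), and `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.
Two degenerate branches are handled explicitly: if `var(e)` does not
exceed what sampling alone explains, `d0 = Inf` with the bias-corrected
geometric mean as `s0^2`; if all sample variances are *identical* (no
sampling scatter at all — only possible with degenerate input), the
common value itself is used, so squeezing is then an exact no-op. Zero
variances are floored at 1e-8 (beta-scale variance far below anything an
array produces) before taking logs.

Each probe's variance is squeezed to
`s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and tested with
`F = delta^2 / (s~^2 (1/n1 + 1/n2))` against F(1, d + d0) — the prior
contributes `d0` extra degrees of freedom (chi-square(1) at `d0 = Inf`;
exactly the classical pooled t-test squared at `d0 = 0`). The test runs on
betas, not M-values: the whole analysis interprets betas as methylation
fractions, and the subtraction estimator lives on the beta scale, so
testing the same scale keeps effect sizes and calls coherent. P-values are
BH-adjusted (step-up, authored in the package and cross-checked against
brute force and `p.adjust` in the tests) and calls are two-sided with the
sign taken from `delta`, so positive and negative significant probes are
accounted separately.

## What the simulator emulates — and what it does not

`simulate_truth()` + `simulate_intensities()` generate the whole study:
a synthetic genome of 30 kb gene units (1 kb flanks, UTRs, three exons,
CpG islands at ~60% of TSSs plus occasional intergenic islands), probes
placed in features with 450K-like density, and per-probe true
`(C, 5mC, 5hmC)` summing to one exactly. Regional structure follows the
biology the analysis must resolve: islands and TSS-proximal probes carry
low 5mC and are *less likely* to carry 5hmC, gene bodies the opposite,
while nonzero 5hmC *levels* are drawn from one distribution everywhere
(uniform on [0.005, 0.45] by default) — so per-region medians among
carriers are roughly flat even though carrier proportions differ, and the
marginal carrier fraction is exactly `1 - pi0` (default `pi0 = 0.7`).

Replicate noise is injected on the beta scale as a Beta-distributed
perturbation with **exact** mean equal to the arm's true level and SD
equal to the probe's `noise_sd` (drawn uniform on [0.005, 0.05] by
default; the SD is capped at `0.9 * sqrt(p(1-p))` where a Beta law cannot
reach the target). A logit-normal perturbation was considered and
rejected: its mean bias of order `sigma^2 p(1-p)(1-2p)` breaks the
unbiasedness of the measurement model precisely at the low betas where
the detection floor is decided. Noisy betas are converted to channel
intensities `M = T*beta`, `U = T*(1-beta)` with lognormal per-cell totals
(Type I probes 1.25x brighter, giving SWAN real work), a small
`fail_rate` of cells is replaced by background draws (exercising the
detection filter), and negative-control probes are drawn from the
background throughout. At these defaults, between-replicate beta
correlations land at ~98 (x100 scale) within each arm, the regime the
assay needs.

What it does **not** model: dye bias, batch or position effects, probe
cross-hybridization, SNPs under probes, bisulfite-conversion failure, or
Type I/II chemistry beyond an intensity scale factor. Passing tests
therefore show the *analysis* is correct and calibrated under honest
noise; they do not certify performance on any real tissue.

## Numerical choices and conventions

* Coordinates are 0-based half-open in all BED/TSV artifacts, 1-based
  internally via `GenomicRanges`. Probe-to-island distance is bp to the
  nearest merged island edge (0 inside); shore is (0, 2000] and shelf
  (2000, 4000], half-open on the outer edge, so a probe exactly 4000 bp
  away is still shelf.
* Gene-feature precedence for probes under several features:
  5'UTR > 3'UTR > exon > intron > upstream > downstream, across all
  overlapping genes; inside a transcript but in no feature is `other`;
  touching nothing (including the 1 kb flanks) is `intergenic`.
* The TSS profile uses signed strand-aware distance (negative =
  upstream), 200 bp bins to +-4 kb.
* qPCR: the protected fraction relative to the undigested control is
  `efficiency^-(Cq - Cq_undig)`; 5hmC is the glucosylated-minus-mock
  difference of protected fractions, clamped to [-1, 1]. Replicate Cqs
  are averaged on the Cq scale before exponentiation (standard practice).
  Efficiency defaults to 2 (perfect doubling) and is configurable per
  site. Only Cq differences enter the estimate.
* Replicate-subset analyses refit the shrinkage prior within each subset,
  mirroring genuinely separate analyses; default subsets are pairs {1,3}
  and {2,4} in both arms. Pair counts are reported both for all
  significant probes and positives only, since the two accountings differ.
* Every stochastic step (truth, intensities, SWAN subset, qPCR noise) is
  seeded through configuration; identical configuration gives
  byte-identical TSV artifacts.

## Problem sizes and limitations

The bundled analysis scripts and acceptance checks run one simulated
study of 100k probes with 4 + 4 replicates (seconds on one core);
power-comparison loops use 20k probes over 10 seeds and pure-null
calibration 50k probes over 20 seeds. These sizes give binomial standard
errors small enough to check 1%-scale error rates without overnight runs.

Two limitations are worth knowing. First, the empirical-Bayes prior
assumes one variance population; under strongly heteroskedastic noise
(per-probe SD spanning 0.005–0.05) the fitted `d0` is small (~2) and the
squeeze still pulls the *quietest* probes' variances up toward the
population value. That is exactly what floors the detectable 5hmC
estimate near 3% in the simulated study — low-noise probes lose their
advantage to the prior. A variance model stratified by detection
intensity or a robust prior would lower the floor; both are future work.
Second, `alpha = 100` and SWAN each compress betas slightly (a few tenths
of a percentage point on the 5hmC difference at default brightness), a
known property of the transform; estimator-calibration checks therefore
run on `alpha = 0`, non-normalized betas, while error-rate and power
checks run the full default pipeline.
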