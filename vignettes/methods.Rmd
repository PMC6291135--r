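---
title: "Models and methods behind methagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methagree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methagree)
```

## The problem

When the same biological samples are measured twice — for example, DNA from
the same blood donors extracted with different methods and hybridised to a
methylation array — the question is not whether the two measurement series
correlate (they always do; between-subject biology dominates), but whether
they *agree*: how large are the paired differences, do they depend on the
methylation level, and do any sites or genomic regions differ
systematically between the two series? `methagree` implements an analysis
pipeline for this question on beta-value matrices (per-CpG methylation
fractions in $[0,1]$, sites in rows, samples in columns), built around four
stages: Bland–Altman agreement with a heteroscedastic variance function,
binned summaries of per-site mean differences, principal-component
screening against technical covariates, and paired differential testing at
the global, per-CpG and regional level.

## The heteroscedastic Bland–Altman model

For a pair of measurement series, every subject–site combination yields an
average $x_i$ and a signed difference $d_i$. Classical Bland–Altman limits
of agreement, $\bar d \pm 1.96\,\mathrm{sd}(d)$, assume the differences are
homoscedastic and normal. Array beta-values violate this visibly: noise is
compressed near the boundaries 0 and 1 and largest at intermediate
methylation. The package therefore fits

$$ d_i \sim \sigma(x_i)\,e_i, \qquad e_i \sim N(0,1), \qquad
   \sigma(x) = e^{a + b\,(x - 0.5)^2}, $$

so that $b < 0$ gives a noise band widest at $x = 0.5$. The constants
$(a, b)$ are estimated by minimising the Gaussian negative log-likelihood

$$ \ell(a,b) = \sum_i \Big[ \log \sigma(x_i) +
   \frac{d_i^2}{2\,\sigma(x_i)^2} \Big], $$

which is the objective implied by the model; a least-squares fit to $|d|$
would estimate a different functional and is deliberately not offered.
Minimisation uses BFGS with the analytic gradient, started at
$a_0 = \tfrac12 \log \overline{d^2}$, $b_0 = 0$, with a relative objective
tolerance of $10^{-12}$; convergence failures are flagged on the returned
object and warned about, never silent. Limits of agreement are
$\pm z\,\sigma(x)$ with $z = 1.96$ by default. Two consequences of the
model are used as internal checks: with $b$ fixed at 0 the MLE has the
closed form $e^{2a} = \overline{d^2}$, and data simulated from a fitted
model should place 95% of differences inside the limits.

The model has no mean-difference (bias) term. Because classical
Bland–Altman analysis centres its limits on the mean difference, the
empirical mean difference is always computed and reported alongside the
fit (`mean_diff` in `glance()`), so a global bias between series remains
visible even though the limits are symmetric around zero.

The fit uses all points by default — two parameters against millions of
points is a desk-scale problem — with an optional seeded subsample for
exploratory work. Repeated Shapiro–Wilk tests on random subsamples
(default ten draws of 5,000 differences) document whether the classical
homoscedastic-normal assumption would have been tenable.

## Difference-distribution tables

Per site, the mean over subjects of the signed difference is computed and
its absolute value binned into $[0, 0.01), [0.01, 0.02), \dots,
[0.09, 0.10), [0.10, \infty)$; the table reports the percentage of sites
per bin. Bins are half-open on the right: a published table of such ranges
does not state edge handling, and half-open intervals make the bins a
partition with no double counting. Percentages are exact fractions of the
site count and sum to 100 before any display rounding.

## PCA and covariate screening

PCA treats samples as observations and sites as variables, with site-wise
centring and no scaling (beta-values already share one scale); this is one
of several defensible conventions, so variance-explained figures from other
toolchains reproduce only approximately. At most $n_{\text{samples}} - 1$
components are meaningful after centring and only those are retained —
trailing zero-variance components are numerical noise whose test results
would not be reproducible.

Each retained PC is tested against each technical covariate:
Kruskal–Wallis for categorical covariates (extraction method, position on
chip), two-sided Spearman correlation for numeric ones (DNA yield,
A260/280, A260/230). Multiple testing is corrected by Bonferroni
*per covariate across components* ($m$ = number of PCs tested). This is the
stricter of the two readings of "Bonferroni across the screen" (the other
pools all covariate–PC combinations into one family); it keeps each
covariate's conclusion self-contained. Both rank tests are thin wrappers
around the standard R implementations; degenerate inputs (all values tied,
constant covariate) return explicit `H = 0, p = 1` or `NA` results with
warnings rather than errors, so a screen over many PCs never aborts
mid-way.

## Paired differential testing

Three levels, all two-sided at conventional thresholds:

* **Global** ($\alpha = 0.05$): per subject, beta-values are averaged over
  all sites separately per series; a paired t-test compares the
  $n_{\text{subjects}}$ global means.
* **Per CpG** (FDR < 5%): a paired t-test per site, vectorised via the
  closed form $t = \bar d / (s_d / \sqrt{n})$, with Benjamini–Hochberg
  adjustment across sites (`stats::p.adjust`). Sites with zero-variance
  differences have no defined t statistic; they are reported as `NA`,
  excluded from the BH family, and counted in a warning — silently
  dropping them would shrink the family and bias the adjustment.
* **Regional** (FWER < 5%): a bump-hunting search described next.

## The region search and its null

Sites are grouped into clusters: a new cluster starts at each chromosome
change or when the gap to the previous site exceeds `max_gap` (default
1000 bp; a gap of exactly `max_gap` stays together, i.e. the split rule is
strictly-greater). Within clusters of at least 7 sites the per-site mean
differences are loess-smoothed over genomic position; smaller clusters use
raw effects, since a local quadratic smoother needs support. The loess
span is chosen per cluster so that the smoothing window covers roughly
`bp_span` (default 1000 bp) and never fewer than 7 sites, capped at
`loess_span = 0.75`. A constant span fraction was considered and rejected:
in a long cluster (the synthetic default places all sites 500 bp apart, so
one chromosome is a single cluster) a 0.75 span averages over most of the
chromosome and erases any region-scale signal; parameterising the window
in base pairs keeps the smoother's bandwidth aligned with the genomic
scale of the regions being sought, which is how cluster-based smoothers in
this field are parameterised.

Candidate regions are maximal same-sign runs of sites whose absolute
smoothed effect reaches `cutoff` (default 0.01 on the beta scale), scored
by area = the sum of absolute smoothed effects over the run. Significance
uses a sign-flip bootstrap: under the paired null hypothesis each
subject's entire difference vector is symmetric around zero, so flipping
the sign of each subject's vector independently with probability ½ yields
an exchangeable null draw that preserves all within-subject correlation
structure. Each of `n_boot` (default 250) bootstraps repeats the
smoothing-and-run search and records its *maximum* area; a region's FWER
is the fraction of bootstraps whose maximum reaches the region's observed
area. This max-statistic construction controls the family-wise error rate
across all candidate regions simultaneously. It deliberately replaces the
linear-model residual bootstrap of the original bump-hunting package: for
a two-series paired design the sign-flip null is exact, simpler, and does
not require refitting a model per bootstrap.

## The synthetic-data generator

The generator produces datasets with the structure the analysis assumes,
so every stage can be exercised end-to-end without downloads:

* **Site means** come from a three-component mixture of beta
  distributions — weights $(0.40, 0.15, 0.45)$ on
  $\mathrm{Beta}(2,20)$, $\mathrm{Beta}(5,5)$, $\mathrm{Beta}(20,2)$ —
  reproducing the bimodal distribution of whole-blood array
  methylation, where most CpGs are either strongly methylated or strongly
  unmethylated and a minority sit at intermediate levels.
* **Subjects** vary around the site mean on the logit scale with standard
  deviation `subject_sd` (default 0.5, about 0.1 on the beta scale at
  intermediate methylation) — an order of magnitude above the technical
  noise, matching the observation that biological differences dwarf
  method differences.
* **Technical noise** is added per measurement with standard deviation
  $\sigma(x)/\sqrt2$, where $\sigma(x) = e^{a + b (x-0.5)^2}$ with
  defaults $a = -3$, $b = -4$ (difference SD $\approx 0.05$ at $x = 0.5$,
  $\approx 0.018$ at the boundaries). The $\sqrt2$ split makes the
  *difference* of two series have SD exactly $\sigma(x)$ — the quantity
  the agreement model fits. The paper-facing model describes only the
  difference; the per-measurement decomposition is this package's choice.
* **Method effects** can be injected as global offsets per method or as
  genomic regions (chromosome, span, affected method, delta) for
  positive-control experiments.
* Values are **clamped** to $[0,1]$ after adding noise. Clamping slightly
  deflates the variance near the boundaries; with $b < 0$ boundary noise
  is already tiny, so the deflation is negligible away from extreme
  sites. This is a known, accepted bias chosen over logit-scale noise for
  transparency: on the beta scale the injected effect sizes and the
  variance function mean exactly what they say.

By default sites sit on one chromosome at 500-bp spacing, so under the
1000-bp cluster gap they form one cluster — convenient for region-search
tests. Sample sheets are populated with method-typical DNA yields and
purity ratios and BeadChip-style positions (a subject's samples share a
chip), so the covariate screen has realistic inputs.

What the generator does *not* emulate: Infinium probe-type chemistry
(type I/II differences), cell-type composition, genomic autocorrelation of
methylation beyond injected regions, and probe-level artefacts. Passing
tests therefore demonstrate the statistical machinery is correct under the
stated model, not that any particular laboratory comparison will behave
this way.

## Numerical and design choices

* **Filtering order.** Sites are removed by the first matching rule in
  the order blacklist → detection p-value → non-CpG → missing →
  chromosome, and counted once, so per-category counts plus retained
  always equal the input count. The order mirrors the conventional
  listing of these filters; exclusive first-match counting is an explicit
  convention since published totals rarely state one.
* **Detection filter.** A site is dropped when any sample's detection
  p-value exceeds 0.01 (strictly greater). Iterative probe/sample removal
  schemes are out of scope; the pipeline expects already-normalised
  betas.
* **Half-open bins**, **strictly-greater gap splits**, and
  **strictly-greater detection threshold** are the package's tie-break
  conventions, each chosen to make boundaries unambiguous and stated in
  the corresponding function documentation.
* **Determinism.** Every stochastic step (simulation, subsampling,
  normality screen, bootstrap) takes an explicit seed; the pipeline
  report isolates its timestamp in a single header field so reruns are
  otherwise byte-identical, and embeds a hash of the effective
  configuration.
* **Problem sizes in the test suite.** The statistical checks run at
  200,000 points for variance-model recovery, 100,000 draws for coverage,
  10,000 sites for the t-test level, and 100 seeded runs of 2,000 sites
  with 50 bootstraps for the FWER calibration — sizes at which the
  Monte-Carlo error is comfortably below the tolerances asserted while a
  full run stays interactive.

## Known limitations

* The variance-model fit assumes conditionally Gaussian differences; for
  grossly heavy-tailed differences the MLE of $(a,b)$ is still defined
  but the 95% interpretation of $\pm 1.96\sigma(x)$ degrades. The
  normality screen documents this.
* The sign-flip bootstrap requires the paired design; it does not extend
  to unpaired comparisons.
* With 250 bootstraps the smallest attainable FWER is 0; resolution below
  1/250 requires more bootstraps.
* PCA variance-explained fractions depend on the centring/scaling
  convention; cross-toolchain comparisons should expect tolerance-level,
  not exact, agreement.
* The region search reports candidate regions at any FWER; filtering at
  5% is the caller's decision, and with small subject counts (< 5) the
  sign-flip null has too few distinct flip patterns to be useful.
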