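---
title: "Multiple-testing control for IBD-rate selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-testing control for IBD-rate selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdscan)
```

## The scan and its null model

Recent positive selection leaves an excess of long identity-by-descent (IBD)
haplotype segments around the selected allele. The scan statistic at a focal
genetic position $m$ is the IBD rate
$$\bar Y_m = f(n)^{-1} \sum_{(a,b)} Y_{a,b}(m),$$
the fraction of eligible haplotype pairs $(a,b)$ sharing a detectable segment
(genetic length at least the detection threshold, typically 2.0 or 3.0 cM)
that overlaps $m$. The pair count is $f(n) = 2n(2n-1)/2 - 2n$ for $n$ diploid
individuals and $f(n) = n^2$ for haploids; `pair_count()` implements these
formulas exactly as stated, although we note that the diploid form subtracts
$2n$ where only $n$ within-individual haplotype pairs exist. For consistency,
`compute_ibd_rates()` excludes within-individual (homozygosity-by-descent)
pairs from the numerator as well.

Focal positions are laid out on a uniform genetic grid with spacing $\Delta$
(default 0.02 cM) by `build_grid()`, with segment endpoints converted between
bp and cM by linear interpolation on the recombination map. By default the
grid trims a margin equal to the detection threshold (2.0 cM) from each
chromosome end, where a threshold-length segment cannot be fully observed;
for ten 100 cM chromosomes at 0.02 cM spacing this gives
$M = 10 \times (\lfloor 96/0.02 \rfloor + 1) = 48{,}010$ tests. A segment
covers a focal position under the closed-interval convention
(start cM $\le m \le$ end cM), which makes the grid arithmetic exact; coverage
is accumulated with a difference array in one pass over the segments.

The test rejects at position $m$ when
$\bar Y_m - \hat\mu > z_{\alpha^*} \hat\sigma$ (strict inequality; equality
fails to reject). Under large-sample conditions the standardized rates
$\tilde Z_m = (\bar Y_m - \hat\mu)/\hat\sigma$ are approximately standard
normal, and we model them along the genome as a stationary
Ornstein–Uhlenbeck (OU) process with autocovariance
$\mathrm{Cov}(\tilde Z_{m_1}, \tilde Z_{m_2}) =
\exp(-\theta \Delta |m_2 - m_1|)$, where $\theta$ (per Morgan) is the
exponential decay rate of the autocorrelation. Larger $\theta$ means faster
decorrelation and more effectively independent tests.

## Robust standardization

Real scans contain loci under strong selection whose rates would corrupt the
null moments, so `robust_standardize()` uses two passes: an initial outlier
threshold (genome-wide median + 4 SD over all rates, plain sample SD with
denominator $M-1$), then revised mean and SD over the rates at or below that
threshold. All positions are standardized with the revised moments; the
outlier rule is applied once, not iterated. If every non-outlier rate is
identical (e.g. all zero, as happens when the sample is too small to observe
any segments), standardization fails loudly rather than emitting a constant
track — with small samples the scan plots should be reviewed for rates
truncated at zero.

## Estimating the decay parameter

`estimate_theta()` estimates $\theta$ from empirical autocovariances
$\hat c_k$ of the standardized rates at lags $k\Delta$ for
$k = 1, 2, \dots$ up to 4.0 cM. Pairs are formed within chromosomes only and
pooled across chromosomes (one $\theta$ per genome is what the thresholds
need), pairs touching an outlier position are excluded, and each estimate
centers by the mean of the included values with the pair count as
denominator. A log-linear model with no intercept is then fit by ordinary
least squares, $\log \hat c_k = -\theta \cdot k\Delta$, giving
$$\hat\theta = -\frac{\sum_k (k\Delta) \log \hat c_k}{\sum_k (k\Delta)^2}.$$
Non-positive $\hat c_k$ carry no log-scale information and are dropped; if
fewer than three positive estimates remain the fit fails rather than
extrapolate. The estimator is agnostic to the grid spacing and equivariant
to the genetic unit (relabelling cM as Morgans multiplies $\hat\theta$ by
100); internally all threshold computations are done in Morgans, since the
analytical formula mixes $\theta L$ and $\theta \Delta$ and a single unit
avoids silent factor-of-100 errors. Recovery is reliable for
$30 \le \theta \le 90$ on genomes of at least 400 cM, which is the regime
the package's tests exercise.

## Genome-wide significance thresholds

Three corrections are provided for the family-wise level $\alpha$ (the
probability of at least one false rejection genome-wide).

**Analytical** (`analytical_quantile()`): the boundary-crossing
approximation for the maximum of a discretely observed OU process over a
genome of $C$ chromosomes and total length $L$ Morgans,
$$P\!\left(\max_m \tilde Z_m \ge z\right) \approx 1 - \exp\!\left\{
-\Big[C(1-\Phi(z)) + \theta L z \phi(z)\,
\nu\big(z\sqrt{2\theta\Delta}\big)\Big]\right\},$$
solved for $z_{\alpha^*}$ by bracketed bisection on $z \in [1, 10]$, polished
to a residual below $10^{-12}$. The factor $\nu(\cdot)$ corrects for
discretization, evaluated by the standard rational approximation
$\nu(y) = [(2/y)(\Phi(y/2)-\tfrac12)] / [(y/2)\Phi(y/2)+\phi(y/2)]$ with
$\nu(0)=1$ (the continuous limit) and $\nu(y) \approx e^{-0.583y}$ for small
$y$. The per-test genome-wide significance level is
$\alpha^* = 1 - \Phi(z_{\alpha^*})$.

**Simulation** (`simulation_quantile()`): draws $J$ (default 2000) OU chains
via the first-order recursion $z_1 \sim N(0,1)$,
$z_m \mid z_{m-1} \sim N(z_{m-1} e^{-\theta\Delta},\, 2 - 2e^{-\theta\Delta})$,
each a single chromosome of the total genome length ($M = \lfloor L/\Delta
\rfloor$ steps — a deliberate simplification over per-chromosome chains,
whose effect on the maximum is negligible because the chromosome-count term
contributes under 1% of the crossing rate at scan-relevant $z$). The
threshold is the order statistic of rank $\lceil (1-\alpha) J \rceil$ of the
$J$ chain maxima. The published conditional variance $2 - 2e^{-\theta\Delta}$
is used verbatim by default; it exceeds the exactly stationary form
$1 - e^{-2\theta\Delta}$ at order $(\theta\Delta)^2$, giving the chain a
stationary variance of $2/(1+e^{-\theta\Delta})$, about 0.5% above 1 at
default spacings. The `stationary` flag switches to the exact form. The
recursion is evaluated with `stats::filter()`, so a 2000-replicate threshold
for a 10-Morgan genome takes seconds.

**Bonferroni** (`bonferroni_quantile()`): $\alpha^* = \alpha/M$, roughly an
order of magnitude more stringent than the OU-based corrections at default
geometries, because it ignores the correlation between nearby tests.

For any shared geometry the quantiles are ordered Bonferroni $\ge$
analytical $\ge$ single-test, $z^*$ increases in $\theta$, $L$ and
$1/\alpha$, and decreases as $\Delta$ grows (coarser grids take fewer
effective tests; this is the direction implied by the formula, since $\nu$
is decreasing). The simulation-based approach is recommended when
$\hat\theta \le 20$, where the analytical approximation is noticeably
conservative; `ibd_scan()` emits that recommendation when triggered. The
heuristic median-plus-four-SD rule is always computed alongside for
comparison; its implied level is fixed at $1-\Phi(4) = 3.17\times 10^{-5}$
regardless of genome size or spacing.

## Region calling and diagnostics

`call_regions()` reports maximal runs of consecutive rejections within a
chromosome whose genetic span (run length $-1$ times $\Delta$) is at least
0.50 cM, with the peak at the run's maximum rate and a normal upper-tail
p value at the peak; p values below the smallest positive double are
reported as `underflow` rather than 0. Sub-threshold gaps do not merge
regions — a region is a strictly contiguous significant stretch.
`max_min_statistic()` (window 3) replaces each statistic by the minimum over
itself and its in-chromosome flanks before taking the genome maximum, which
suppresses isolated one-point exceedances; `count_significant_windows()`
partitions chromosomes into windows anchored at the first grid point (the
phase is a package choice) and counts windows containing a rejection.

## The validation harness and what it shows

`simulate_ou_genome()` draws independent per-chromosome OU chains and
`run_fwer_experiment()` measures, over (by default 500) simulated null
genomes, the fraction with at least one rejection. Each simulated genome is
passed through the same two-pass standardization as real data before
thresholding — the test never standardizes by the generative truth — which
also absorbs the Algorithm-level variance inflation noted above. With this
harness, on ten 100 cM chromosomes at 0.02 cM spacing the analytical
threshold at $\alpha = 0.05$ yields an empirical FWER of about 0.04
(conservative), and the simulation-based threshold about 0.05, with binomial
standard error $\approx 0.01$ at 500 replicates. Thresholds are computed
once from the true $\theta$ by default; `reestimate_theta = TRUE` instead
re-estimates $\hat\theta$ from every simulated genome, emulating the full
analysis pipeline at extra cost.

`synthetic_segment_file()` provides an end-to-end fixture: segment midpoints
uniform along the genome, genetic lengths from a shifted exponential with
mean `length_scale_cm` above the detection threshold, and haplotype pairs
drawn uniformly (redrawn when both haplotypes fall in one diploid
individual, so the realized rate matches the target under the
within-individual exclusion). The segment count is set so the expected
interior rate equals `mean_rate`. This generator exercises the scan
plumbing — coordinate conversion, filtering, counting, thresholding — but
deliberately does not emulate coalescent features of real IBD data: segment
lengths are not correlated with local ancestry depth, segments do not
cluster around shared ancestors, and the rate process it induces is not an
OU process. Passing tests on these fixtures therefore demonstrate correct
mechanics and calibrated thresholds under the OU null, not FWER control
under true coalescent IBD-rate processes, whose heavier upper tail can make
the 2.0 cM scan anti-conservative.

## Numerical and design choices

* Flat (zero-recombination) map stretches invert cM→bp to the leftmost bp;
  duplicate bp records collapse to the first.
* Grid points sit at `start + trim + k·Δ`, anchored per chromosome; no
  global phase alignment across chromosomes.
* The length filter uses the segment file's cM column (detector semantics);
  spans are converted to cM by interpolation, clamped to the mapped range.
* The empirical simulation quantile uses the rank-$\lceil(1-\alpha)J\rceil$
  order statistic, no interpolation; `J = 2000` by default, with
  `J \ge 100` and $\alpha J \ge 5$ enforced.
* Problem sizes in the test suite — OU genomes of 400–1000 cM, 100
  replicates for recovery studies, 500 for FWER — were chosen as the
  smallest sizes at which the targeted quantities are stable relative to
  their Monte Carlo error.
* All randomness flows through R's RNG; functions with internal simulation
  accept an integer `seed` and record it in their results, making every
  experiment bit-reproducible.

## Limitations

The OU model assumes spatial homogeneity and near-Markov behavior of the
rate process; both are approximations for real IBD rates, and the upper
tail of real rates can be heavier than normal, particularly for the 2.0 cM
detection threshold in large or recently bottlenecked populations. The
package does not detect IBD segments, phase data, or infer demography, and
provides no power analysis under explicit sweep models; it starts from
detected segments and a recombination map.
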