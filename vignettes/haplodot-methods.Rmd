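---
title: "Models and methods behind haplodot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplodot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodot)
```

## The generative model

haplodot works on haplotype-aggregated allele-specific expression (ASE): for
each gene in each individual, the RNA-seq reads overlapping phased
heterozygous sites are summed per haplotype into a single pair of counts
$(a, b)$.  Aggregation across sites discards the linkage structure between
individual regulatory variants and measurement sites, so instead of modelling
variant-level configurations we place *all* cis-regulatory variation in one
latent quantity: the log allelic fold change

$$\delta_{gi} \sim \mathcal{N}(0,\ \sigma_g^2), \qquad
  a_{gi} \mid \delta_{gi} \sim
  \mathrm{Binomial}\!\left(n_{gi},\ \mathrm{logistic}(\delta_{gi})\right),$$

where $n_{gi} = a_{gi} + b_{gi}$ is the total coverage.  The marginal law of
$a$ is a binomial-logit-normal (BLN) distribution.  The per-gene parameter
$\sigma_g$ — the population standard deviation of the log allelic fold
change — is the quantity of interest: genes under tight regulatory
constraint have small $\sigma_g$, genes with common regulatory variants of
large effect have large $\sigma_g$.  The latent mean is fixed at zero
because haplotype A/B labels are arbitrary per individual, which makes the
marginal law symmetric; the package exposes `mu` in the distribution
functions for generality, but every estimation and testing path uses
`mu = 0`.  For interoperability with variance-convention reference tables,
estimates also carry `vg = sd_g^2 / 2`, the per-haplotype variance of the
half log fold change; two-column legacy tables can be loaded with an
explicit convention flag (`read_vg_table(..., vg_convention =)`).

## Numerical evaluation of the BLN law

The pmf has no closed form.  `dbln()` evaluates
$\Pr(x) = \int \mathrm{Binom}(x; n, \mathrm{logistic}(\delta))\,
\varphi(\delta; 0, \sigma^2)\, d\delta$ by Gauss–Hermite quadrature that is
recentred and rescaled at the mode of the integrand (the Liu–Pierce adaptive
rule): a damped-free Newton iteration finds the mode of the strictly concave
log-integrand, the local curvature sets the scale, and the quadrature nodes
are placed there.  This matters because the integrand has two length scales
— $\sigma$ from the latent normal and $\approx 1/\sqrt{n p q}$ from the
binomial kernel — and plain Gauss–Hermite under-resolves the binomial factor
whenever $\sigma \gg 1/\sqrt{n}$.  With mode centring, order 61 (the
default; order 25 in the fitting hot path) reproduces a $10^6$-draw
Monte-Carlo oracle to within Monte-Carlo noise across $n$ up to $10^3$ and
$\sigma$ up to 2, and normalizes to machine accuracy.  All arithmetic is in
log space with log-sum-exp and log-gamma binomial coefficients, so the pmf
stays finite for totals up to at least $10^5$.

Tail probabilities (`pbln()`, `bln_two_sided_p()`) integrate the conditional
binomial CDF against the latent normal density on a dense trapezoidal grid
in $\delta$, with spacing $\min(\sigma, 1/\sqrt{n\tilde p \tilde q})/8$ and
range covering both the latent distribution and the binomial transition
region.  Summing per-$x$ pmf values would cost $O(n)$ quadratures per tail;
the CDF-under-the-integral form costs one vectorised `pbinom` sweep and is
what makes the $10^5$-test calibration studies feasible.  Both tails share
one grid, and everything is carried in log space so extreme imbalances
(e.g. $100|0$ under $\sigma = 0.05$, $p \approx 10^{-29}$) are exact rather
than underflowed.

## Estimating sd_g

`fit_gene()` maximizes the per-gene profile likelihood
$\sum_i \log \Pr(a_i \mid n_i, \sigma)$ over
$\sigma \in [10^{-3}, 5]$ by Brent search on $\log \sigma$ (compiled; the
bounds span "no detectable regulatory variance" through complete monoallelic
switching, and estimates that land on a bound are flagged `at_bound`).
Genes qualify when at least 6 individuals have total coverage of at least 30
(`eligible_genes()`); within a fit, individuals below a total of 10 are
dropped, aligning the likelihood with the outlier-test coverage threshold.
The optimum was validated against a brute-force 2000-point grid search on
random small instances.

Confidence intervals come from a parametric bootstrap (`bootstrap_ci()`,
default `B = 1000`): counts are resampled from the fitted BLN law
*conditional on the observed totals* — coverage is ancillary to regulatory
variance, so it is held fixed — and each replicate is refit.  The interval
is the percentile interval (inverse-ECDF quantiles, so `B = 2` degenerates
to the min/max of the two refits), clipped to bracket the point estimate so
the `ci_low <= sd_g <= ci_high` invariant always holds.  Per-gene bootstrap
seeds in `fit_matrix()` are derived from the master seed and the gene
position, which makes results byte-identical for any worker count.

## The dosage outlier test

Given a reference table of population `sd_g` values, `dot_sample()` tests
each gene of one sample against its population null
$\mathrm{BLN}(n = a + b,\ \mu = 0,\ \sigma = \mathrm{sd}_g)$ with the
two-sided p-value $p = \min(1, 2\min(\Pr(X \le a), \Pr(X \ge a)))$ (both
tails include the observed count).  Genes are tested when total coverage is
at least 10, a reference value exists, the gene is in the FDR universe
(typically protein-coding and lncRNA), and the gene is not on an exclusion
list; untested genes are kept with `tested = FALSE` as an audit trail.
Benjamini–Hochberg adjustment runs within the sample over tested genes only,
and outliers are calls with $q \le 0.05$ (configurable).

Because the support is discrete and the doubled tail includes the observed
point, the p-value is conservative: under a matched null with totals
log-uniform on $[30, 3000]$ and $\mathrm{sd}_g = 0.2$, the empirical CDF of
$10^5$ null p-values sits below the diagonal with a Kolmogorov distance of
about 0.05, concentrated near $p = 1$ (the acceptance script reports this as
`dot_null_ks_distance`); the fraction of null tests at $p \le 0.05$ is
about 0.044, so FDR control at the decision threshold errs on the safe
side.  Deep coverage does not remove this: the atom at $p = 1$ persists for
any discrete symmetric test that doubles an inclusive tail.

## Downstream screens

* **False-positive-prone genes** (`screen_fp_genes()`): a gene that is an
  outlier in many unrelated samples is more plausibly a model artifact
  (e.g. unmodelled mapping bias) than shared rare regulatory variation.
  Per gene, the cohort outlier rate $k/m$ gets an exact Clopper–Pearson
  interval (two-sided, level 0.95 by default — the flag's confidence level
  is exposed because only the 1% rate threshold is fixed by convention);
  genes are flagged when the lower bound exceeds 1%.  A two-sided exact
  binomial test against the threshold rate is reported for information but
  never drives the flag.
* **Rare-variant enrichment** (`build_pairs()`, `relative_risk()`,
  `enrichment_by_significance()`): tested (individual, gene) pairs —
  restricted by default to genes outlying in at least one individual — are
  joined to a precomputed rare-variant annotation table (variant calling,
  MAF filtering and VEP consequences happen upstream; absent records mean
  non-carrier).  The primary statistic is the risk ratio
  $\mathrm{rr} = \frac{a/(a+b)}{c/(c+d)}$ of carrying a rare variant given
  outlier status, with a Katz log-normal CI; the sampling odds ratio is
  emitted alongside since the two are often conflated in the literature.
  Zero cells take a Haldane–Anscombe $+0.5$ correction, recorded in the
  output row.
* **Population comparison** (`ci_overlap_similarity()`,
  `cross_population_dot()`): for each population pair, the fraction of
  common genes whose `sd_g` confidence intervals intersect (closed
  intervals — touching endpoints count as overlap, since the binary rule
  does not specify boundary behaviour); $D = 1 - S$ feeds average-linkage
  clustering, which is provided for visualization only.  The cross-
  population outlier matrix runs the dosage test for every (test cohort,
  reference) combination and reports the median per-sample outlier count
  plus its fold change against the ancestry-matched diagonal.

## The simulator, and what passing tests do not show

`simulate_population()` draws exactly from the generative model: per-gene
`sd_g` (fixed, recycled vector, or log-normal across genes), totals from a
log-uniform law on $[30, 3000]$ by default (spanning the eligibility
threshold through deep coverage; a negative-binomial option is provided),
then latent effects and binomial counts.  Outlier cells are planted by
replacing $\delta$ with $\pm\delta^*$ (random sign, as haplotype labels are
arbitrary) or forcing complete monoallelic expression, and
`simulate_variant_table()` draws per-class carrier flags at configurable
rates given planted-outlier status.  Everything is a deterministic function
of the config seed.

The simulator deliberately omits what the upstream pipeline handles:
reference-mapping bias, phasing errors, double-counted overlapping reads,
sample contamination, and any dependence between coverage and regulatory
variation.  Tests passing on these cohorts therefore establish statistical
correctness of the estimator and test under the model's own assumptions —
not robustness to the technical artifacts of real ASE data, which is why the
false-positive-prone screen exists as an empirical backstop.

## Study sizes used by the test suite

The packaged verification studies use: recovery of
$\mathrm{sd}_g \in \{0.05, 0.1, 0.2, 0.4\}$ from cohorts of 600 individuals
(50 replicate genes each, median relative error below 10%, bias below
0.02); bootstrap coverage with $B = 200$ over 200 replicates (nominal 95%,
accepted range 90–98%); calibration on $10^5$ matched-null tests; and power
above 90% on planted complete-monoallelic outliers at totals of at least
100 with reference $\mathrm{sd}_g = 0.2$.  `scripts/acceptance.R` re-runs
scaled versions of the same studies from a command-line seed.

## Known limitations

* The conservatism described above means null p-values are not exactly
  uniform; calibration is one-sided (never anti-conservative in the bulk).
* `sd_g` estimates at the search bounds (perfectly balanced or fully
  switching genes) are censored values, not interior optima; they are
  flagged and their bootstrap intervals inherit the censoring.
* The model assumes one latent effect per individual per gene; genuinely
  multimodal allelic states (imprinting, somatic events) inflate `sd_g`
  rather than being modelled.
* Estimates across tissues or populations are computed independently;
  no information is shared across cohorts.
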