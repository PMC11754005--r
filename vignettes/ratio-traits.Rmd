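---
title: "Simulating the distribution and heritability of ratio traits"
author: "ratioherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the distribution and heritability of ratio traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioherit)
```

## The problem

Ratio traits — feed efficiency, fat percentage, feed conversion ratio —
are quotients $p_0 = p_1 / p_2$ of two measured component traits. Breeders
routinely estimate genetic parameters for them and select on them, yet the
quotient of two normal variables is not normal, and the heritability a
midparent–offspring analysis assigns to the ratio is not a simple function
of the component heritabilities. This package simulates the process
end-to-end so the relationships can be mapped: component parameters in,
ratio-trait distribution and realised heritability out.

## The model

Component phenotypes are $p_{ij} = \mu_j + g_{ij} + e_{ij}$, $j = 1, 2$,
jointly normal. The additive-genetic covariance matrix is
$$\mathbf{G} = \begin{pmatrix} h_1^2 \sigma_{p1}^2 &
r_G h_1 h_2 \sigma_{p1}\sigma_{p2} \\
r_G h_1 h_2 \sigma_{p1}\sigma_{p2} & h_2^2 \sigma_{p2}^2 \end{pmatrix},$$
and the environmental matrix $\mathbf{E}$ has diagonal
$(1 - h_j^2)\sigma_{pj}^2$ and off-diagonal
$r_E \sqrt{(1-h_1^2)(1-h_2^2)}\,\sigma_{p1}\sigma_{p2}$. Their sum is the
phenotypic matrix $\mathbf{P}$, whose off-diagonal
$$\mathrm{cov}(p_1, p_2) = \left[r_G h_1 h_2 +
r_E\sqrt{(1-h_1^2)(1-h_2^2)}\right]\sigma_{p1}\sigma_{p2}$$
is the single quantity through which the correlations drive the ratio
trait's mean and variance. `componentCovariance()` implements it; with
unit variances and $r_G, r_E \in \{-0.5, 0, 0.5\}$,
$h^2 \in \{0.1, 0.3, 0.5\}$, it spans $[-0.5, 0.5]$. The formula is often
quoted for unit phenotypic variances; the $\sigma_{p1}\sigma_{p2}$ factor
is forced by dimensional analysis and reduces to the familiar form when
variances are 1.

Correlated draws come from lower Cholesky factors:
$g = \mathbf{L}_g z$, $e = \mathbf{L}_e z$ with independent standard
normal $z$. `buildCovStructure()` assembles $\mathbf{G}$, $\mathbf{E}$,
$\mathbf{P}$, $\mathbf{L}_g$, $\mathbf{L}_e$ with a closed-form 2x2
factorisation that tolerates singular but positive-semidefinite input
(e.g. $h^2 \in \{0, 1\}$), which a pivot-free generic Cholesky would
reject.

## The two-generation population

Founders (G0) are unrelated, unselected and non-inbred: `nSires` males
and `nSires * damsPerSire` females with $g$ and $e$ drawn as above.
Each sire is mated to `damsPerSire` dams — dams are shuffled under the
run's seed and then assigned in consecutive blocks, so there is no
selection, no polyandry and no inbreeding — and each dam produces
`offspringPerDam` offspring. Offspring breeding values follow the
Mendelian-sampling recursion
$$g_{i1} = \tfrac{1}{2}(g_{s1} + g_{d1}) + \sqrt{0.5}\, L_{g,11} z_{i1},
\qquad
g_{i2} = \tfrac{1}{2}(g_{s2} + g_{d2}) + \sqrt{0.5}\,(L_{g,21} z_{i1} +
L_{g,22} z_{i2}).$$

Two numerical choices here are deliberate:

* **The $\sqrt{0.5}$ scale.** Scaling the Cholesky factor by $\sqrt{0.5}$
  gives the within-family (Mendelian-sampling) covariance
  $\mathbf{G}/2$; added to the midparent variance $\mathbf{G}/2$ this
  keeps the offspring generation's genetic covariance equal to the
  founders' — the stationarity the midparent–offspring estimator relies
  on, and which the test suite asserts directly. A literal $0.5$ scale
  would shrink genetic variance by a quarter each generation and is not
  supported.
* **Offspring phenotypes include $\mu_j$.** G1 phenotypes are
  $p_j = \mu_j + g_j + (\mathbf{L}_e z)_j$, exactly as in G0. Omitting
  the mean would centre the denominator on zero and make the ratio
  explode; with it, G1 ratio means sit near $\mu_1/\mu_2$ as they must.

Ratios are computed as-is, with no truncation or rejection near a zero
denominator: truncation would bias the moments, and at the default
settings ($\mu_2 = 10$ with unit variance, i.e. $\mu_2 = 10\sigma$) a
non-positive denominator has probability below $10^{-23}$. A warning is
emitted if any $|p_2| < 10^{-6}|\mu_2|$.

`simulateIndependentRecords()` is the pedigree-free counterpart:
independent $p_1 \sim N(\mu_1, (CV_1\mu_1)^2)$,
$p_2 \sim N(\mu_2, (CV_2\mu_2)^2)$, used to map how the ratio's
distribution depends on the means and coefficients of variation alone.

## Estimating heritability

For each family (a sire–dam mating and its full sibs),
`estimateHeritability()` forms the midparent value
$m = (p_s + p_d)/2$ and the offspring value $o$, then
$$\hat\sigma_g^2 = 2\,\mathrm{cov}(m, o), \qquad
\hat\sigma_p^2 = 2\,\mathrm{var}(m), \qquad
\hat h^2 = \hat\sigma_g^2 / \hat\sigma_p^2 .$$
With unrelated parents $\mathrm{var}(m) = \sigma_p^2/2$ and
$\mathrm{cov}(m, o) = \sigma_g^2/2$, so both estimators are consistent.
For the ratio trait the parent values are the parents' own ratios
$p_1/p_2$ — not a ratio of midparent components. Three further choices:

* **Family means by default.** $o$ is the mean of the family's sibs.
  $\mathrm{cov}(m, \bar o)$ has the same expectation as a per-offspring
  pairing but less noise. `pairing = "per_offspring"` is available for
  sensitivity analysis; the two agree in expectation (tested), their
  replicate SDs differ slightly.
* **Divide-by-n moments.** All covariances/variances here (and in
  `momentSummary()`) are population-form. At the intended sample sizes
  ($10^4$–$10^6$ families) Bessel's correction is far below every
  tolerance in use, and one convention throughout keeps cross-checks
  exact.
* **No clamping.** $\hat h^2$ is reported raw; sampling can push it
  outside $[0, 1]$ and replicate averaging needs the unclamped value.

## Delta-method closed forms

Second-order Taylor expansion of $p_1/p_2$ around the means gives
$$E(p_0) \approx \frac{\mu_1}{\mu_2} - \frac{\mathrm{cov}(p_1,p_2)}{\mu_2^2}
+ \frac{\mu_1 \mathrm{var}(p_2)}{\mu_2^3}, \qquad
\mathrm{var}(p_0) \approx \frac{\mathrm{var}(p_1)}{\mu_2^2}
+ \frac{\mu_1^2\mathrm{var}(p_2)}{\mu_2^4}
- \frac{2\mu_1 \mathrm{cov}(p_1,p_2)}{\mu_2^3}.$$
At the default setting ($\mu = 10$, $\sigma_p^2 = 1$) these bound the
grid: $1.005 \le E(p_0) \le 1.015$ and $0.01 \le \mathrm{var}(p_0) \le
0.03$, attained where the component covariance is $\mp 0.5$. The
expansion is a small-CV approximation: it tracks simulated variances
well for $CV \le 0.10$ and degrades as the denominator's CV grows — the
simulated variance exceeds it because the ratio's heavy right tail is a
higher-order effect the expansion cannot see.

Applying the same expansion to the (unobservable) breeding value of the
ratio gives the `deltaHeritability()` approximation, a ratio of two
quadratic forms: the numerator in $\mathrm{var}(g_j)$,
$\mathrm{cov}(g_1, g_2)$ and the assumed breeding-value means
$E(g_1), E(g_2)$; the denominator the phenotypic delta variance.
Breeding values are relative quantities — only differences are
identifiable — so $E(g_1), E(g_2)$ are a location choice the caller
makes, defaulting to $\mu_1, \mu_2$, under which the approximation
returns $h^2$ exactly when the traits share a heritability and are
uncorrelated. The qualitative pattern this form predicts — $\hat h_0^2$
falling in $r_G$ and rising in $r_E$, to the point where the ratio can
out-inherit both components — is treated as a grid-checked property,
not a theorem: the monotonicity argument leans on the assumed
$E(g_1)/E(g_2)$ and the test suite verifies it by direct evaluation over
the study grid.

## Moment conventions

`momentSummary()` reports population-moment mean, variance, skewness and
*excess* kurtosis. Excess form makes the normal baseline testable as 0
and makes "positive kurtosis" mean what the heavy-tailed ratio
distributions show; no small-sample bias correction is applied (samples
are $10^4$ and up).

## The experiment grids and their scale

`runExperiment1()` crosses mean ratios with CV pairs for independent
records; `runExperiment2()` crosses $(h_1^2, h_2^2, r_G, r_E)$ for
two-generation populations, estimating the ratio trait's moments and
heritability per replicate and aggregating means and SDs per cell. The
default mean-ratio grid is $\{10/25, 10/20, 10/15, 10/10, 15/10, 20/10,
25/10\}$: seven ratios, with $10/20$ included as the natural midpoint
of the descending arm; the grid is configurable if a different set is
wanted. Variance is also reported
multiplied by 10 (`variance_x10`), the scale on which these results are
conventionally plotted.

The reference scale is 100,000 sires x 10 dams x 2 offspring
(2,000,000 offspring, 1,000,000 families) with 100 replicates per cell,
available via `fullScale = TRUE`. The package default is a desk-scale
profile — 2,000 sires (20,000 families, 40,000 offspring), 20 replicates
— chosen because the estimators are consistent, so only replicate noise
changes with scale: the acceptance tests verify that 20-replicate means
at 20,000 families reproduce full-scale cell means to $\pm 0.02$
(heritability) and $\pm 0.01$ (10x variance), in seconds per cell. The test suite also
checks the $1/\sqrt{n}$ SD scaling that justifies this argument.
Independent-record summaries default to $10^5$ records per replicate
against the reference $2 \times 10^6$, on the same reasoning.

Every replicate's RNG stream is derived from (base seed, cell index,
replicate index) through an integer mixing function, so cell results do
not depend on evaluation order and any run is bit-reproducible from its
configuration. Deviates are drawn as vectorised trait-wise columns
within a generation.

## What the generator does and does not emulate

It emulates: bivariate-normal component traits, additive inheritance
with Mendelian sampling, a balanced hierarchical mating design,
unrelated founders, and a single discrete generation step. It does not
emulate: selection, inbreeding accumulation, more than two generations,
unbalanced or overlapping families, dominance or epistasis, maternal
effects, or non-normal component traits. Passing tests therefore show
that the estimator and the closed forms behave as claimed *under the
model's own assumptions*; real feed-efficiency or percentage data
violate several of them (selection, non-normality of components,
unbalanced pedigrees), and the package makes no claim about estimator
behaviour there.

## Known limitations

* The delta-method forms are second-order and untrustworthy for
  $CV_2 \gtrsim 0.15$ or $\mu_2$ near zero.
* Heritability is estimated by midparent–offspring statistics only; no
  REML/animal-model or Bayesian machinery, and no standard error for a
  single replicate (uncertainty is the SD across replicates).
* True breeding values of the ratio trait itself are not defined by the
  model, so its "heritability" is specifically the midparent–offspring
  quantity above.

## A compact session

```{r example}
gp <- geneticParams(h2_1 = 0.1, h2_2 = 0.1, rG = -0.5, rE = 0.5)
componentCovariance(gp)
deltaMoments(gp)
pop <- simulatePopulation(gp, populationDesign(nSires = 500), seed = 1)
estimateHeritability(pop$g0, pop$g1, trait = "p0")
```
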