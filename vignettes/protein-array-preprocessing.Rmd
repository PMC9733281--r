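---
title: "Pre-processing single-channel protein microarrays with ProtArray"
author: "ProtArray maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-processing single-channel protein microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtArray)
```

# The problem

Functional protein microarrays immobilize hundreds of proteins on a slide,
probe them with a single fluorescently detected sample per array, and
report one median foreground and one median local-background intensity per
spot.  Before any biology can be read off these numbers, several layers of
technical structure must be removed: optical background, array-to-array
intensity distortions, unequal array quality, and replicate-spot
redundancy.  ProtArray implements a complete pre-processing and
differential-expression path for such data — spot filtering, background
correction, normalization, REML array-quality weights, replicate
consolidation, and empirical-Bayes moderated-t testing — together with a
synthetic array generator so that every stage can be exercised and
benchmarked without access to patient data.

The central container is `ProteinArraySet`, a `SummarizedExperiment` with
assays `fg` and `bg`, spot annotation as `rowData`, the sample targets as
`colData`, and a processing log in `metadata()`.

# The pipeline, stage by stage

## Spot filtering

For each array $j$ the noise threshold is
$T_j = \mathrm{median}(B_j) + 2\,\mathrm{sd}(B_j)$, computed over the
backgrounds of all spots of that array.  Foreground intensities below
$T_j$ are regarded as non-specific binding and set missing; the matrix
shape is preserved so downstream stages see an `NA`, not a dropped row.
The threshold uses all spots (not only non-empty ones): empty spots carry
exactly the background signal the threshold is trying to characterize.
Filtering precedes background correction, matching the recommended
pipeline order, and is idempotent.

## Background correction

Four methods are provided.  *None* leaves foregrounds untouched.
*Subtraction* computes `fg - bg`; spots whose background exceeds their
foreground become non-positive and are lost at the log2 step — the
hidden cost of this popular method.  *Moving minimum* first replaces each
spot's background by the minimum over its 3×3 within-block neighbourhood
(blocks are physically separate sub-arrays, so neighbourhoods never cross
block boundaries), making the subtraction robust to locally inflated
background estimates such as dust.

*Normexp* is the model-based method and the package's default.  The
background-subtracted intensity is modelled as a convolution
$X = B + S$ with $B \sim \mathcal{N}(\mu, \sigma^2)$ and
$S \sim \mathrm{Exp}(\text{mean } \alpha)$; the marginal density is

$$f(x) = \frac{1}{\alpha}
  \exp\!\left(\frac{\mu - x}{\alpha} + \frac{\sigma^2}{2\alpha^2}\right)
  \Phi\!\left(\frac{x - \mu - \sigma^2/\alpha}{\sigma}\right).$$

`normexpFit()` maximizes this likelihood exactly, under a
log-parametrization of $\sigma$ and $\alpha$, starting from moment-based
values ($\mu_0$ = 5th percentile of $x$; $\sigma_0$ = sd of the mirrored
lower tail; $\alpha_0 = \max(\bar{x} - \mu_0, \epsilon)$).  Numerically,
the log-likelihood is evaluated in a rearranged form,
$\log f = -\log\alpha - t^2/2 + h(a - t)$ with $t = (x-\mu)/\sigma$,
$a = \sigma/\alpha$ and $h(u) = u^2/2 + \log\Phi(-u)$: the naive form
cancels catastrophically when $\alpha \ll \sigma$ (the exponential
component vanishing), whereas the rearranged form tends exactly to the
normal log-density in that limit, with $h$ evaluated by its Mills
asymptotic series for large $u$.  The corrected intensity is the
posterior mean $E[S \mid X = x]$ — the mean of a normal truncated to the
positive half-line — so every corrected value is strictly positive and
strictly increasing in $x$.  An optional offset $k$ is added after
correction; `selectOffset()` picks $k$ over a grid (default 0, 5, …, 50)
by maximizing the empirical-Bayes prior degrees of freedom of the
downstream fit, the most variance-stable choice.  The default is $k = 0$.

## Normalization

*Scale* normalization works on the linear scale: each array is multiplied
by $f_j = g / \mathrm{median}_j$, $g$ the geometric mean of the array
medians.  *Quantile* normalization is the classic rank-mean algorithm
(reference built from complete rows; rows with missing values are
rank-interpolated; ties receive the mean of their tied reference values).
*Fast cyclic loess*, the default, normalizes each array against the
reference array — the probe-wise mean of all arrays — by subtracting a
robust local-linear (tricube, two robustness iterations) lowess fit of
$M_j = Y_j - \mathrm{ref}$ on the reference value, iterated three times
with the reference recomputed each pass; span defaults to 0.7.

A subtle but consequential choice is the abscissa of that regression.
Regressing $M_j$ on $(Y_j + \mathrm{ref})/2$ puts array $j$'s own noise
into the regressor; whenever replicate noise is comparable to the
between-probe spread, the smoother then explains the array's own
deviations and subtracting the fit strips array-specific signal almost
completely (in our simulations, per-array residual variance collapsed by
three orders of magnitude, destroying fold changes and any basis for
array-quality estimation).  ProtArray therefore regresses on the
reference value itself, the construction used by the established
single-channel implementations.

## Array-quality weights

Residual array-level quality variation is modelled as
$y_g = X\beta_g + \varepsilon_g$ with
$\mathrm{Var}(\varepsilon_{gj}) = \sigma_g^2 e^{\gamma_j}$, the
$\gamma_j$ constrained to sum to zero.  `fitArrayWeights()` estimates
$\gamma$ by Fisher scoring on the restricted (REML) log-likelihood
aggregated over probes, with $\sigma_g^2$ profiled out per probe: each
iteration fits every probe by weighted least squares at the current
weights $w = e^{-\gamma}$, and the squared standardized residuals minus
the hat-matrix leverages form the score, with expected information
$\tfrac12 Z^\top (M \circ M) Z$, $M = I - H$.  The update solves the
scoring system through an eigen-pseudoinverse, which leaves directions
with no information untouched — necessary because some designs genuinely
cannot identify all contrasts of the $\gamma_j$ (with two arrays per
group under a group-means design, the pair residual only informs the sum
of the pair's variance factors).  Convergence is declared at
$\max|\Delta\gamma| < 10^{-6}$; the sum-to-zero constraint makes the
weights multiply to one.  On small instances the scoring solution agrees
with a brute-force generic-optimizer maximization of the profiled REML
criterion to better than $10^{-3}$, which is the implementation's key
correctness oracle.  Weights may be used directly in the probe-wise fits
(the default), ignored ("equal"), or used to drop the lowest-weight
arrays (`dropLowestArrays()`, default two, ties broken by array order).

## Consolidation

`consolidate()` averages replicate spots per probe per array on the log2
scale (means are taken after normalization), drops the control and empty
categories by default, and reports per-cell replicate counts.  No
minimum-replicate rule is imposed — spots are discarded only by the 2-SD
filter — so users can apply their own count threshold downstream.

## Differential expression

Probe-wise weighted least squares under a group-means design with
explicit contrasts (`makeComparisons("B-A")`), then empirical-Bayes
moderation: with $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the
prior degrees of freedom solve
$\psi'(d_0/2) = \overline{(e - \bar e)^2}\,\tfrac{n}{n-1} -
\overline{\psi'(d_g/2)}$ by Newton inversion of the trigamma function
(initial value $0.5 + 1/x$, tolerance $10^{-8}$), handling varying $d_g$
from missing values exactly.  A non-positive right-hand side gives
$d_0 = \infty$, in which case the prior variance is the arithmetic mean
of the probe variances (the maximum-likelihood value when all true
variances coincide, and the only choice that keeps the all-equal case a
fixed point).  Posterior variances
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ give moderated
$t = \hat\beta / (u \tilde s_g)$ on $d_0 + d_g$ degrees of freedom
(normal reference when $d_0 = \infty$); at $d_0 = 0$ the ordinary t-test
is recovered exactly.  Benjamini–Hochberg adjustment uses the standard
step-up rule; the significance flag in `rankedTable()` uses the raw
p-value at `alpha` (default 0.05) with the adjusted p-value reported
alongside.

# The synthetic generator

`simDesign()` / `simulateArraySet()` emulate a 130-feature design: 123
proteins plus two negative and five positive controls printed in
triplicate, hybridized as four arrays in each of two conditions, with
background mean 100, background sd 15 and signal mean 200 fluorescence
units — the intensity scale on which the normexp recovery properties are
stated.  Each spot draws its background from
$\mathcal{N}(\mu_j, \sigma^2 v_j)$ and its signal from an exponential
with protein-specific mean; protein abundances are log-normal with sd 1
on the log2 scale (`abundanceLog2Sd`), giving the wide dynamic range seen
in MA plots.  Negative draws truncate at zero, as scanners report
non-negative medians.  Ground truth (per-protein means, DE labels,
variance factors) is returned alongside the data and never written into
fixture files, so tests cannot leak it through the pipeline.

Three generator choices deserve comment:

* **Recorded background is informative.** The spot's true background and
  its recorded local-background estimate share a common component
  (`bgShare`, default 0.8 of the variance); both marginals remain the
  stated normals.  Local background is, physically, a measurement of the
  spot's surroundings; were the two independent, subtracting the recorded
  background could only ever add noise and no correction method could
  help by construction.

* **Variance factors multiply the whole residual.** For arrays with
  $v_j \neq 1$ the signal is drawn as
  $\mu \cdot \mathrm{Gamma}(1/v_j, \text{scale } v_j)$ — mean $\mu$,
  variance $v_j \mu^2$, and exactly the stated exponential at $v_j = 1$.
  Inflating only the background draw would shift log-scale residual
  variance by one or two percent, invisible to any quality-weight
  estimator, because per-spot exponential signal noise (log2 sd ≈ 1.8,
  independent of the mean) dominates the log scale.

* **What the generator does not emulate.** Per-spot signal draws are
  independent exponentials, so replicate CVs sit near $1/\sqrt{3}$
  rather than the ~15% of careful real experiments; there are no spatial
  artefacts beyond the variance factors and no scanner saturation.  One
  consequence is worth knowing: on the log2 scale the background level in
  *uncorrected* data acts as a variance-stabilizing offset for this
  high-CV signal, so the residual-variance-versus-intensity comparison
  across correction methods ranks no-correction lowest on synthetic data
  — the opposite of what background-driven real arrays show.  Passing
  tests on this generator therefore demonstrate the correctness of each
  algorithm and the qualitative behaviour of filtering and normalization,
  not the real-data superiority ranking of correction methods.

Control-probe CVs used to compare normalization methods are computed
across arrays (CV per control of the per-array replicate means, linear
scale): any per-array monotone correction moves all replicate spots of a
control together, so within-array CVs are invariant to normalization by
construction and only the cross-array version can distinguish methods.

# Worked example

```{r example}
sim <- simulateArraySet(simDesign(deFraction = 0.1, deLog2FC = 1.5),
    seed = 7)
fl <- filterSpots(sim$arrays)
corr <- bgCorrectNormexp(fl$arrays)
norm <- normalizeSet(corr, "cyclicloess")
weights <- fitArrayWeights(norm$Y, conditionDesign(arrayTargets(norm$arrays)))
cons <- consolidate(norm$Y, probeInfo(norm$arrays))
stats <- moderateStats(
    fitProbewise(cons$E, conditionDesign(arrayTargets(norm$arrays)),
        weightValues(weights)),
    makeComparisons(arrayTargets(norm$arrays), "B-A"))
head(rankedTable(stats), 5)
```

The same path, from files on disk, is one call:

```{r pipeline, eval = FALSE}
fx <- writeFixtureGPRs(sim$arrays, "fixtures")
res <- runPipeline(runConfig(
    inputs = fx$gpr, targets = fx$targets,
    probeAnnotations = fx$annotations,
    comparisons = "B-A", outDir = "out"))
```

# Numerical choices and limitations

* Optimizer: Nelder–Mead followed by a BFGS polish, objective tolerance
  $10^{-8}$; convergence is reported and the best iterate returned on
  non-convergence.
* The quantile reference needs at least two complete rows; a column with
  no finite values is an error.  The loess smoother requires at least ten
  complete points per array.
* Scoring iterations cap at 200; strong, barely-identified
  heteroscedasticity can use over a hundred (the expected-information
  step is linearly convergent far from equilibrium).
* Tie rules are deterministic everywhere: lowest wavelength for intensity
  column auto-detection, first occurrence for the offset grid, array
  order for weight-based dropping.
* Problem sizes in the test-suite simulations (hundreds of probes, 8
  arrays, 10–20 seeds for averaged properties; $10^5$ spots for
  maximum-likelihood recovery) were chosen so each property is measured
  well inside its tolerance.
* Estimated array weights are treated as known in the downstream fits —
  the standard practice — which makes weighted moderated statistics
  slightly anticonservative when the number of probes is small; with few
  hundred probes the raw-p null flagging rate runs one to three points
  above nominal for the weighted analysis.  The weights' benefit shows in
  detection power; an FDR advantage over equal weighting should not be
  expected at this probe count.
* Differential fractions concentrated in one direction violate the
  balance assumption all global normalizations share; at 10% one-sided
  DE the normalization absorbs part of the shift and null probes acquire
  a small opposite bias.
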