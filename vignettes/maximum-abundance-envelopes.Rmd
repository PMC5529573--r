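---
title: "Maximum-abundance envelope models and phylogenetic diversity for plankton surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-abundance envelope models and phylogenetic diversity for plankton surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxenvelope)
library(dplyr)
```

## Scope and model

This package analyses amplicon-survey OTU tables collected along
environmental gradients — the setting of basin-scale marine plankton studies
where temperature, salinity and depth structure both who is present
(composition) and how abundant they are (structure). Its centrepiece is the
maximum-abundance envelope species distribution model: rather than
regressing a taxon's mean abundance on a gradient, it models the *upper
quantile* of abundance within gradient categories, an estimate of the
taxon's potential abundance where other limiting factors happen not to bind.

For one taxon and one gradient $x$:

1. The $n$ observations are split into $k = \max(3, \lceil n/20 \rceil)$
   equal-frequency categories, contiguous in sorted $x$, sizes differing by
   at most one. The constraints — no category above 20 observations, at
   least three categories, roughly equal occupancy — pin down $k$; the
   equal-frequency construction is our choice, made because quantile bins
   keep the per-category quantile estimates comparably precise across a
   non-uniformly sampled gradient.
2. Each category $j$ contributes an envelope point: the 95th percentile
   $q_j$ of abundance (type-7 linear interpolation between order
   statistics), the category median $\tilde x_j$, and its size $m_j$.
3. A GLM with log link and Poisson likelihood is fitted to the points,
   $\log \mathbb{E}[q] = \sum_{i=0}^{d} \beta_i x^i$, with prior weights
   $m_j$, for candidate degrees $d = 1 \dots 3$.
4. Degree selection applies two rules jointly, scanning upward against the
   best model admitted so far (starting from the intercept-only baseline): a
   degree is admitted only if it lowers the AIC *and* raises the proportion
   of deviance explained, $1 - D_d / D_0$, by more than one percentage
   point. Among admitted models the one explaining the most deviance is
   reported; if nothing is admitted the fit is degree 0. The scan does not
   stop at the first rejection: a symmetric thermal niche is invisible to a
   linear term yet perfectly captured by a quadratic, so the quadratic must
   be reachable even when the linear step fails.
5. The fitted response is evaluated on a 512-point grid over the observed
   range and classified: `flat` if the relative variation of the fitted mean
   is below 1%; `monotone_up`/`monotone_down` if the grid derivative keeps
   one sign; `unimodal` if there is exactly one abundance maximum and it is
   interior; `other` for two or more maxima (counting boundary maxima).
   With the cubic cap, genuine bimodality surfaces as `other`.

### Assumptions

* Abundances are non-negative counts (or count-like averages) whose envelope
  scales multiplicatively along the gradient, making the log link natural.
* Gradient variables act one at a time; no joint response surfaces are
  fitted.
* Categories are exchangeable apart from their size, which enters only as a
  regression weight.

## Numerical choices

* **Non-integer envelopes.** A 95th percentile of counts is generally not an
  integer, so candidate models are maximised as continuous quasi-Poisson
  likelihoods (`stats::glm`, `quasipoisson(link = "log")`), for which the
  deviance is well-defined on non-negative reals. The AIC is computed from
  the gamma-function extension of the Poisson log-likelihood,
  $\ell = \sum_j m_j (q_j \log \mu_j - \mu_j - \log\Gamma(q_j + 1))$, which
  coincides with the ordinary Poisson AIC at integer responses. Rounding the
  envelopes instead would bias small envelopes downward.
* **Conditioning.** Polynomials are fitted on centred-and-scaled $x$ and the
  coefficients mapped back to natural units by binomial expansion; peak
  locations therefore shift exactly with a shift of the gradient origin
  (verified by test).
* **Representative x.** The category median, not the midpoint of the
  category's range: extreme quantile bins have ill-defined outer bounds, and
  the median is stable under the long tails typical of station coverage.
  The midpoint is available as `envelope_config(representative = "midpoint")`.
* **The "1%" gain rule** is read as one percentage point of deviance
  explained (absolute, not relative); `envelope_config(deviance_gain = )`
  exposes it.
* **Quantile rule.** Type 7 (the default linear-interpolation rule), pinned
  by oracle tests so the choice is load-bearing, not incidental.

## Diversity metrics

Faith's PD is the total branch length of the minimal rooted subtree spanning
a sample's OTUs. Unweighted UniFrac is unique branch length over observed
branch length; weighted UniFrac is
$\sum_b \ell_b \lvert A_b - B_b \rvert$ with $A_b, B_b$ the fractions of
each community's reads descending from branch $b$. Two decisions:

* Branch fractions use **relative abundances**, so the metric is
  depth-invariant and well-defined on unrarefied tables too.
* The weighted variant is **normalised by default** (divided by the
  abundance-weighted maximum $\sum_i d_i (A_i + B_i)$ over tips, $d_i$ the
  root-to-tip distance), mapping into $[0,1]$ so weighted and unweighted
  values are comparable; `normalized = FALSE` gives the raw form.
* OTUs present in a table but absent from the tree abort with an error:
  silently dropping them would change every denominator.

Rarefaction follows the multiple-subsampling workflow: filter samples below
the target depth, draw `n_replicates` independent rarefied tables (replicate
$r$ seeded as `seed + r`), compute each metric per replicate, and average at
the metric level. Averaging tables instead would create non-integer counts
and understate sampling variance. For envelope input the replicate-averaged
table, rounded to integers, is used; this "rarefied counts" unit is recorded
in every fit, and a relative-abundance mode is provided, since survey
practice varies and raw, rarefied and proportional abundances give
envelope fits on different scales.

## Environmental statistics

* **Environmental distance** is Euclidean on z-scored variables; z-scoring
  removes the units problem when mixing °C, PSU and µmol/L.
* **Mantel tests** correlate upper triangles (Pearson by default, Spearman
  as an option — survey literature is often ambiguous between "Pearson" and
  "rank" methods, so both are exposed) and permute one matrix's rows and
  columns jointly, with the one-tailed $+1$-corrected p-value
  $(1 + \#\{r^* \ge r\})/(1 + N)$. Defaults: 999 permutations. Exact
  enumeration of all permutations is available up to 7 samples.
* **Mixed layer depth** is the shallowest depth where density exceeds the
  density at a 10 m reference by 0.125 kg m⁻³ (a standard criterion; both
  knobs are arguments since conventions differ), linearly interpolated
  between levels, with the cast's maximum depth returned when the threshold
  is never crossed. Density comes from the one-atmosphere EOS-80 polynomial
  (Millero & Poisson coefficients), implemented in-package and verified
  against the published check values; a precomputed `density` column is
  honoured when present. The full TEOS-10 thermodynamic treatment is out of
  scope at these accuracies.
* **Scenario classification** crosses turbulence (deep mixed layer = high)
  with nutrient concentration into the four regime quadrants familiar from
  plankton community theory, named by the region-by-season cells of a
  two-region, two-season survey design (North/South × Spring/Fall). Numeric
  thresholds default to median splits; the classifier is a formalisation of
  a conceptual quadrant diagram, not an inference procedure.

## What the synthetic generator emulates — and what it does not

`simulate_community()` provides ground truth: uniform environmental draws
over declared ranges (22–34 °C, 36.5–40.5 PSU, 0–200 m by default, the
photic-zone envelope of a warm semi-enclosed basin), nutrients increasing
with depth under lognormal noise, a random rooted binary phylogeny, and
counts drawn Poisson (or negative binomial) around parameterised response
curves: flat, log-linear monotone, Gaussian-niche unimodal, and bimodal
curves built as the exponential of two Gaussian bumps on the log-mean —
deliberately outside the cubic family, so tests can probe how the
degree-limited fitter approximates two thermal optima (it reports `other`).
A sparsity knob thins background taxa with per-taxon Beta-distributed
dropout, reproducing the empirical pattern that most OTUs occupy few
samples while a few are cosmopolitan.

Not emulated: spatial autocorrelation among stations, compositional
(closure) effects of sequencing, PCR/primer bias, chimeras, taxonomy. A
passing recovery test therefore shows the estimator works when its
assumptions hold at survey-like sizes — not that field data meet those
assumptions.

## Test problem sizes

The suite exercises: envelope recovery at 500 samples per taxon (25
categories) over 50 seeds for degree-1 and degree-2 truths; diversity
metrics against brute-force branch-enumeration oracles on 50 random trees of
up to 16 leaves plus 100 metric-axiom triples; Mantel null calibration with
500 simulations of 15-sample matrices at 99 permutations; 10 000-replicate
hypergeometric checks of rarefaction; and a packaged ≤60-sample pipeline run
twice for byte-determinism. These sizes were chosen so each property is
measured with comfortable statistical margin at desk scale.

## Known limitations

* With few categories (3–8, i.e. up to ~160 samples) the envelope has few
  points and the AIC-plus-gain rule admits cubic terms more often than the
  truth warrants; flat background taxa can surface as `other` with modest
  deviance explained. Users modelling small surveys should read
  `deviance_explained` alongside `shape`, or lower `max_per_bin` only when
  observations are plentiful.
* The selection rule is data-adaptive, so reported deviance explained is
  optimistic in the usual post-selection sense; no correction is attempted.
* Weighted UniFrac's normalisation makes values comparable across sample
  pairs but not across trees with different depth structure.
* The scenario classifier assumes one mixed-layer depth and one nutrient
  level per group of samples; within-group heterogeneity is averaged away.
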