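---
title: "Distinguishing selection from history in geographic clines: methods and design"
author: "clineCoCo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing selection from history in geographic clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clineCoCo)
```

# The problem

A one-dimensional cline — a monotone geographic gradient in allele
frequency — is the textbook signature of diversifying selection across an
environmental gradient. It is also exactly what neutral secondary contact
produces: two populations diverge in allopatry, meet again, and their
diffusing allele-frequency step looks like a cline at every locus that
happened to differentiate during isolation. `clineCoCo` implements a
genome-scan workflow for transect data (many loci scored in many
populations along, e.g., a coastline) that asks whether any individual
locus stands out against the *genomic* distribution of clines, together
with a neutral simulator that shows how much clinality pure history
generates.

The package has four analysis layers:

1. **Per-locus cline detection.** Each locus is reduced to a single focal
   allele and its frequency is modeled against latitude with a
   *twice-broken-stick* model — two flat plateaus joined by one linear
   segment.
2. **Genomic Co-Co analysis.** Every clinal locus becomes a point at
   (cline midpoint, log |slope|); loci in the low-density tail of a 2-D
   kernel density over these points have unusual cline *location*
   (coincidence) or *shape* (concordance).
3. **FST-outlier scan.** The classic island-model coalescent null for
   (heterozygosity, FST) pairs, with conditional quantile envelopes.
4. **Secondary-contact simulation.** A split–isolate–expand stepping-stone
   demography whose simulated loci are pushed through the very same
   screens.

# The twice-broken-stick model

For a locus with focal-allele counts $x_i$ out of $n_i$ gene copies at
sites with latitudes $\ell_i$, the model is

$$
p(\ell) = \begin{cases}
p_S & \ell \le b_S\\
p_S + (p_N - p_S)\dfrac{\ell - b_S}{b_N - b_S} & b_S < \ell < b_N\\
p_N & \ell \ge b_N
\end{cases}
$$

with four parameters: the two break coordinates $(b_S, p_S)$ and
$(b_N, p_N)$. The cline midpoint is $(b_S + b_N)/2$ and the slope
$(p_N - p_S)/(b_N - b_S)$, in frequency change per degree latitude.

**Likelihood.** We maximize the binomial log-likelihood
$\sum_i [x_i \log \hat p(\ell_i) + (n_i - x_i)\log(1 - \hat p(\ell_i))]$
with predictions clamped to $[10^{-6}, 1 - 10^{-6}]$. A binomial objective
respects the heteroscedasticity of frequency estimates across unequal
sample sizes; a Gaussian least-squares objective
(`likelihood = "gaussian"`) is provided for comparison.

**Optimization.** The likelihood surface is multimodal in the breaks, so
the fit is multi-start: all ordered pairs of nine sampled-latitude
quantiles seed the breaks, plateau frequencies are initialized from the
pooled frequencies outside each break pair, and the best three starts are
refined by Nelder–Mead on transformed parameters (logits for frequencies;
a center/width transform that enforces $b_S < b_N$). Breaks may lie one
degree beyond the sampled range so edge clines are representable; break
separation is bounded below at 0.01 degrees — fits at that bound are
flagged `"step-like"` and their bounded slope is used downstream. Ties
(within $10^{-8}$ log-likelihood) go to the smaller |slope|.

Two properties are guaranteed by construction rather than hoped for:

* *Nesting*: the horizontal model ($p_S = p_N$) is always evaluated as a
  candidate, so the broken-stick log-likelihood never falls below the
  intercept-only log-likelihood.
* *Reflection symmetry*: data are internally reflected so the pooled
  focal frequency is $\le 0.5$ before fitting. Swapping the focal allele
  for its complement therefore gives bitwise-identical log-likelihood,
  midpoint and |slope| (the slope sign flips), rather than
  optimizer-noise-identical.

**The clinality test.** Clinality is a likelihood-ratio test of the
broken-stick fit against the horizontal fit, $2\Delta\ell$ referred to
$\chi^2_3$ (4 vs 1 parameters). The break locations are not identified
under the null, so $\chi^2_3$ is a nominal reference, not an exact
distribution; we verified empirically that the realized type-I error at
$\alpha = 0.05$ on flat binomial data stays in the 0.01–0.12 band. A
four-parameter logistic cline (`fitLogistic()`) is included purely as a
cross-check: on well-behaved steep clines its midpoint agrees with the
broken-stick midpoint to within half a degree, and on flat data it fails
or degenerates — which is why the broken stick, not the logistic, is the
screening workhorse.

# Screening and what "clinal" means

A locus enters the Co-Co analysis when it passes **two** criteria at
$\alpha = 0.05$: (1) a significant Mantel test of per-locus pairwise
Weir–Cockerham FST against latitudinal distance (isolation by distance),
and (2) a significant broken-stick LRT. The published clinal percentages
this package is checked against (44% of SNPs, 47% of all loci) count the
loci passing this two-criterion screen, and `percentClinal()` therefore
defaults to it (`criterion = "screen"`). This matters enormously for
simulated data: under secondary contact most segregating loci are rare,
geographically clustered variants that pass the LRT (a local step fits
them well) but show no genome-wide isolation-by-distance signal; the LRT
alone calls ~80% of neutral loci clinal, the two-criterion screen ~25–50%
depending on dispersal. `criterion = "lrt"` is exposed for null
calibration, where the nominal $\alpha$ only has meaning for a single
test: under panmixia the LRT-only clinal fraction is ~5%, while the
intersection of two tests is necessarily smaller.

Mantel details (the sources are silent on these): Pearson correlation of
lower triangles, one-sided for positive association, 999 permutations,
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$; geographic distance
is absolute latitude difference, since the transect is effectively
one-dimensional.

The marker-class summary (`clinalContingency()`) tabulates clinal status
by marker class, collapses to SNP vs non-SNP, and applies a two-sided
Fisher exact test (sidedness was our choice; the exact hypergeometric
enumeration is cross-checked in the test suite).

# Co-Co densities and envelopes

Clinal loci are embedded at (midpoint, $\log|$slope$|$); the natural log
is used (the base only shifts the axis) because slope magnitudes are
strongly right-skewed. A Gaussian-kernel density with a full
$2 \times 2$ bandwidth matrix is estimated over these points. The default
bandwidth selector minimizes the least-squares cross-validation criterion
over (log sd, log sd, atanh correlation); when the CV surface degenerates
(it can, for tight clusters) the normal-scale reference bandwidth
$\hat\Sigma\, n^{-1/3}$ is used instead and recorded — this is also the
`"plugin"` option. A full plug-in selector in the Sheather–Jones sense is
not implemented; for the unimodal, roughly elliptical clouds this
analysis produces, the normal-scale fallback is adequate and the CV
selector is the default.

Highest-density regions are computed on a discrete grid (default
$256^2$, padded three bandwidths beyond the data): the level for mass $m$
is the density at which the grid cells above it first accumulate mass
$m$. Envelopes at 75/95/99% are drawn; **outliers** are loci whose
(bilinearly interpolated) density falls below the 95% level, with the
99% level also reported. Grid-sum mass is renormalized to 1 (the padding
keeps the correction below $10^{-3}$), and HDR nesting is exact by
construction. One correction matters for calibration: when flagging the
same points the density was estimated from, each point's own kernel is
removed first (leave-one-out). Without it an isolated locus sits on its
own density bump — at $n = 150$ the realized outlier rate drops to ~1%
instead of the nominal 5%; with it, homogeneous Gaussian point sets are
flagged at $5\% \pm 3$ points.

# The FST-outlier null

The null is a finite-island structured coalescent: 100 demes, 11 sampled
with 20 diploids each (40 gene copies, matching the genotype-synthesis
convention), infinite-alleles mutation dropped on the genealogy. The
scaled mutation rate is drawn log-uniformly per replicate
(`thetaRange`, default 0.01–10 on the total-population scale) so the null
spans the heterozygosity axis; the conditional envelope given He is
insensitive to this distribution, which is the point of conditioning.
The migration rate is **calibrated by bisection** until the pilot mean
Weir–Cockerham FST hits the target (0.33) within 0.01, using common
random numbers so the pilot mean is monotone in the rate — the mean of
per-locus theta under infinite alleles sits well below the
coalescent-time FST of the model, which is why fdist-style methods
calibrate by simulation rather than by Wright's closed form (we verified
the engine itself against the exact structured-coalescent expectation
$F = 1/(1 + Md/(d-1))$ using the pooled multi-locus estimator).

Envelopes are conditional quantiles (0.5/2.5/50/97.5/99.5%) in 25
equal-count He bins, smoothed by a 3-bin running median — binned
quantiles rather than kernel quantile regression, matching the stepped
look of classic fdist output. Empirical loci are classified by their
pooled-sample He; the empirical p-value is the fraction of null pairs in
the locus's bin with FST at least as large.

# The secondary-contact simulator

Backwards in time (defaults in parentheses): a chain of 40 stepping-stone
demes of diploid size 2,500 exchanging $4Nm \in \{0.4, 4, 40\}$ with
their neighbors since the expansion (10,000 generations ago); two
isolated relicts of size 50,000 from then back to the split (100,000
generations ago); a single ancestor of size 100,000 before that. Total
effective size is identical in every epoch. Each locus is an independent
genealogy of 40 gene copies per deme with **one segregating site placed
uniformly on the genealogy** (the fixed-$S{=}1$ convention for biallelic
SNP loci; uniform placement makes every locus segregate in the total
sample, so the rejection path for monomorphic draws exists only as a
guard). The spatial coordinate is the deme index, so slopes are per-deme.
300 loci per replicate and 10 replicates per condition are the
publication-scale defaults (the sources do not state their counts); tests
and the acceptance script scale these down and say so.

The coalescent engine is a single compiled Gillespie simulation over
piecewise demographies (epochs with per-deme sizes, island or
stepping-stone migration, and deme relabeling at epoch boundaries),
driven by R's RNG for reproducibility. It was cross-validated against
msprime under the identical demography: derived-allele frequency spectra
and downstream clinal fractions agree within Monte-Carlo error.

# What the synthetic generator does and does not emulate

`generateClineDataset()` produces transects of 10–80 sites (default 20,
denser near 40°N via a symmetric Beta design, mimicking the empirical
sampling), a chosen fraction of clinal loci with logistic (default) or
hard-stepped shape — logistic because a smooth sigmoid is the harder case
for a piecewise-linear fitter — midpoints near 40°N, frequency contrasts
$\Delta p$, flat loci at uniform(0.05, 0.95), and binomial counts at 40
gene copies per site (20 diploids, the same assumption used when
published frequency-only tables are converted to counts). Ground truth is
returned alongside. What it does **not** emulate: linkage between loci,
ascertainment bias of marker discovery, spatial autocorrelation of
sampling noise, or overdispersion beyond binomial — so a green recovery
test establishes that the estimators work on data matching their
assumptions, not that those assumptions hold for any particular empirical
compilation.

# Numerical choices and degenerate inputs

* Counts are canonical; frequency input is converted by
  largest-remainder rounding at an assumed 40 copies/site
  (configurable) so counts sum exactly.
* Missing data are $n_{i\ell} = 0$ rows, never NaN frequencies.
* Loci with fewer than 5 assayed sites or fewer than 3 distinct
  latitudes are excluded from fitting with a logged reason.
* All-monomorphic loci have undefined FST (flagged NaN); negative
  pairwise FST estimates are clamped to 0 only where a distance matrix
  is required.
* GenePop I/O accepts 2- and 3-digit allele codes and always writes
  3-digit; the genotype round trip is identical on codes.
* Every stochastic routine takes a seed; screening derives per-locus
  Mantel seeds from one master seed so results are reproducible
  locus-by-locus.

# Known limitations

* The $\chi^2_3$ reference for the clinality LRT is nominal (break
  non-regularity); empirical type-I is verified but not exact.
* The two-criterion screen's power depends on the per-site sample sizes;
  with the 40-copies-per-deme convention the simulated clinal fraction
  at the lowest dispersal condition (4Nm = 0.4) comes out around 25%,
  several points below the published 36%, while the middle and high
  dispersal conditions reproduce the published 41% and 50% within
  tolerance. The sources do not state their simulated sample size; we
  did not adjust ours to chase the published number.
* The Co-Co analysis flags outliers but does not classify them as
  steeper/shallower — read that off the plot.
* No linkage disequilibrium, no selection in simulations, diploid
  autosomal loci only (mtDNA is handled as haploid counts in the same
  structure).
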