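---
title: "Methods: skeletal volumetrics and body-proportion macroevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeletal volumetrics and body-proportion macroevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`skelevol` implements a complete comparative pipeline for studying how
tetrapod body proportions scale with overall size and diverge across
ecological groups. Its stages are: (1) convex-hull volumetrics of skeletal
body segments and assembly of the whole-body convex hull volume (WBCHV);
(2) time-scaling of cladograms from fossil occurrence data; (3) phylogenetic
regression of log segment metrics on log WBCHV; (4) Mk-model inference and
stochastic character mapping of discrete ecological regimes; (5) multi-regime
Brownian-motion (BM) and Ornstein-Uhlenbeck (OU) models of continuous traits
fitted per stochastic map and summarised across maps; and (6)
Brownian-motion ancestral state reconstruction. A synthetic-data module
generates inputs with the exact statistical structure each stage assumes, so
the whole pipeline is testable against known ground truth without any
external data.

# Body size and shape metrics

Each body segment (skull, neck, trunk, tail and eight limb segments) is
summarised by the volume of the convex hull of its skeletal point cloud, and
WBCHV is the sum of the available segment hull volumes. Hull volumes are
computed by an in-package 3D quickhull and the facet-tetrahedron signed sum;
the computation is exact up to floating point for polyhedral input, invariant
to interior points and rigid motion, and scales as $s^3$ under isotropic
scaling by $s$. Linear measures (GA, FL, SL, MtL, PL, HL, FaL, McL, ML) are
inputs rather than being derived from meshes, because they are defined
between approximate joint centres and require anatomical judgement; meshes
feed only hull volumes.

Size-normalised shape metrics divide linear measures by WBCHV$^{1/3}$ and
volumetric measures by WBCHV. We use the exact exponent $1/3$ (isometric
length scaling of a volume), so a globally rescaled animal has identical
normalised shape; reported conventions of "0.33" are treated as a rounded
print of the same exponent. For incomplete fossils, WBCHV is computed over
the available segments and a `complete` flag is propagated so downstream
analyses can filter; whether to include partial skeletons is left to the
analyst rather than silently imputed. Group tightness of normalised metrics
is summarised by the coefficient of variation with the $n-1$ standard
deviation; CoV is undefined (an error) for non-positive group means.

# Time-scaling with the 'equal' rule

Cladograms are dated from first/last appearance data (FAD/LAD, Ma). Node
ages are initialised to the oldest descendant FAD, tip ages to their own
FADs, and the root age to the oldest FAD plus a configurable
`root_extension` (default 10 Myr; the choice only stretches the root stem).
Zero-length branches are removed by the 'equal' rule: the nearest ancestral
branch with positive duration donates its span, which is divided equally
among itself and the maximal chain of consecutive zero-duration branches
below it. When several zero chains hang below one ancestor the procedure
iterates, resolving one chain at a time (each pass strictly raises node
ages, so it terminates); this matches the common published behaviour of the
method, whose tie-breaking details are not standardised. The output is
guaranteed to have strictly positive durations, which the test suite checks
on 1000 random occurrence sets.

# Phylogenetic regression

All regressions are on base-10 logarithms of positive metrics. PGLS assumes
residual covariance $\sigma^2 V(\lambda)$ where $V(\lambda)$ is the BM
covariance (shared root-to-MRCA path lengths) with off-diagonals multiplied
by Pagel's $\lambda$. $\lambda$ is profile-maximised on $[0,1]$ by bounded
scalar optimisation (tolerance $10^{-6}$), with endpoint candidates always
evaluated; flat likelihoods resolve toward $\lambda = 1$. The log-likelihood
is the full multivariate-normal likelihood with $\sigma^2$ profiled out, and
the AICc parameter count is coefficients + residual variance + $\lambda$
(when estimated), so model ranks are internally consistent. Confidence
intervals use the $t$ distribution with $n - p$ degrees of freedom and the
unbiased residual-variance estimate, which reproduces classical OLS
inference exactly in the star-tree limit.

Quadratic fits centre the predictor before squaring to tame collinearity and
report coefficients back-transformed to the uncentred scale (the covariance
matrix is transformed accordingly). Isometry is classified against the
conventional expectations (1/3 for length vs volume, 1 for volume vs volume)
by whether the expectation falls inside the 95% CI of the slope.

Size-binned slopes split taxa at thresholds nominally given in kg; the
measured size variable is WBCHV, and the conversion assumes mass =
density_coefficient x WBCHV with a default of 1000 kg m^-3 (a water-like
whole-body density with WBCHV in m^3). The coefficient is configurable
because the mapping between mass thresholds and a skeletal hull volume is
not uniquely defined. Each bin is fitted independently on the pruned tree
and the between-bin slope contrast is a normal-theory Wald comparison of
independent fits.

The phylogenetic ANCOVA fits a single PGLS with per-group intercepts and
per-group slopes under one shared ML $\lambda$, and reports all pairwise
Wald contrasts on slopes and intercepts with Holm-adjusted p-values
alongside the raw ones (Holm is applied within one quantity across the
pairwise family; the choice of family-wise procedure is a package decision).
This interaction-contrast construction is validated against classical
ANCOVA in the star-tree limit; it is a documented stand-in for
published phylANCOVA variants whose exact statistic construction differs in
details that are not material on the star-tree oracle.

# Discrete regimes: Mk models and stochastic maps

Ecological characters evolve by a continuous-time Markov (Mk) model with
rate matrix constraints ER (one rate), SYM (symmetric) or ARD (all rates
different). Likelihoods use Felsenstein pruning with per-branch
$P(t) = e^{Qt}$ computed from an eigendecomposition of $Q$ (with a
scaling-and-squaring fallback for defective matrices) and per-node scaling
against underflow. The root is treated by conditional-likelihood weighting
(FitzJohn-style) by default — the ML root state is also reported — with flat
and stationary policies available; the default was chosen because it is also
the natural distribution from which to sample root states when simulating
histories. Rates are optimised on the log scale; because the likelihood
flattens onto a saturation plateau as $q \to \infty$, the optimiser is
seeded from a coarse log-grid on a shared rate, which in testing reliably
avoids the plateau. Model choice among ER/SYM/ARD uses AICc with
$k = 1,\ s(s-1)/2,\ s(s-1)$ and $n$ = number of tips, ties resolving to
fewer parameters.

Stochastic maps are sampled exactly: node states are drawn from their joint
conditional distribution (backward pruning, forward sampling), then each
branch history is sampled conditional on its endpoint states by
uniformization. Uniformization guarantees termination on long branches with
unlikely transitions, unlike rejection sampling. Whether each map's root
state is drawn from the joint conditional posterior (default) or afresh from
the root policy is exposed as an option, since published workflows are
ambiguous on this point. Every returned painting tiles its branch lengths
and terminates tip branches in the observed states, which the tests assert
on every map.

# Multi-regime trait models

Seven models of continuous trait evolution are fitted on a painted tree:
BM1, OU1, BMS, OUM, OUMV, OUMA and OUMVA, freeing $\sigma^2$, $\alpha$ and
$\theta$ per regime in the standard combinations. The likelihood uses the
exact first two moments of an OU process with piecewise-constant parameters
along each lineage: per epoch of duration $d$ in regime $r$,

$$m \leftarrow m e^{-\alpha_r d} + \theta_r (1 - e^{-\alpha_r d}), \qquad
  V \leftarrow V e^{-2\alpha_r d} + \frac{\sigma^2_r (1 - e^{-2\alpha_r d})}{2\alpha_r},$$

with the BM limit $\sigma^2_r d$ at $\alpha_r = 0$; tip covariance is the
MRCA variance discounted by $e^{-\int \alpha}$ along both descending paths.
Fossil tips keep their true, non-contemporaneous path lengths — no
ultrametricisation. The same recursion, run with regime-indicator weights,
expresses the tip mean as a linear function of $(\theta_1, \ldots,
\theta_R, y_0)$ and the tip covariance as a linear combination of
per-regime components; the optima and the overall $\sigma^2$ scale are
therefore profiled out analytically by GLS, leaving only the $\alpha$s and
$\sigma^2$ ratios (at most $2R - 1$ values) to bounded numerical
optimisation in log space. This profiling is why the fits are fast enough to
repeat over a map ensemble.

The root value $y_0$ is tied to the root regime's $\theta$ for OU models
(the stationary-start analogue) and free for BM models; a free-root
alternative is exposed as a switch. Parameter counts are BM1 2, OU1 3, BMS
$R+1$, OUM $R+2$, OUMV/OUMA $2R+1$, OUMVA $3R$. $\alpha$ is bounded above by
50 / tree depth to avoid numerically flat likelihoods, and bound hits,
vanishing $\sigma^2$ and optimiser codes are reported as convergence flags.
Optimisation uses one deterministic moment-based start plus 4 seeded random
starts by default. Traits enter on the log10 scale
for sizes and lengths; normalised torso volume enters on its normalised
scale, since it is already dimensionless and approximately symmetric — the
log transform is left to the analyst if desired.

Because each stochastic map has its own likelihood surface, raw parameter
estimates are never averaged across maps. The ensemble summary computes
within-map pairwise differences per parameter and regime pair and counts the
maps in which each qualitative pattern (a focal regime exceeding all others)
holds, retaining the per-map estimates for export.

# Ancestral states

Continuous traits are reconstructed at internal nodes under single-rate BM:
the root estimate is the GLS phylogenetic mean, internal nodes the Gaussian
conditional expectations given the tips, with $\sigma^2$ estimated by REML
so node variances are unbiased by the mean fit (the variance of the
estimated mean is propagated into node variances). These estimates coincide
with the weighted squared-change solution, which the tests verify against a
direct linear solve on small trees. Along-branch interpolation for gradient
figures is linear in time and export-only.

# The synthetic-data generator

The generator is first-class, tested code. It produces: Yule trees by
forward simulation (expected depth $\sum_{k=2}^{n-1} 1/(k\lambda) +
1/(n\lambda)$, which the tests check by Monte Carlo), with a configurable
fraction of tips truncated to positive ages to emulate fossils — the default
preset matches the 92/410 extinct/total ratio typical of a large mixed
extant-fossil skeletal dataset; forward CTMC regimes returning the true
painting; traits by exact per-epoch OU transitions (the agreement of their
sample moments with the analytic moments is the cornerstone
cross-validation of the regime-model mathematics, asserted at 2000
replicates); log-log allometries with Brownian residuals so PGLS is the
correctly specified estimator; and meshes of known hull volume (cuboid and
polygonal frustum exact; ellipsoid by Fibonacci-lattice tessellation with
relative tolerance 1e-3 at the default 10,000 surface points). The default
study preset uses 200 tips, 5 diet states, ER rates tuned to about 15
expected transitions, and $\alpha \cdot$depth in $[1, 10]$, chosen so model
selection is informative at desk scale. All generators are bit-reproducible
under a seed, and seeds are scoped per call so adding one generator call
does not perturb others.

What the generator does *not* emulate: measurement error in the hull
volumes, correlated evolution between segments beyond the shared size
signal, diversification linked to the regimes (state-dependent speciation),
or non-Markovian ecological change. Passing tests therefore demonstrate the
correctness of the estimators under their assumed models, not robustness to
violations of those assumptions on real data.

# Validation problem sizes

The statistical validation studies run at desk scale, chosen so the whole
suite completes comfortably on one CPU while leaving the checks
statistically meaningful: OUM optimum recovery uses 50 replicates of
200-tip trees (unit birth rate, so tree depth is about 5 and
$\alpha \cdot$depth about 10); ER rate recovery 50 replicates at 300 tips;
PGLS confidence-interval coverage 200 replicates at 200 tips; the
seven-model selection studies 50 replicates at 120 tips; stochastic-map
calibration 10,000 maps on a two-tip tree against the enumerated posterior;
and dating safety 1000 random occurrence sets. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch under a
user-supplied seed.

# Known limitations

Hull volumes assume the segment point clouds are already segmented and
cleaned; no mesh repair is attempted. The PGLS engine fits a single
$\lambda$ per model (no per-group $\lambda$ in the ANCOVA). Regime models
are univariate; correlated multi-trait OU is out of scope. Mk models have no
hidden rate classes. Ten-state locomotor regimes are supported by the
machinery, but regime-model fitting is intended for the five-state diet
character — with ten states and small group sizes the models are typically
unidentifiable, mirroring practical experience with this model family.
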