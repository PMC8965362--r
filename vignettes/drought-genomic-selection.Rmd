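---
title: "Models and methods: genomic selection for drought response in polycross trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genomic selection for drought response in polycross trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtgs)
```

`droughtgs` analyses drought response in replicated polycross progeny
trials of forest trees: from daily climate and tree-ring series to
drought-response phenotypes, genomic/pedigree relationship matrices,
REML genetic evaluation, cross-validated prediction and multi-trait
selection gains. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The trial and its synthetic emulation

The design the package targets is a polycross progeny test: each of
`n_mothers` (default 38) maternal families is sired by an equal-volume
pollen mix shared across `n_fathers` (default 19) fathers, so paternity
is initially unknown but recoverable from markers; the package assumes a
recovered, per-offspring pedigree. Offspring (default 8 per
family per site) are planted on `n_sites` (default 2) sites in
`n_blocks` (default 4) randomized complete blocks, genotyped at
`n_snps` biallelic SNPs (default 500, configurable up to the ~4,000 of a
typical conifer array), measured for growth and wood traits, and cored
for ring series.

`simulate_trial()` generates such a trial with known ground truth:

* **Founders** drawn under Hardy–Weinberg at per-SNP allele frequencies
  uniform on `maf_range` (default 0.05–0.5); offspring receive one
  Mendelian gamete per parent per locus.
* **Traits** follow a marker-effect architecture: per-SNP effects are
  multivariate normal across traits with the configured genetic
  correlation matrix, and each trait's effects are rescaled so the
  realized additive variance among offspring equals `h2_true` exactly on
  a standardized within-site scale (phenotypic variance 1). Phenotype =
  site mean + block effect (SD `block_sd_frac` = 0.1) + true breeding
  value + residual, mapped to the measurement scale by per-site means and
  SDs. Defaults are realistic for white spruce at a boreal and a milder,
  more productive site (height ~784/1100 cm, DBH ~126/160 mm, wood
  density ~383/369 kg/m³, acoustic velocity ~3.0/3.2 km/s) with
  heritabilities 0.41–0.46. A marker-effect (rather than pedigree-MVN)
  model is used deliberately so that GBLUP has true Mendelian-sampling
  information to exploit relative to ABLUP.
* **Drought**: each tree carries a heritable drought-year growth
  multiplier (site means 0.94 and 0.88 — a 6% and a 12% mean growth
  loss — total SD 0.18, h² = 0.25, genetic correlation 0.25 with height,
  clamped to [0.05, 1.5]). Ring series follow a saturating juvenile BAI
  trend (time constant 6 years) scaled by a height-linked vigor term,
  lognormal site-year effects (SD 0.15) and tree-year noise (SD 0.1); in
  the site's drought year expected BAI is multiplied by the tree's
  multiplier. Widths are recovered from BAI assuming growth from the
  pith, so the width↔BAI round trip is exact.
* **Climate**: sinusoidal seasonal temperature with Gaussian noise and
  Bernoulli–Gamma precipitation. In drought years, June–August rain is
  scaled by 0.4. The dry window starts in June rather than July because
  the Drought Code integrates deep-layer moisture with a multi-week lag:
  a July-onset deficit barely moves the July monthly mean DC, whereas
  observed drought summers in such trials show above-normal DC across
  much of the season. July–August rain is still at least 40% below
  baseline in expectation.

All generators are pure functions of (configuration, seed); sub-streams
are derived from the master seed by fixed offsets, so adding a consumer
never reshuffles existing draws.

**What the generator does not emulate** — and what passing tests
therefore cannot certify about real data: linkage disequilibrium and
marker–QTL distance (every SNP is causal), genotype×environment
interaction (sites differ only in means and drought year, mirroring a
separate-site analysis), dominance and epistasis, selection and drift
across generations, measurement error in ring dating, and missing
genotypes (available as an input case but not generated). Results on
real trials will additionally depend on all of these.

One property worth knowing when validating against truth: with 57
founders, realized correlations between true breeding values across the
trial are *founder-limited* — their effective dimension is roughly twice
the founder count, so single-trial realized genetic correlations scatter
around the target with an SD near 0.1 regardless of `n_snps`. The
generator is unbiased (verified on founder-rich designs), but a single
57-founder replicate can realize a correlation 0.2 away from its target.
This mirrors real small breeding populations.

## Drought Code and anomalies

`drought_code_step()` implements the standard daily DC recursion:
potential evapotranspiration V = max(0, 0.36·(T + 2.8) + L_f(month))
with T floored at −2.8 °C and the northern-hemisphere monthly day-length
factors L_f ∈ {−1.6, …, 6.4}; when rain exceeds 2.8 mm the moisture
equivalent Q = 800·exp(−DC/400) is recharged by 3.937·(0.83·P − 1.27)
before DC gains 0.5·V. `monthly_dc()` iterates the recursion within a
fire season (April 1 – October 31 by default), restarting each spring
from `overwinter_reset` (default 15; the overwintering rule of the
original spatial-simulation software is undocumented, so a fixed spring
reset is used and exposed as a parameter), and averages daily DC per
calendar month. `scale_monthly()` centers and scales each calendar month
on a baseline period (e.g. 1985–2015); a month with zero baseline SD is
an error naming the month, not silently propagated.

Only the DC is implemented; the Soil Moisture Index that is sometimes
reported alongside it correlates strongly with DC and adds no decision
value here. Other FWI components are out of scope.

## Tree-ring processing

BAI conversion assumes coring to the pith (`r0 = 0`, configurable).
Detrending divides each BAI series by a cubic smoothing spline whose
frequency response equals `f` (default 0.7) at a stated wavelength. When
only `f` is given, the wavelength defaults to 0.67 × series length — the
dendrochronological convention. The Cook–Peters parameterization maps
(f, wavelength) to the classical smoothing parameter
p = 1/(((cos(2π/λ)+2)(1−f))/(12f(cos(2π/λ)−1)²) + 1), which is handed to
`stats::smooth.spline` as λ = (1−p)/p corrected for its internal
rescaling of the x-axis (division by range³). The implementation is
verified empirically: a sinusoid at the design wavelength is attenuated
to 0.70 ± 0.01 of its amplitude. A fitted curve that touches zero is an
error suggesting a stiffer spline, never a silent negative index.

Dating quality control correlates each detrended series with the
arithmetic mean of all others over their overlap and flags series below
0.2 (or with fewer than 5 overlapping years). Flagging is deliberate:
the manual shift-and-recheck step used in practice is not faithfully
automatable, so the package reports rather than repairs. Chronologies
are per-year Tukey biweight robust means (c = 9, median start, iterated
to convergence) with sample depth recorded; `min_frac = 0.5` reproduces
the common "at least half the trees present" subsetting. Whether
detrending should use the subset or the full series per tree is
ambiguous in practice; the package detrends whatever years are passed
in, and the pipeline passes full series, applying the depth filter at
the chronology stage only.

Climate–growth correlations are Pearson correlations between the
chronology and a monthly climate index for May–August of the current and
preceding year, with a seeded year-resampling bootstrap (default 1,000
resamples, 95% percentile interval); a correlation is significant when
its interval excludes zero.

## Lloret components

For drought year d with `pre` = 2 and `post` = 3: resistance =
BAI(d)/mean(BAI(d−2..d−1)), recovery = mean(BAI(d+1..d+3))/BAI(d),
resilience = post/pre means, relative resilience = resilience −
resistance. Two identities are exact by construction and tested to
1e−12: resistance × recovery = resilience, and relative resilience =
resilience − resistance. Components are computed on raw BAI by default
(a detrended-index variant is available via `value_col` plumbing for
sensitivity analysis). When the post window is unusable — a truncated
series, or a stand thinning right after the drought
(`post_valid = FALSE`) — only resistance is returned, and downstream
stages (evaluation, gains) automatically restrict that site to
resistance. Per-tree failures in `batch_components()` are collected into
a rejects table rather than aborting the batch.

## Relationship matrices

`build_A()` uses the tabular method with inbreeding
(a₍ᵢᵢ₎ = 1 + a(mᵢ,fᵢ)/2; a₍ᵢⱼ₎ = (a(j,mᵢ)+a(j,fᵢ))/2), after a
topological sort so any input ordering works; unknown parents are
unrelated non-inbred founders, and cycles are reported. The inverse is
obtained by Cholesky inversion — on these pedigree sizes (hundreds) the
numerical route is exact to far beyond the 1e−8 product-test contract,
and the test suite checks it against a brute-force recursive coancestry
oracle. `build_G()` is VanRaden method 1 with allele frequencies
estimated from the genotyped sample itself (the observed-data
convention), per-SNP mean imputation of missing dosages, and exclusion
of monomorphic/low-MAF SNPs (count reported). Because a marker-based G
on n > rank data is singular, `blend_K()` forms (1−w)G + wI with
w = 0.01 by default before anything needs an inverse; positive
definiteness is verified by factorization and failure advises a larger
w. F = diag(K) − 1 for either matrix.

## The animal model and REML

The univariate model is y = Xβ + Za + e with a ~ N(0, σ²ₐK),
e ~ N(0, σ²ₑI); fixed effects are an intercept plus block (any
one-sided formula is accepted; numeric blocks are treated as
categorical). Internally the likelihood is evaluated in the eigenbasis
of the phenotyped submatrix ZKZ′, where V is diagonal, so each REML
iteration costs O(n·p²) after one eigendecomposition. Updates are
average-information steps; when an AI step leaves the parameter space or
decreases the restricted likelihood, the step is first retried projected
onto the boundary (variance floor 1e−8 × phenotypic variance) and
otherwise replaced by an EM step, which cannot leave the space.
Convergence is a relative log-likelihood change below 1e−7 (maximum 200
iterations); the trajectory is retained and non-convergence is a warning
carrying the last change. Heritability h² = σ²ₐ/(σ²ₐ+σ²ₑ) takes a
delta-method SE from the inverse AI matrix. The test of σ²ₐ = 0 uses the
50:50 χ²₀:χ²₁ boundary mixture (measured size ≈ 5% at the nominal 5% over
400 null replicates). BLUPs and their prediction SEs come from the
mixed-model equations over *all* individuals in K — so unphenotyped
trees are predicted through relationships, which is exactly what
cross-validation needs; a cheap point-EBV route
(â = σ²ₐ K Z′ P y) avoids the full coefficient-matrix inverse when SEs
are not required. Theoretical accuracy is
rᵢ = √(1 − SEᵢ²/((1+Fᵢ)σ²ₐ)), clamped to [0, 1] with clamps counted. The
formula for predictive accuracy is PACC = PA/√h²; both PA and the h²
used are surfaced so the alternative normalization PA/h² can be formed
by the caller if desired.

The bivariate model stacks two traits with shared K, parameterized as
per-trait variances plus correlations (r_a, r_e), optimized
unconstrained on log-variances and atanh-correlations via `nlminb`
started from the univariate fits. V is block-diagonal in the rotated
basis (2×2 per observation), so likelihood evaluations are O(n).
Standard errors come from the numerical Hessian on the natural scale;
the phenotypic correlation is assembled from components,
r_p = (r_a·√(σ²ₐ₁σ²ₐ₂) + r_e·√(σ²ₑ₁σ²ₑ₂)) / √(σ²ₚ₁σ²ₚ₂), with a
delta-method SE. Significance uses likelihood-ratio tests against
r_a = 0 (1 df) and r_a = r_e = 0 (2 df). A fit driven to |r| ≈ 1 is
flagged `boundary` rather than reported as an interior estimate. Trees
lacking either trait are dropped (complete-case); the two sites are
never pooled and no G×E term is fitted.

## Cross-validation

`make_folds()` deals each family's shuffled members round-robin over a
shuffled fold order, so within-family fold counts differ by at most one.
`cross_validate()` removes the test fold's phenotypes, refits on the
training trees (variance components re-estimated per fold by default;
`reestimate = FALSE` fixes them at the full-data estimates), predicts
the held-out trees through K, and reports PA per fold with mean ± SD
over the default 10 folds × 10 repeats. PACC divides mean PA by √h² of
a reference fit — conventionally the GBLUP h², which the pipeline uses
for both methods. Failed fold fits are recorded and excluded rather than
silently dropped.

## Selection gains

Single-trait gain is 100 × mean(EBV of the top ⌈p·n⌉ trees by EBV) /
phenotypic mean, with p = 0.05 by default; a zero phenotypic mean is an
error advising absolute gains (relevant to relative resilience, whose
mean is near zero and whose percentage gains are therefore inflated).
The selection index SI = Σ wᵢ·EBVᵢ uses weights in [0, 1] summing to 1;
scenarios S1–S5 put weight 1 on height; 0.8/0.2 on height with
resistance or resilience; and 0.6/0.2/0.2 adding wood density. Because
raw-scale EBVs make weights unit-dependent, EBVs are standardized to
unit variance before weighting by default; `standardize = FALSE`
reproduces the literal raw-scale index, and both are labeled. Ties break
deterministically: descending score, then ascending tree id. Gains are
always reported per trait as % of that trait's site phenotypic mean.

## Pipeline

`run_pipeline()` chains every stage under one configuration and master
seed and writes CSV report tables (trait summaries with CV%;
heritabilities with SEs, additive-variance p-values and mean theoretical
accuracies; bivariate correlations; CV summaries; S1–S5 and single-trait
gains; the family-level between-site rank correlation of resistance)
plus a provenance manifest into `run_<confighash>/`, where the hash
covers the analysis-relevant configuration. Reruns with the same
configuration are byte-identical. A stage failure halts with the stage
named, preserving partial outputs. The default configuration analyses a
two-site trial with thinning at site 2 (resistance only there) and
completes in about a minute on one CPU.

## Problem sizes used in the checks

The test suite validates parameter recovery at the trial's own scale:
single-site trials of 608 offspring for h² recovery (20 replicates per
level at h² ∈ {0.16, 0.25, 0.46}) and genetic-correlation recovery
(20 replicates at r_a = 0.6), 400 pure-noise replicates for the size of
the boundary-corrected LRT, full 10×10 cross-validation for fold
mechanics, and a 1,216-offspring single-site trial for the
selection-index trade-off checks. Small-n REML fits (n ≤ 60) are checked
against an independent dense-matrix grid-search oracle, and the pedigree
A against a recursive coancestry oracle.

## Known limitations

* No single-step (H-matrix) blending of pedigree and genomic
  information; A and G are used separately.
* No multi-site models with type-B genetic correlations; sites are
  analysed separately by design.
* The REML machinery is dense; it is comfortable to a few thousand
  individuals but not built for national-scale evaluations.
* The drought year is an input (supported by the scaled-DC table), not
  detected automatically.
* Bivariate fits near |r_a| = 1 are flagged rather than constrained
  away; interpret boundary fits with care.
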