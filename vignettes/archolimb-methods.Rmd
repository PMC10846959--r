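---
title: "Models and methods behind archolimb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind archolimb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(archolimb)
```

`archolimb` studies locomotor evolution in early archosauromorph reptiles
(Pseudosuchia, non-dinosaurian Avemetatarsalia, Dinosauria, and earlier
diverging archosauromorphs) from limb-bone shape and limb proportions.
This vignette is the package's own account of the models, the tunable
parameters, and the numerical and design choices, at the level of detail
a user would need to trust or criticise a result.

## 1. Shape analysis

### Landmark scheme

Every bone outline carries 47 two-dimensional points: 3 fixed anatomical
landmarks (the proximal head centre and the anterior and posterior distal
condyles) and three ordered semi-landmark curves of 18, 18 and 8 points
(anterior margin, posterior margin, distal cap).  Semi-landmark positions
along an outline are arbitrary, so they are allowed to slide during
superimposition.  Digitisation orientation must be consistent across
specimens: reflections are deliberately disallowed in the rotation fit
because lateral-view bones have handedness, so a mirrored specimen is a
data error, not something the software should silently absorb.

### Generalized Procrustes analysis

`gpa_align()` removes position and size (`center_and_scale()`: centroid at
the origin, centroid size one) and fits proper rotations by SVD.  The
iteration has two phases:

1. plain GPA — superimpose on the consensus, recompute the consensus,
   repeat until the consensus moves by less than `tol` (default `1e-8`);
2. sliding — up to `max_slide_rounds` (default 5) alternations of chord
   min-d² semi-landmark sliding against the converged consensus with
   re-superimposition.

Sliding is scheduled *after* plain convergence for a concrete reason: if
semi-landmarks slide toward an early consensus (which is seeded from one
input configuration), the fixed point depends on input order.  With the
two-phase schedule, permuting the inputs changes the result by less than
`1e-8`, which is one of the package's tested invariants.

Chord min-d² sliding displaces each semi-landmark only along its local
chord (the direction between its two curve neighbours; curve endpoints use
their single adjacent chord) by the closed-form projection that minimises
its squared distance to the consensus point.  The projection can only
decrease the distance, so sliding is monotone — also tested, against a
201-step brute-force line search per point.  Relative-warp weighting
(the α parameter of some relative-warp implementations) is not replicated;
the ordination is the plain α = 0 case.

A final canonical rotation (consensus landmark 1 → 2 direction along +x)
makes outputs reproducible across platforms and input orders.

### Ordination

`shape_pca()` is an eigen-decomposition of the specimen covariance of the
flattened aligned coordinates (n − 1 denominator).  Axis signs follow the
rule "largest-magnitude loading positive".  Scores are isometric to the
aligned shapes: Euclidean distances between score vectors equal distances
between aligned configurations, to `1e-8`.  Group morphospace occupation
is summarised by convex hull areas (`hull_area()`); fewer than three or
collinear points give area zero with a warning flag rather than an error,
because sparse groups are common in fossil data.

## 2. Disparity through time

Species are assigned to every time bin their stratigraphic range
(FAD–LAD, in Ma) overlaps.  The overlap is strict on both edges, with bins
half-open on the younger boundary, so a range that only touches a bin's
older boundary does not enter it.  Range overlap (rather than midpoint
assignment) keeps every species usable and is the common choice in
disparity-through-time studies.  Bins with fewer than `min_n = 2` species
merge into their younger neighbour (the youngest bin, if sparse, merges
older); merging toward the present is a deterministic, documented
tie-break for a rule whose direction is genuinely open.

Disparity is the sum of variances (SoV) over ordination axes — all axes
by default, configurable — with a percentile interval from 2000 plain
bootstrap replicates (resampling rows at the original n; no rarefaction).
Group differences use a permutational MANOVA on Euclidean distances over
all axes, with `p = (1 + #[F* ≥ F]) / (n_perm + 1)` (9999 permutations by
default) and Bonferroni-adjusted pairwise tests.  An exhaustive variant
(`npmanova_exhaustive()`) enumerates all labelings for small samples and
is the oracle in the tests.

## 3. Locomotor indices and the phylogenetic ANCOVA

Quadrupedality = (humerus + radius) / (femur + tibia); cursoriality =
metatarsal III / femur.  Both are unitless ratios of maximum element
lengths, undefined (NA, never zero) when an element is missing, and
invariant to isometric scaling of a specimen.  Flying and fully aquatic
taxa are excluded before any locomotor analysis.  Where several specimens
represent a species, the largest (by femur length, falling back to the
longest shared element) is kept and missing elements are scaled up
isometrically from a smaller specimen via a shared element.  Body size is
log10 femur length.

`pgls_ancova()` fits cursoriality ~ group + body size by generalized
least squares with a Pagel's λ correlation structure: off-diagonal
phylogenetic covariances multiplied by λ ∈ [0, 1].  No group × size
interaction is included.  λ is estimated by restricted maximum likelihood
on a 1001-point grid followed by local polishing — the grid guards
against the multimodal profiles that small fossil samples produce.  The
implementation diagonalises the scaled covariance once, so each λ
evaluation is O(n·p) and the 1001-point profile is cheap.  With λ = 0 on
an ultrametric tree, or on a star phylogeny, the fit reduces to ordinary
least squares (tested to 1e-8 / 1e-6).

## 4. Fossil-tree time-scaling

`mbl_timescale()` places tips at their FADs and each internal node
`mbl` (default 0.1 Myr) older than its oldest child — the minimal
rootward shift giving every branch at least the floor duration.

`cal3_timescale()` is the probabilistic method.  Tip observation ages are
drawn uniformly within each tip's FAD–LAD range.  Moving tipward-to-root,
each node is placed a random *gap* older than its oldest dated child; the
gap is the waiting time until a clade would first leave observable
evidence under a birth–death–sampling process with branching λ,
extinction μ and fossil-sampling ψ (all per lineage Myr).  The package
uses an exponential gap with hazard

  ρ = ψ + λ·(1 − p₀),   p₀ = (λ + μ + ψ − √((λ + μ + ψ)² − 4λμ)) / (2λ),

i.e. the lineage is either sampled directly (ψ) or branches into a
daughter clade that is ever sampled (λ·(1 − p₀), with p₀ the no-sampled-
descendant probability).  The density is discretised at 0.001 Myr steps
and truncated at `max_gap` (50 Myr).  This density is a deliberate,
documented approximation: rather than claiming numeric identity with any
reference implementation, the package validates it by simulation
calibration — on trees from the forward birth–death–sampling simulator
with matched rates, 95% central intervals of drawn root ages cover the
true root age in ≥ 80% of replicates (measured ≈ 93% at 8 tips, 200
replicates).  Ancestor–descendant collapsing is never performed.

Sampling rates, when not supplied, are drawn uniformly from
0.018–0.18 per lineage Myr, the span of published estimates for Devonian
tetrapods and Mesozoic dinosaurs; branching and extinction default to a
user multiplier times the sampling rate, because the literature derivation
of those rates from sampling is not reproduced here.  Zero-length
branches — which the probabilistic method can produce — get 0.0001 Myr
(`fix_zlb()`); on dated trees the fix keeps tip ages anchored and pushes
parents rootward, cascading where necessary.

Polytomies are resolved uniformly over labeled rooted binary topologies
by sequential random edge insertion (a 4-way polytomy hits each of its 15
resolutions uniformly; χ² test over 3000 draws in the suite).

## 5. Variable-rates Brownian motion

The trait model is Brownian motion with branch variance
σ² × duration × r, where each branch either evolves at the background
rate (r = 1) or carries a scalar r > 0.  The likelihood is the restricted
(independent-contrasts) likelihood computed by Felsenstein pruning; it
equals full-matrix restricted GLS, which the tests verify to 1e-8 on all
random trees up to 10 tips.

A reversible-jump MCMC (C++ core, driven by R's RNG for exact seed
reproducibility) samples:

* `log σ²` — random walk, log-uniform prior on [1e-6, 1e6];
* per-branch activation — birth/death toggles with the scalar proposed
  from its prior (so proposal and prior densities cancel), activation
  prior Bernoulli(π = 0.05) per branch — a sparsity prior, since the
  analysis asks for a few exceptional branches, not a free rate per
  branch;
* active scalars — log random walk within the log-uniform prior on
  [10⁻³, 10³].

Desk-scale defaults are 2×10⁶ iterations, thinning 200, 20% burn-in;
production-scale settings are arguments, not code changes.  Effective
sample sizes for σ² and the log-likelihood are reported (ESS > 200 is the
convergence yardstick) but not enforced.

The *modal scalar* of a branch is the histogram mode (50 bins in log
space) of its posterior scalars, with the point mass at r = 1 (samples
where the branch is unscaled) winning whenever it outnumbers every bin of
the active samples — so an unscaled branch reports exactly 1.  The
*scaling frequency* is the fraction of retained samples in which the
branch carries a scalar.  Positive phenotypic selection is called on a
branch only when the modal scalar exceeds 2 (magnitude) and the scaling
frequency exceeds 0.95 (certainty) in *every* tree of the set — the
all-trees criterion guards against conclusions that hinge on one
time-scaling draw.

### What single-branch scalars can and cannot detect

A scalar on one branch enters exactly one independent contrast, so the
data carry a single χ²₁-distributed piece of evidence about it.  For a
×10 shift the evidence statistic is ≈ 10·χ²₁, whose median (≈ 4.5) is
routinely matched by the maximum of the ~50 null χ²₁ draws on the other
branches of a 30-tip tree.  Two consequences, both visible in the
acceptance report and deliberately not papered over:

* ranking: the planted branch uniquely tops the modal scalars in well
  under half of replicates, whatever the priors;
* detection: posterior scaling frequencies above 0.95 for a single ×10
  branch are rare, so the selection detector has high specificity (the
  homogeneous null flags essentially nothing) but low single-branch
  sensitivity.

Sustained or clade-wide rate shifts (which affect many branches) are the
regime in which this machinery has power; clade-level scalars are out of
scope here.

### Marginal likelihoods and Bayes factors

`stepping_stone_logml()` runs power posteriors at powers placed on
Beta(0.4, 1) quantiles and combines them with the stepping-stone
estimator in log space.  Desk-scale default: 50 stones × 2000 iterations
(the production 1000 × 100 000 is reachable through the arguments).  The
estimator is validated on a conjugate-normal toy against the closed-form
marginal (within 0.1; typically within 0.03).  Evidence grades use
log BF = 2 × Δ(log marginal likelihood), graded positive / strong / very
strong at 2 / 5 / 10.

Ancestral cursoriality states are maximum-likelihood GLS reconstructions
(`ancestral_states()`, cross-checked against an independent
implementation), on a strict consensus tree whose branch lengths are the
across-tree means of duration × posterior-mean scalar — so rate-inflated
branches are stretched and absorb more apparent change.  The regression
variant (`vr_regression()`) adds a flat-prior slope of cursoriality on
log10 body size (geometric mean √(femur × tibia) by default; femur +
tibia selectable, since both readings of the published proxy are
defensible) with residuals carrying the variable-rates structure.

## 6. The synthetic-data generator

The generator supplies every input with known ground truth.

* **Outlines** (`make_bone_outline()`): a parametric template (two
  epiphyses joined by a shaft) deformed by three interpretable axes —
  signed shaft curvature, epiphysis width, and a proximo-anterior crest
  bump — plus isotropic jitter.  Increasing crest prominence strictly
  increases the area between the anterior curve and the shaft chord;
  negating curvature mirrors the outline.  These give PCA axes a known
  meaning, without copying any real specimen.
* **Measurement tables** (`make_limb_records()`): element lengths are
  back-solved from sampled index values (per-group means, sd 0.1) and
  lognormal femur lengths (median 300 mm, log-sd 0.5), so planted group
  means are recovered in expectation (tested at n = 200, tolerance 0.03).
* **Fossil trees** (`simulate_fossil_tree()`): forward Gillespie
  birth–death conditioned on the number of sampled tips, with Poisson(ψ)
  fossil occurrences along terminal branches; FAD/LAD are the first/last
  occurrences, and true divergence times are returned.  Default bundle
  rates (λ = 0.08, μ = 0.04, ψ = 0.12 lmy⁻¹) give mid-Triassic-like tree
  shapes with usable fossil ranges at a few dozen tips.
* **Traits**: log-cursoriality evolves by BM (σ² = 0.002 per Myr from a
  root of log 0.5) with planted fourfold shifts on two branches by
  default; working on the log scale keeps the back-solved metatarsal III
  lengths positive.

What the generator does *not* emulate: taphonomic correlations between
body size and preservation, measurement error in the literature data,
allometric shape change, and topological uncertainty.  Green tests on
synthetic data therefore validate the *machinery* (estimators recover
known truth under the stated model), not the paleobiological conclusions
one would draw from real measurements.

## 7. Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen to make every
stochastic check stable under a fixed seed while staying interactive:
8-specimen ordinations; 200-replicate bootstrap-coverage and
cal3-calibration experiments (100 draws per replicate at 8 tips);
500-replicate NPMANOVA type-I simulation at 199 permutations; 20-replicate
MCMC experiments at 30 tips and 2×10⁶ iterations; 200-replicate PGLS
recovery at n = 100.  All stochastic stages take explicit seeds, and every
generator is a pure function of (parameters, seed).

## 8. Known limitations

* 2D landmarks only; no image digitisation or deformation-grid display.
* The cal3-style gap density is an approximation validated by
  calibration, not an exact waiting-time law for serially sampled clades.
* Branch-level scalars only; clade-level rate shifts and the
  Ornithoscelida-versus-standard topology comparison are data questions,
  not package features — any tree set can be supplied.
* The homogeneous-vs-variable Bayes factor at desk scale has Monte Carlo
  noise of order ±1–2 log-BF units; grade boundaries are exact, but
  borderline gradings need production-scale stones.
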