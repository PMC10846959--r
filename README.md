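# archolimb

Limb-bone morphometrics, disparity and locomotor evolution of early
archosauromorphs.

Early archosauromorphs — crocodile-line Pseudosuchia, bird-line
Avemetatarsalia (including the first dinosaurs) and their earlier-diverging
relatives — radiated between the Permian and the Early Jurassic.  Whether
dinosaurs out-competed pseudosuchians, and whether locomotion had anything
to do with it, is usually asked with four kinds of evidence: limb-bone
*shape* (geometric morphometrics), shape *disparity* through time, limb
*proportions* (locomotor indices), and *rates* of trait evolution on dated
phylogenies.  `archolimb` implements that entire workflow as one tested R
package, together with a synthetic-data module that generates every input
with known ground truth, so each estimator can be validated by
parameter-recovery rather than by trust.

## What is implemented

* **Geometric morphometrics** — 47-landmark scheme (3 fixed + semi-landmark
  curves of 18/18/8), TPS reading/writing, generalized Procrustes
  superimposition with chord min-d² semi-landmark sliding, PCA
  morphospaces, per-group convex hull areas.
* **Disparity** — stage-level time bins (ICS 2019/05 boundary ages,
  Changhsingian–Toarcian), range-overlap bin assignment, sparse-bin
  merging, sum-of-variances (SoV) disparity with 2000-replicate bootstrap
  intervals, permutational MANOVA (pseudo-F, 9999 permutations, Bonferroni
  pairwise) plus an exhaustive small-sample variant.
* **Locomotor indices** — quadrupedality `(humerus + radius)/(femur +
  tibia)` and cursoriality `metatarsal III / femur`, largest-specimen
  isometric scaling, flying/aquatic filtering, log10 femur body size, and
  a phylogenetic ANCOVA under Pagel's λ (REML grid + polish on [0, 1]).
* **Time-scaling** — uniform random polytomy resolution, minimum branch
  length (0.1 Myr) dating, a probabilistic birth–death–sampling
  (cal3-style) dating with randomized tip ages, sampling rates drawn from
  U(0.018, 0.18) lmy⁻¹, and the 0.0001 Myr zero-length-branch fix.
* **Evolutionary rates** — variable-rates Brownian motion by
  reversible-jump MCMC (contrasts likelihood in C++), stepping-stone
  marginal likelihoods, log-BF evidence grades at 2/5/10, per-branch modal
  scalars and scaling frequencies, a three-criterion positive-selection
  test across whole tree sets, rate-rescaled consensus trees, ML ancestral
  states, and a body-size-adjusted regression variant.
* **Synthetic data** — parametric bone outlines with interpretable
  deformation axes, measurement tables with planted index means, forward
  birth–death–sampling fossil trees with true node dates, and BM traits
  with planted branch-rate shifts; `make_study_bundle()` writes a complete
  coherent study to disk (TPS + CSV + Newick + truth JSON).

The model at the core of the rates module: trait increments on branch *b*
are Gaussian with variance σ²·tᵦ·rᵦ, where σ² is the background Brownian
rate, tᵦ the branch duration (Myr) and rᵦ a branch scalar that is 1 unless
the sampler activates it (log-uniform prior on [10⁻³, 10³], Bernoulli(0.05)
activation).  Positive phenotypic selection is called on a branch when its
modal scalar exceeds 2 with scaling frequency above 0.95 in every tree of
the set.

## Worked example

```r
library(archolimb)

# a complete synthetic study: 16 species, femur outlines, fossil tree
bundle <- make_study_bundle(list(n_per_group = 4L, elements = "femur",
                                 sampling = 0.3), seed = 2)

aln <- gpa_align(bundle$landmarks$femur)
ord <- shape_pca(aln)
print(ord)
#> <shape_ordination> 16 specimens, 15 axes
#>   variance: PC1 = 56.81%, PC2 = 24.01%, PC3 = 7.68%, PC4 = 1.88%

idx <- locomotor_indices(bundle$records)
aggregate(cbind(quadrupedality, cursoriality) ~ group, idx, mean)
#>                              group quadrupedality cursoriality
#> 1                         dinosaur      0.5141465    0.6101069
#> 2 non_archosaurian_archosauromorph      0.9130106    0.4333859
#> 3           other_avemetatarsalian      0.8108796    0.6161743
#> 4                    pseudosuchian      0.8925004    0.5773564

tree <- fix_zlb(bundle$tree)
fit <- variable_rates_mcmc(tree, log(setNames(idx$cursoriality,
                                              idx$species)),
                           iterations = 2e5, thin = 100, seed = 1)
print(fit)
#> <rates_result> 1600 retained samples, 30 branches
#>   sigma2 median 0.002587; ESS(sigma2) = 1224, ESS(loglik) = 738
```

PC1 of the ordination tracks the planted crest/curvature deformations; the
group means reflect the planted index structure (dinosaurs markedly more
bipedal than pseudosuchians; at n = 4 per group the cursoriality means
still carry visible Brownian spread); and the posterior background rate
brackets the generating σ² = 0.002 on the log-cursoriality scale.

`run_pipeline(config, seed)` chains the same steps from a YAML/JSON config
into a run directory with a `manifest.json`, byte-reproducible given
(config, seed).

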