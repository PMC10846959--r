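test_that("two-tip restricted likelihood equals the closed form", {
  tr <- fixture_tree("(A:1,B:1);")
  x <- c(A = 0, B = 2)
  # single contrast 2 with variance sigma2 * (1 + 1) = 2
  expect_equal(contrasts_loglik(tr, x, sigma2 = 1),
               dnorm(2, 0, sqrt(2), log = TRUE), tolerance = 1e-12)
})

test_that("duration-rate rescaling symmetry leaves the likelihood fixed", {
  tr <- random_tree(9, seed = 30)
  x <- simulate_bm_trait(tr, 0.5, seed = 31)$tips
  for (c_scale in c(0.1, 3, 40)) {
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * c_scale
    expect_equal(contrasts_loglik(tr, x, sigma2 = 0.7),
                 contrasts_loglik(tr2, x, sigma2 = 0.7 / c_scale),
                 tolerance = 1e-10)
  }
})

test_that("pruning equals full-matrix restricted GLS on random trees", {
  for (s in 1:12) {
    n <- sample(4:10, 1)
    tr <- random_tree(n, seed = 300 + s)
    x <- simulate_bm_trait(tr, 0.3, seed = 400 + s)$tips
    scalars <- with_seed2(500 + s, exp(rnorm(nrow(tr$edge), 0, 0.5)))
    s2 <- with_seed2(600 + s, runif(1, 0.1, 2))
    expect_equal(contrasts_loglik(tr, x, s2, scalars),
                 gls_reml_oracle(tr, x, s2, scalars), tolerance = 1e-8)
  }
})

test_that("the C++ pruning likelihood matches the R implementation", {
  for (s in 1:5) {
    tr <- random_tree(8, seed = 700 + s)
    x <- simulate_bm_trait(tr, 0.4, seed = 710 + s)$tips
    scalars <- with_seed2(720 + s, exp(rnorm(nrow(tr$edge), 0, 0.4)))
    pre <- archolimb:::preprocess_tree(tr)
    xv <- archolimb:::align_trait(tr, x)
    expect_equal(
      archolimb:::contrasts_loglik_cpp(pre, xv, scalars, 0.9),
      contrasts_loglik(tr, x, 0.9, scalars), tolerance = 1e-10)
  }
})

test_that("missing tip traits and bad parameters are rejected", {
  tr <- fixture_tree()
  expect_error(contrasts_loglik(tr, c(A = 1, B = 2, C = 3), 1), "D")
  expect_error(contrasts_loglik(tr, c(A = 1, B = 2, C = 3, D = 4), 0),
               "sigma2")
})

test_that("ancestral states: symmetric root, GLS weighting, oracle", {
  tr <- fixture_tree("(A:1,B:1);")
  a <- ancestral_states(tr, c(A = 0, B = 2))
  expect_equal(unname(a$root), 1.0, tolerance = 1e-10)

  # unequal branches: GLS weights are inverse durations, so the tip on
  # the short branch dominates
  tr2 <- fixture_tree("(A:1,B:3);")
  a2 <- ancestral_states(tr2, c(A = 0, B = 2))
  expect_equal(unname(a2$root), (0 / 1 + 2 / 3) / (1 / 1 + 1 / 3),
               tolerance = 1e-10)

  # matches phytools::fastAnc on random trees
  skip_if_not_installed("phytools")
  for (s in 1:4) {
    tr3 <- random_tree(8, seed = 800 + s)
    x <- simulate_bm_trait(tr3, 0.5, seed = 810 + s)$tips
    mine <- ancestral_states(tr3, x)$states
    ref <- phytools::fastAnc(tr3, x)
    expect_equal(unname(mine), unname(as.numeric(ref)), tolerance = 1e-6)
  }
})

test_that("root estimate stays inside the tip range", {
  for (s in 1:6) {
    tr <- random_tree(10, seed = 900 + s)
    x <- simulate_bm_trait(tr, 1, seed = 910 + s)$tips
    a <- ancestral_states(tr, x)
    expect_gte(a$root, min(x))
    expect_lte(a$root, max(x))
  }
})

test_that("zero-duration branches are refused", {
  tr <- ape::read.tree(text = "(A:0,B:1);")
  expect_error(ancestral_states(tr, c(A = 0, B = 1)), "fix_zlb")
})
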