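rates_tree <- function(n = 20, seed = 2) {
  with_seed2(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length * 4 + 0.5
    tr
  })
}

test_that("the sampler is a pure function of data and seed", {
  tr <- rates_tree(8)
  x <- simulate_bm_trait(tr, 0.5, seed = 3)$tips
  a <- variable_rates_mcmc(tr, x, iterations = 2e4, thin = 20, seed = 4)
  b <- variable_rates_mcmc(tr, x, iterations = 2e4, thin = 20, seed = 4)
  expect_identical(a$sigma2, b$sigma2)
  expect_identical(a$scalars, b$scalars)
  c3 <- variable_rates_mcmc(tr, x, iterations = 2e4, thin = 20, seed = 5)
  expect_false(identical(a$sigma2, c3$sigma2))
  expect_error(variable_rates_mcmc(tr, x, iterations = 0), "iterations")
})

test_that("homogeneous data keep branch scalars at the background rate", {
  tr <- rates_tree(20, seed = 6)
  x <- simulate_bm_trait(tr, 0.5, seed = 7)$tips
  res <- variable_rates_mcmc(tr, x, iterations = 5e5, thin = 100, seed = 8)
  expect_equal(median(res$modal_scalar), 1)
  expect_lt(mean(res$scaling_frequency > 0.95), 0.05)
  expect_true(all(res$scaling_frequency >= 0 & res$scaling_frequency <= 1))
  expect_true(all(res$modal_scalar > 0))
  # sigma2 posterior brackets the generating value
  expect_gt(quantile(res$sigma2, 0.995), 0.5 * 0.5)
  expect_lt(quantile(res$sigma2, 0.005), 2 * 0.5)
  expect_gt(res$ess[["sigma2"]], 200)
})

test_that("stepping-stone recovers a conjugate-normal marginal likelihood", {
  set.seed(10)
  n <- 20; s2 <- 2; mu0 <- 0; t2 <- 1.5
  y <- rnorm(n, 0.7, sqrt(s2))
  loglik <- function(th) sum(dnorm(y, th, sqrt(s2), log = TRUE))
  logprior <- function(th) dnorm(th, mu0, sqrt(t2), log = TRUE)
  Sig <- s2 * diag(n) + t2
  closed <- as.numeric(-0.5 * (n * log(2 * pi) +
                                 determinant(Sig, log = TRUE)$modulus +
                                 t(y - mu0) %*% solve(Sig) %*% (y - mu0)))
  est <- stepping_stone_mh(loglik, logprior, init = 0, proposal_sd = 0.8,
                           stones = 50, iters_per_stone = 2000, seed = 11)
  expect_lt(abs(est - closed), 0.1)
  expect_identical(est, stepping_stone_mh(loglik, logprior, 0, 0.8,
                                          50, 2000, seed = 11))
})

test_that("more stones reduce the spread of repeated estimates", {
  set.seed(12)
  y <- rnorm(12, 1, 1)
  loglik <- function(th) sum(dnorm(y, th, 1, log = TRUE))
  logprior <- function(th) dnorm(th, 0, 2, log = TRUE)
  est <- function(stones, seed)
    stepping_stone_mh(loglik, logprior, 0, 0.8, stones = stones,
                      iters_per_stone = 400, seed = seed)
  few <- vapply(1:20, function(s) est(10, 100 + s), numeric(1))
  many <- vapply(1:20, function(s) est(100, 200 + s), numeric(1))
  expect_lt(sd(many), sd(few))
})

test_that("Bayes-factor grades switch exactly at 2, 5 and 10", {
  expect_equal(bayes_factor(3, 0)$grade, "strong")      # log BF = 6
  expect_equal(bayes_factor(6, 0)$grade, "very strong") # log BF = 12
  expect_equal(bayes_factor(1, 1)$grade, "none")
  expect_equal(bayes_factor(1, 0)$log_bf, 2)
  expect_equal(bayes_factor(1, 0)$grade, "positive")
  expect_equal(bayes_factor(2.5, 0)$grade, "strong")
  expect_equal(bayes_factor(5, 0)$grade, "very strong")
  expect_equal(bayes_factor(0.9999, 0)$grade, "none")
})

test_that("tree-model stepping stone is reproducible and sane", {
  tr <- rates_tree(12, seed = 13)
  x <- simulate_bm_trait(tr, 0.5, seed = 14)$tips
  m1 <- stepping_stone_logml(tr, x, "bm", stones = 20,
                             iters_per_stone = 1000, seed = 15)
  m2 <- stepping_stone_logml(tr, x, "bm", stones = 20,
                             iters_per_stone = 1000, seed = 15)
  expect_identical(m1, m2)
  # the marginal likelihood cannot exceed the maximized likelihood
  expect_lt(m1, bm_reml(tr, x)$loglik)
})

test_that("selection calls combine magnitude, certainty and all-trees", {
  fake <- function(modal, freq, keys = c("A", "B"))
    structure(list(modal_scalar = modal, scaling_frequency = freq,
                   mean_scalar = modal, edge_keys = keys),
              class = "rates_result")
  # flagged: modal > 2 and freq > 0.95 in every tree
  res <- list(fake(c(2.5, 1), c(0.97, 0.3)),
              fake(c(2.6, 1), c(0.99, 0.2)))
  out <- detect_positive_selection(res)
  expect_true(out$flagged[out$edge == "A"])
  expect_false(out$flagged[out$edge == "B"])
  # one tree below the certainty criterion blocks the call
  res2 <- list(fake(c(2.5, 1), c(0.97, 0.3)),
               fake(c(2.5, 1), c(0.90, 0.3)))
  expect_false(any(detect_positive_selection(res2)$flagged))
  # magnitude criterion alone is not enough
  res3 <- list(fake(c(1.5, 1), c(0.99, 0.3)),
               fake(c(1.5, 1), c(0.99, 0.3)))
  expect_false(any(detect_positive_selection(res3)$flagged))
})

test_that("consensus scalars average shared edges and drop others", {
  fake <- function(mean_scalar, keys)
    structure(list(mean_scalar = mean_scalar, edge_keys = keys),
              class = "rates_result")
  res <- list(fake(c(1, 2), c("A", "B")), fake(c(3, 5), c("A", "C")))
  out <- consensus_scalars(res)
  expect_equal(out$scalars, c(A = 2))
  expect_equal(out$omitted, 2)
  res2 <- list(fake(c(1, 3), c("A", "B")), fake(c(3, 1), c("A", "B")))
  expect_equal(consensus_scalars(res2)$scalars, c(A = 2, B = 2))
})

test_that("regression variant recovers an exact linear relationship", {
  tr <- rates_tree(15, seed = 16)
  x <- simulate_bm_trait(tr, 0.3, seed = 17)$tips
  y <- 2 * x
  res <- vr_regression(tr, y, x, iterations = 2e5, thin = 100, seed = 18)
  expect_lt(abs(res$slope_summary[["median"]] - 2), 0.05)
  r2 <- vr_regression(tr, y, x, iterations = 2e4, thin = 100, seed = 19)
  r3 <- vr_regression(tr, y, x, iterations = 2e4, thin = 100, seed = 19)
  expect_identical(r2$slope, r3$slope)
})

test_that("the regression slope interval covers zero for unrelated traits", {
  cover <- vapply(1:8, function(s) {
    tr <- rates_tree(30, seed = 500 + s)
    x <- simulate_bm_trait(tr, 0.5, seed = 600 + s)$tips
    y <- simulate_bm_trait(tr, 0.5, seed = 700 + s)$tips
    res <- vr_regression(tr, y, x, iterations = 1e5, thin = 100,
                         seed = 800 + s)
    res$slope_summary[["lo95"]] <= 0 && res$slope_summary[["hi95"]] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.75)
})

test_that("body-size covariate offers both readings of the proxy", {
  rec <- fixture_records()
  gm <- body_size_covariate(rec)
  expect_equal(unname(gm[1]), log10(sqrt(100 * 90)))
  sm <- body_size_covariate(rec, method = "sum")
  expect_equal(unname(sm[1]), log10(190))
})
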