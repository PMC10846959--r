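#' Variable-rates Brownian-motion inference by reversible-jump MCMC
#'
#' Fits the variable-rates independent-contrasts model: trait evolution is
#' Brownian with background rate `sigma2`, and each branch either evolves
#' at the background rate or carries a multiplicative rate scalar.  A
#' reversible-jump sampler toggles scalars on and off (birth proposals
#' draw from the log-uniform scalar prior so densities cancel), perturbs
#' active scalars on the log scale, and random-walks `log(sigma2)`.
#'
#' Default settings are desk-scale (2e6 iterations, thinning 200, 20%
#' burn-in); production-scale settings are reachable through the
#' arguments.
#'
#' @param tree binary dated `phylo`, durations > 0.
#' @param trait named numeric vector covering every tip (>= 5 tips).
#' @param iterations total MCMC iterations (> 0).
#' @param thin sampling interval.
#' @param burnin fraction of retained samples discarded (default 0.2).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param scalar_bound half-width of the log-uniform scalar prior
#'   (default `log(1000)`: scalars in `[1e-3, 1e3]`).
#' @param pi_active prior probability that a branch carries a scalar.
#' @param power power on the likelihood (used by the stepping-stone
#'   sampler; 1 = posterior).
#' @return object of class `rates_result`: posterior samples (`sigma2`,
#'   `loglik`, `scalars` matrix), per-branch `modal_scalar`,
#'   `scaling_frequency` and `mean_scalar`, `ess` for the monitored
#'   traces, and the edge bipartition keys.
#' @export
variable_rates_mcmc <- function(tree, trait, iterations = 2e6L, thin = 200L,
                                burnin = 0.2, seed = 1L,
                                scalar_bound = log(1000),
                                pi_active = 0.05, power = 1) {
  if (iterations <= 0) stop("iterations must be > 0")
  if (length(tree$tip.label) < 5) stop("need at least 5 tips")
  x <- align_trait(tree, trait)
  pre <- preprocess_tree(tree)
  run <- function() vr_mcmc_cpp(pre, x, numeric(0), power,
                                as.integer(iterations), as.integer(thin),
                                pi_active, scalar_bound,
                                log(1e-6), log(1e6),
                                0.5, 0.4, 0.25, TRUE, FALSE,
                                init_sigma2(tree, x))
  raw <- if (is.null(seed)) run() else with_seed(seed, run())
  summarize_rates(raw, tree, burnin, regression = FALSE)
}

#' Variable-rates regression of one trait on another
#'
#' Independent-contrast regression through the origin: the response is
#' modelled as `y = slope * x + epsilon` with `epsilon` Brownian on the
#' tree, the residual variance carrying the variable-rates branch
#' scalars.  The slope receives a flat prior and a random-walk move.
#'
#' @inheritParams variable_rates_mcmc
#' @param y,x named numeric vectors covering every tip (response and
#'   covariate, e.g. cursoriality and body size).
#' @return a `rates_result` with an additional `slope` sample vector and
#'   `slope_summary`.
#' @export
vr_regression <- function(tree, y, x, iterations = 2e6L, thin = 200L,
                          burnin = 0.2, seed = 1L,
                          scalar_bound = log(1000), pi_active = 0.05,
                          power = 1) {
  if (iterations <= 0) stop("iterations must be > 0")
  yv <- align_trait(tree, y)
  xv <- align_trait(tree, x)
  pre <- preprocess_tree(tree)
  run <- function() vr_mcmc_cpp(pre, yv, xv, power,
                                as.integer(iterations), as.integer(thin),
                                pi_active, scalar_bound,
                                log(1e-6), log(1e6),
                                0.5, 0.4, 0.1, TRUE, TRUE,
                                init_sigma2(tree, yv))
  raw <- if (is.null(seed)) run() else with_seed(seed, run())
  summarize_rates(raw, tree, burnin, regression = TRUE)
}

init_sigma2 <- function(tree, x) {
  s2 <- mean(prune_contrasts(tree, x, rep(1, nrow(tree$edge)))$contrasts^2 /
               prune_contrasts(tree, x, rep(1, nrow(tree$edge)))$variances)
  log(max(s2, 1e-6))
}

# flatten a binary phylo into the arrays the C++ sampler consumes
preprocess_tree <- function(tree) {
  if (any(tree$edge.length <= 0))
    stop("zero or negative branch duration; apply fix_zlb() first")
  po <- postorder_edges(tree)
  e1 <- integer(length(po$nodes)); e2 <- integer(length(po$nodes))
  for (k in seq_along(po$nodes)) {
    ee <- po$child_edges[[as.character(po$nodes[k])]]
    if (length(ee) != 2) stop("tree must be binary")
    e1[k] <- ee[1]; e2[k] <- ee[2]
  }
  list(ntip = length(tree$tip.label), nnode = tree$Nnode,
       parent = as.integer(tree$edge[, 1]), child = as.integer(tree$edge[, 2]),
       len = as.numeric(tree$edge.length),
       po_node = as.integer(po$nodes),
       po_e1 = as.integer(e1 - 1L), po_e2 = as.integer(e2 - 1L))
}

summarize_rates <- function(raw, tree, burnin, regression) {
  n <- length(raw$sigma2)
  keep <- seq.int(floor(burnin * n) + 1L, n)
  sc <- raw$scalars[keep, , drop = FALSE]
  freq <- colMeans(sc != 1)
  modal <- apply(sc, 2, modal_scalar)
  res <- list(
    sigma2 = raw$sigma2[keep],
    loglik = raw$loglik[keep],
    scalars = sc,
    modal_scalar = modal,
    scaling_frequency = freq,
    mean_scalar = colMeans(sc),
    ess = c(sigma2 = ess(raw$sigma2[keep]), loglik = ess(raw$loglik[keep])),
    edge_keys = edge_bipartitions(tree),
    tree = tree)
  if (regression) {
    res$slope <- raw$slope[keep]
    res$slope_summary <- c(median = median(res$slope),
                           lo95 = unname(quantile(res$slope, 0.025)),
                           hi95 = unname(quantile(res$slope, 0.975)))
    res$ess <- c(res$ess, slope = ess(res$slope))
  }
  structure(res, class = "rates_result")
}

#' @export
print.rates_result <- function(x, ...) {
  cat("<rates_result>", length(x$sigma2), "retained samples,",
      length(x$modal_scalar), "branches\n")
  cat(sprintf("  sigma2 median %.4g; ESS(sigma2) = %.0f, ESS(loglik) = %.0f\n",
              median(x$sigma2), x$ess["sigma2"], x$ess["loglik"]))
  if (!is.null(x$slope))
    cat(sprintf("  slope median %.4g [%.4g, %.4g]\n", x$slope_summary[1],
                x$slope_summary[2], x$slope_summary[3]))
  invisible(x)
}

# Histogram mode of the log scalars (50 bins over the sampled range),
# back-transformed.  The point mass at 1 (samples where no scalar is
# applied) wins when it outnumbers every bin of the active samples.
modal_scalar <- function(s) {
  n1 <- sum(s == 1)
  act <- log(s[s != 1])
  if (length(act) == 0) return(1)
  if (diff(range(act)) < 1e-12) {
    if (n1 >= length(act)) return(1) else return(exp(act[1]))
  }
  h <- graphics::hist(act, breaks = 50, plot = FALSE)
  if (n1 >= max(h$counts)) return(1)
  exp(h$mids[which.max(h$counts)])
}

# effective sample size from the autocorrelation function, truncated at
# the first non-positive estimate
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  a <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(a <= 0)
  if (length(pos) > 0) a <- a[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(a))
}

#' Log marginal likelihood by stepping-stone sampling
#'
#' Runs power-posterior chains at powers placed on the quantiles of a
#' Beta(`alpha`, 1) schedule and combines them with the stepping-stone
#' estimator.  `model = "bm"` is the homogeneous Brownian model (no
#' branch scalars); `model = "vr"` the variable-rates model.
#'
#' @inheritParams variable_rates_mcmc
#' @param model `"vr"` or `"bm"`.
#' @param stones number of stones (>= 2); desk-scale default 50.
#' @param iters_per_stone MCMC iterations per stone (default 2000).
#' @param alpha Beta schedule shape (default 0.4).
#' @param x optional covariate for the regression variant.
#' @return scalar log marginal likelihood (of the contrasts).
#' @export
stepping_stone_logml <- function(tree, trait, model = c("vr", "bm"),
                                 stones = 50L, iters_per_stone = 2000L,
                                 seed = 1L, alpha = 0.4,
                                 scalar_bound = log(1000),
                                 pi_active = 0.05, x = NULL) {
  model <- match.arg(model)
  if (stones < 2) stop("need at least 2 stones")
  tv <- align_trait(tree, trait)
  xv <- if (is.null(x)) numeric(0) else align_trait(tree, x)
  pre <- preprocess_tree(tree)
  betas <- (seq(0, stones - 1) / stones)^(1 / alpha)   # Beta(alpha,1) quantiles
  betas <- c(betas, 1)
  run <- function() {
    thin <- 5L
    ll_by_stone <- vector("list", stones)
    for (k in seq_len(stones)) {
      raw <- vr_mcmc_cpp(pre, tv, xv, betas[k],
                         as.integer(iters_per_stone), thin,
                         pi_active, scalar_bound, log(1e-6), log(1e6),
                         0.5, 0.6, 0.1, model == "vr", length(xv) > 0,
                         init_sigma2(tree, tv))
      ll <- raw$loglik
      ll_by_stone[[k]] <- ll[-seq_len(floor(length(ll) * 0.2))]
    }
    stepping_stone_combine(ll_by_stone, betas)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Combine power-posterior log-likelihood samples into a log marginal
#' likelihood
#'
#' The stepping-stone estimator: for each adjacent pair of powers
#' `(b_k, b_{k+1})` the ratio is estimated as the mean of
#' `exp((b_{k+1} - b_k) * logL)` over the samples drawn at power `b_k`,
#' accumulated in log space.
#'
#' @param ll_by_stone list of numeric vectors, log-likelihood samples per
#'   stone (at powers `betas[1..K]`).
#' @param betas increasing powers of length `K + 1`, ending at 1.
#' @return scalar log marginal-likelihood estimate.
#' @export
stepping_stone_combine <- function(ll_by_stone, betas) {
  K <- length(ll_by_stone)
  stopifnot(length(betas) == K + 1)
  total <- 0
  for (k in seq_len(K)) {
    d <- betas[k + 1] - betas[k]
    ll <- ll_by_stone[[k]]
    m <- max(d * ll)
    total <- total + m + log(mean(exp(d * ll - m)))
  }
  total
}

#' Generic stepping-stone estimator with a random-walk MH kernel
#'
#' Estimates a log marginal likelihood for an arbitrary one-parameter (or
#' vector-parameter) model by running power posteriors with a Gaussian
#' random-walk Metropolis kernel.  Used for validating the estimator on
#' conjugate toys with closed-form marginals.
#'
#' @param loglik function(theta) -> log-likelihood.
#' @param logprior function(theta) -> log prior density.
#' @param init initial parameter vector.
#' @param proposal_sd random-walk standard deviation (recycled).
#' @param stones,iters_per_stone,alpha,seed as in [stepping_stone_logml()].
#' @return scalar log marginal-likelihood estimate.
#' @export
stepping_stone_mh <- function(loglik, logprior, init, proposal_sd = 1,
                              stones = 50L, iters_per_stone = 2000L,
                              alpha = 0.4, seed = 1L) {
  betas <- c((seq(0, stones - 1) / stones)^(1 / alpha), 1)
  run <- function() {
    theta <- init
    ll <- loglik(theta); lp <- logprior(theta)
    ll_by_stone <- vector("list", stones)
    for (k in seq_len(stones)) {
      b <- betas[k]
      keep <- numeric(iters_per_stone)
      for (i in seq_len(iters_per_stone)) {
        prop <- theta + rnorm(length(theta), 0, proposal_sd)
        ll_p <- loglik(prop); lp_p <- logprior(prop)
        if (is.finite(lp_p) &&
            log(runif(1)) < b * (ll_p - ll) + (lp_p - lp)) {
          theta <- prop; ll <- ll_p; lp <- lp_p
        }
        keep[i] <- ll
      }
      ll_by_stone[[k]] <- keep[-seq_len(floor(iters_per_stone * 0.2))]
    }
    stepping_stone_combine(ll_by_stone, betas)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Bayes-factor evidence grade for variable rates
#'
#' `log BF = 2 * (log ML_vr - log ML_bm)`, graded on the conventional
#' scale: none < 2 <= positive < 5 <= strong < 10 <= very strong.
#'
#' @param logml_vr,logml_bm log marginal likelihoods of the variable-rates
#'   and homogeneous models.
#' @return list with `log_bf` and `grade`.
#' @export
bayes_factor <- function(logml_vr, logml_bm) {
  log_bf <- 2 * (logml_vr - logml_bm)
  grade <- if (log_bf >= 10) "very strong" else if (log_bf >= 5) "strong"
  else if (log_bf >= 2) "positive" else "none"
  list(log_bf = log_bf, grade = grade)
}
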