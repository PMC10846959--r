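#' Phylogenetic ANCOVA under Pagel's lambda
#'
#' Generalized least squares with the correlation structure of Brownian
#' motion on the tree, damped by Pagel's lambda (off-diagonal phylogenetic
#' covariance multiplied by lambda).  Lambda is estimated by maximizing the
#' restricted likelihood over `[0, 1]` on a fine grid followed by local
#' polishing, which is robust to multimodal profiles.  With lambda fixed at
#' 0 the fit reduces to ordinary least squares.
#'
#' The default model is the ANCOVA `y ~ group + size` with no
#' group-by-size interaction.
#'
#' @param y named numeric response (e.g. cursoriality), names = species.
#' @param group factor-like, two or more levels, same order as `y`.
#' @param size numeric covariate (e.g. log10 femur length).
#' @param tree a dated `phylo` containing every species in `names(y)`.
#' @param lambda `"ML"` (default: estimated) or a fixed value in `[0, 1]`.
#' @param grid_points grid resolution for the lambda profile (default
#'   1001).
#' @return object of class `pgls_ancova`: `coefficients` (estimate, se, t,
#'   p per term), `lambda`, `logLik_reml`, `sigma2`, `n`.
#' @export
pgls_ancova <- function(y, group, size, tree, lambda = "ML",
                        grid_points = 1001L) {
  sp <- names(y)
  if (is.null(sp)) stop("y must be named by species")
  missing_sp <- setdiff(sp, tree$tip.label)
  if (length(missing_sp) > 0)
    stop("species missing from tree: ", paste(missing_sp, collapse = ", "))
  group <- factor(group)
  if (any(table(group) < 3))
    stop("need >= 3 species per group")
  tr <- ape::keep.tip(tree, sp)
  V <- ape::vcv(tr)[sp, sp]
  X <- stats::model.matrix(~ group + size)
  fit <- pgls_lambda_fit(y, X, V, lambda, grid_points)
  se <- sqrt(diag(fit$vcov_beta))
  tval <- fit$beta / se
  df <- length(y) - ncol(X)
  pval <- 2 * stats::pt(-abs(tval), df)
  coef_tab <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                         t = tval, p = pval, stringsAsFactors = FALSE)
  rownames(coef_tab) <- NULL
  structure(list(coefficients = coef_tab, lambda = fit$lambda,
                 logLik_reml = fit$loglik, sigma2 = fit$sigma2,
                 n = length(y)), class = "pgls_ancova")
}

# REML profile fit over lambda in [0,1] using one symmetric eigen
# decomposition: V(lambda) = D^{1/2} (lambda W + (1-lambda) I) D^{1/2}
# with W = D^{-1/2} V D^{-1/2} = U diag(w) U', so each lambda evaluation
# is O(n p) after rotating X and y once.
pgls_lambda_fit <- function(y, X, V, lambda = "ML", grid_points = 1001L) {
  n <- length(y)
  d <- diag(V)
  s <- 1 / sqrt(d)
  W <- t(V * s) * s                     # D^{-1/2} V D^{-1/2}
  ew <- eigen(W, symmetric = TRUE)
  U <- ew$vectors
  w <- ew$values
  yt <- crossprod(U, y * s)             # U' D^{-1/2} y
  Xt <- crossprod(U, X * s)
  logdet_D <- sum(log(d))
  reml <- function(lam) {
    ev <- lam * w + (1 - lam)
    if (any(ev <= 0)) return(-Inf)
    gls_reml_core(yt, Xt, ev, logdet_D)$loglik
  }
  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, length.out = grid_points)
    ll <- vapply(grid, reml, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-10)
    lam_hat <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  } else {
    lam_hat <- as.numeric(lambda)
    if (lam_hat < 0 || lam_hat > 1) stop("lambda must lie in [0, 1]")
  }
  ev <- lam_hat * w + (1 - lam_hat)
  core <- gls_reml_core(yt, Xt, ev, logdet_D)
  list(lambda = lam_hat, beta = setNames(core$beta, colnames(X)),
       vcov_beta = core$vcov_beta, sigma2 = core$sigma2,
       loglik = core$loglik)
}

# REML of y ~ X with covariance sigma2 * diag(ev) in the rotated basis
# (plus a fixed log|D| term from the original scaling).
gls_reml_core <- function(yt, Xt, ev, logdet_D = 0) {
  n <- length(yt); p <- ncol(Xt)
  Xw <- Xt / ev
  XtVX <- crossprod(Xt, Xw)
  beta <- solve(XtVX, crossprod(Xw, yt))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / ev)
  sigma2 <- rss / (n - p)
  loglik <- -0.5 * ((n - p) * log(2 * pi * sigma2) + sum(log(ev)) +
                      logdet_D + determinant(XtVX, logarithm = TRUE)$modulus +
                      (n - p))
  list(beta = as.numeric(beta), sigma2 = sigma2,
       vcov_beta = sigma2 * solve(XtVX), loglik = as.numeric(loglik))
}

#' @export
print.pgls_ancova <- function(x, ...) {
  cat(sprintf("<pgls_ancova> n = %d, lambda = %.4f, REML logLik = %.3f\n",
              x$n, x$lambda, x$logLik_reml))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
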