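#' Restricted (contrasts) log-likelihood of Brownian motion
#'
#' Felsenstein pruning over the independent contrasts of a binary dated
#' tree, with branch variance `sigma2 * duration * scalar`.  The result is
#' the restricted likelihood (the likelihood of the n - 1 contrasts, which
#' does not depend on the unknown root state) and equals the full
#' multivariate-normal restricted GLS likelihood.
#'
#' @param tree binary dated `phylo` (durations in Myr, all > 0).
#' @param trait named numeric vector covering every tip.
#' @param sigma2 background rate, > 0.
#' @param scalars optional per-edge rate scalars (> 0), in `tree$edge`
#'   order; default all 1.
#' @return scalar log-likelihood.
#' @export
contrasts_loglik <- function(tree, trait, sigma2, scalars = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (is.null(scalars)) scalars <- rep(1, nrow(tree$edge))
  if (any(scalars <= 0)) stop("scalars must be > 0")
  x <- align_trait(tree, trait)
  pr <- prune_contrasts(tree, x, scalars)
  sum(dnorm(pr$contrasts, 0, sqrt(sigma2 * pr$variances), log = TRUE))
}

# one pruning pass: returns contrasts and their (sigma2-free) variances
prune_contrasts <- function(tree, x, scalars) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  val <- numeric(nn); val[seq_len(ntip)] <- x
  extra <- numeric(nn)
  po <- postorder_edges(tree)
  contrasts <- numeric(tree$Nnode)
  variances <- numeric(tree$Nnode)
  k <- 0L
  for (v in po$nodes) {
    e <- po$child_edges[[as.character(v)]]
    if (length(e) != 2) stop("tree must be binary")
    c1 <- tree$edge[e[1], 2]; c2 <- tree$edge[e[2], 2]
    v1 <- tree$edge.length[e[1]] * scalars[e[1]] + extra[c1]
    v2 <- tree$edge.length[e[2]] * scalars[e[2]] + extra[c2]
    k <- k + 1L
    contrasts[k] <- val[c1] - val[c2]
    variances[k] <- v1 + v2
    val[v] <- (val[c1] * v2 + val[c2] * v1) / (v1 + v2)
    extra[v] <- v1 * v2 / (v1 + v2)
  }
  list(contrasts = contrasts[seq_len(k)], variances = variances[seq_len(k)],
       root_value = val[length(tree$tip.label) + 1L],
       root_extra = extra[length(tree$tip.label) + 1L])
}

postorder_edges <- function(tree) {
  nodes <- rev(unique(reorder(tree, "cladewise")$edge[, 1]))
  ce <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  list(nodes = nodes, child_edges = ce)
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("trait length does not match the tree")
    return(as.numeric(trait))
  }
  m <- match(tree$tip.label, names(trait))
  if (anyNA(m))
    stop("tip(s) without trait value: ",
         paste(tree$tip.label[is.na(m)], collapse = ", "))
  as.numeric(trait[m])
}

#' REML estimate of the Brownian-motion rate
#'
#' @inheritParams contrasts_loglik
#' @return list with `sigma2` (REML estimate) and `loglik` at the optimum.
#' @export
bm_reml <- function(tree, trait, scalars = NULL) {
  if (is.null(scalars)) scalars <- rep(1, nrow(tree$edge))
  x <- align_trait(tree, trait)
  pr <- prune_contrasts(tree, x, scalars)
  s2 <- mean(pr$contrasts^2 / pr$variances)
  list(sigma2 = s2,
       loglik = sum(dnorm(pr$contrasts, 0, sqrt(s2 * pr$variances),
                          log = TRUE)))
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' GLS reconstruction of internal-node states: the root is the GLS mean
#' and every node the conditional expectation given the tips, using the
#' full phylogenetic covariance.  The root estimate always lies within the
#' range of the tip values.
#'
#' @param tree dated `phylo`, all branch durations > 0 (apply [fix_zlb()]
#'   first if a time-scaling produced zero-length branches).
#' @param trait named numeric vector covering every tip.
#' @return object of class `ancestral_states`: `states` (named by node
#'   number), `root`, `tree`.
#' @export
ancestral_states <- function(tree, trait) {
  if (any(tree$edge.length <= 0))
    stop("zero or negative branch duration; apply fix_zlb() first")
  x <- align_trait(tree, trait)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)          # node x node MRCA matrix
  Ctt <- matrix(depths[M[seq_len(ntip), seq_len(ntip)]], ntip, ntip)
  nodes <- (ntip + 1L):nn
  Cnt <- matrix(depths[M[nodes, seq_len(ntip), drop = FALSE]],
                length(nodes), ntip)
  Ci <- solve(Ctt)
  one <- rep(1, ntip)
  mu <- sum(Ci %*% x) / sum(Ci)
  states <- as.numeric(mu + Cnt %*% Ci %*% (x - mu))
  structure(list(states = setNames(states, as.character(nodes)),
                 root = states[1], tree = tree),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("<ancestral_states>", length(x$states), "nodes; root =",
      signif(x$root, 5), "\n")
  invisible(x)
}
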