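#' Simulate a Brownian-motion trait with planted branch rate shifts
#'
#' Evolves a continuous trait along a dated tree under Brownian motion with
#' branch variance `sigma2 * duration * scalar`, where per-branch scalars
#' default to 1 and planted shifts multiply the background rate.  Internal
#' node values are returned so that rate-recovery tests can compare against
#' the ground truth.
#'
#' @param tree a dated `phylo` (branch lengths in Myr).
#' @param sigma2 background BM rate (trait^2 / Myr), >= 0.
#' @param root_state trait value at the root.
#' @param shifts named numeric vector of rate scalars (> 0); names are
#'   either tip labels or node numbers identifying the branch by its child
#'   node.  Unnamed branches have scalar 1.
#' @param seed integer seed.
#' @return list with `tips` (named vector, tip-label order), `nodes`
#'   (internal node values indexed by node number), and `scalars` (the full
#'   per-branch scalar vector, one per edge of `tree`).
#' @export
simulate_bm_trait <- function(tree, sigma2, root_state = 0,
                              shifts = NULL, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  scalars <- branch_scalars(tree, shifts)
  if (any(scalars <= 0)) stop("rate scalars must be > 0")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  with_seed(seed, {
    x <- numeric(ntip + nnode)
    root <- ntip + 1L
    x[root] <- root_state
    ord <- reorder(tree, "cladewise")    # parents before children
    for (i in seq_len(nrow(ord$edge))) {
      par <- ord$edge[i, 1]; chi <- ord$edge[i, 2]
      v <- sigma2 * ord$edge.length[i] * scalars_for(tree, scalars, chi)
      x[chi] <- x[par] + rnorm(1, 0, sqrt(v))
    }
    tips <- setNames(x[seq_len(ntip)], tree$tip.label)
    nodes <- setNames(x[(ntip + 1L):(ntip + nnode)],
                      as.character((ntip + 1L):(ntip + nnode)))
    list(tips = tips, nodes = nodes, scalars = scalars)
  })
}

# Expand a named shift map into one scalar per edge (edge order of `tree`).
branch_scalars <- function(tree, shifts) {
  scalars <- rep(1, nrow(tree$edge))
  if (is.null(shifts) || length(shifts) == 0) return(scalars)
  if (is.null(names(shifts)))
    stop("shifts must be a named vector (tip labels or child node numbers)")
  ntip <- length(tree$tip.label)
  for (nm in names(shifts)) {
    tipm <- match(nm, tree$tip.label)
    child <- if (!is.na(tipm)) tipm else suppressWarnings(as.integer(nm))
    if (is.na(child)) stop("unknown branch identifier: ", nm)
    e <- which(tree$edge[, 2] == child)
    if (length(e) != 1) stop("no branch with child node ", nm)
    scalars[e] <- shifts[[nm]]
  }
  scalars
}

scalars_for <- function(tree, scalars, child)
  scalars[which(tree$edge[, 2] == child)]
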