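#' Randomly resolve polytomies, uniformly over labeled topologies
#'
#' Each polytomy is replaced by a rooted binary subtree over its child
#' subtrees, drawn uniformly from the `(2k - 3)!!` labeled rooted binary
#' topologies on `k` children by sequential random edge insertion.  Binary
#' trees pass through unchanged; branch lengths are dropped (the output is
#' an undated topology ready for time-scaling).
#'
#' @param tree a `phylo`.
#' @param seed integer seed.
#' @return binary `phylo` with the same tip set.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  with_seed(seed, {
    if (ape::is.binary.phylo(tree)) {
      tree$edge.length <- NULL
      return(tree)
    }
    nw <- resolve_newick(tree)
    out <- ape::read.tree(text = nw)
    out
  })
}

# Build a resolved newick string recursively; polytomies resolved by
# uniform sequential insertion of child blocks into a growing binary tree.
resolve_newick <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  node_str <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    kids <- children[[as.character(v)]]
    blocks <- vapply(kids, node_str, character(1))
    if (length(blocks) == 1) return(blocks)
    combine_uniform(blocks)
  }
  paste0(node_str(ntip + 1L), ";")
}

# Uniform rooted binary topology over blocks: start from a 2-block cherry,
# then attach each further block on a uniformly chosen edge (including the
# root edge), which yields each labeled topology with equal probability.
combine_uniform <- function(blocks) {
  k <- length(blocks)
  if (k == 2) return(paste0("(", blocks[1], ",", blocks[2], ")"))
  tr <- list(blocks[1], blocks[2])
  for (b in blocks[-(1:2)]) {
    n_edges <- count_edges(tr) + 1L        # + root edge
    e <- sample.int(n_edges, 1)
    tr <- if (e == n_edges) list(tr, b) else attach_at(tr, b, e)$tree
  }
  to_newick(tr)
}

count_edges <- function(tr) {
  if (is.character(tr)) return(0L)
  2L + count_edges(tr[[1]]) + count_edges(tr[[2]])
}

# Attach block b on the e-th edge of tr (edges numbered: left child edge,
# edges inside left subtree, right child edge, edges inside right subtree).
# Returns list(done =, tree =, e = remaining count when not done).
attach_at <- function(tr, b, e) {
  for (side in 1:2) {
    if (e == 1L) {
      tr[[side]] <- list(tr[[side]], b)
      return(list(done = TRUE, tree = tr))
    }
    e <- e - 1L
    child <- tr[[side]]
    if (!is.character(child)) {
      res <- attach_at(child, b, e)
      if (res$done) {
        tr[[side]] <- res$tree
        return(list(done = TRUE, tree = tr))
      }
      e <- res$e
    }
  }
  list(done = FALSE, e = e)
}

to_newick <- function(tr) {
  if (is.character(tr)) return(tr)
  paste0("(", to_newick(tr[[1]]), ",", to_newick(tr[[2]]), ")")
}

#' Minimum branch length time-scaling
#'
#' Tips sit at their first appearance ages; each internal node is placed
#' `mbl` older than its oldest child, which is the minimal rootward shift
#' ensuring every branch lasts at least `mbl` Myr.
#'
#' @param tree binary `phylo` topology.
#' @param dates date table (`species`, `fad`, `lad`).
#' @param mbl minimum branch duration in Myr (> 0; default 0.1).
#' @return a dated `phylo` (class also `timescaled`) with `$ages` (node
#'   ages, Ma) and `$tip_ages` attached.
#' @export
mbl_timescale <- function(tree, dates, mbl = 0.1) {
  if (mbl <= 0) stop("mbl must be > 0")
  if (!ape::is.binary.phylo(tree)) stop("tree must be binary")
  td <- tip_dates(tree, dates)
  ntip <- length(tree$tip.label)
  ages <- numeric(ntip + tree$Nnode)
  ages[seq_len(ntip)] <- td$fad
  po <- rev(postorder_nodes(tree))      # children before parents
  children <- split(tree$edge[, 2], tree$edge[, 1])
  for (v in po) {
    if (v <= ntip) next
    kids <- children[[as.character(v)]]
    ages[v] <- max(ages[kids]) + mbl
  }
  dated_tree(tree, ages, td)
}

postorder_nodes <- function(tree) {
  # nodes ordered parents-first (preorder); reverse for postorder
  ord <- reorder(tree, "cladewise")
  c(ord$edge[1, 1], ord$edge[, 2])
}

dated_tree <- function(tree, ages, td) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(tree$edge.length < 0))
    stop("internal error: negative branch duration")
  tree$ages <- ages
  tree$tip_ages <- setNames(ages[seq_along(tree$tip.label)], tree$tip.label)
  class(tree) <- unique(c("timescaled", class(tree)))
  tree
}

#' Draw an instantaneous fossil-sampling rate
#'
#' Uniform on the published range of sampling-rate estimates for Devonian
#' tetrapods and Mesozoic dinosaurs, 0.018-0.18 per lineage Myr.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param bounds lower/upper bounds (lmy^-1).
#' @return scalar rate.
#' @export
draw_sampling_rate <- function(seed = NULL, bounds = c(0.018, 0.18)) {
  if (bounds[1] <= 0 || bounds[2] <= bounds[1])
    stop("bounds must satisfy 0 < low < high")
  if (is.null(seed)) runif(1, bounds[1], bounds[2])
  else with_seed(seed, runif(1, bounds[1], bounds[2]))
}

#' Birth-death-sampling rate triple
#'
#' @param branching,extinction,sampling rates in lineage/Myr, all > 0.
#' @return list of class `cal3_rates`.
#' @export
cal3_rates <- function(branching, extinction, sampling) {
  if (branching <= 0 || extinction <= 0 || sampling <= 0)
    stop("all rates must be > 0")
  structure(list(branching = branching, extinction = extinction,
                 sampling = sampling), class = "cal3_rates")
}

#' Derive birth-death rates from a sampling rate
#'
#' Convenience helper setting branching = extinction = `multiplier` times
#' the sampling rate.
#'
#' @param sampling sampling rate (lmy^-1).
#' @param multiplier positive scalar.
#' @return a `cal3_rates` object.
#' @export
rates_from_sampling <- function(sampling, multiplier = 1) {
  cal3_rates(multiplier * sampling, multiplier * sampling, sampling)
}

#' Probabilistic (birth-death-sampling) time-scaling
#'
#' A cal3-style a-posteriori time-scaling draw.  Tip observation ages are
#' drawn uniformly between each tip's LAD and FAD.  Moving from the tips
#' toward the root, every internal node is placed a random gap older than
#' its oldest dated child; the gap is the waiting time until the clade
#' would first leave observable evidence under the birth-death-sampling
#' rates, an exponential with hazard
#' `psi + lambda * P_sampled` (where `P_sampled` is the probability that a
#' fresh lineage is ever sampled), discretized on a grid of `step` Myr.
#' Ancestor-descendant collapsing is never performed, so every branch has
#' positive expected duration; exact zeros (gap drawn in the first grid
#' cell with a zero-length tip branch) are removed afterwards with
#' [fix_zlb()].
#'
#' @param tree binary `phylo` topology.
#' @param dates date table (`species`, `fad`, `lad`).
#' @param rates a `cal3_rates` object.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @param step discretization step for node-age increments (Myr).
#' @param max_gap upper truncation for the nodal gap (Myr).
#' @return a dated `phylo` as in [mbl_timescale()].
#' @export
cal3_timescale <- function(tree, dates, rates, seed = 1L, step = 0.001,
                           max_gap = 50) {
  stopifnot(inherits(rates, "cal3_rates"))
  if (!ape::is.binary.phylo(tree)) stop("tree must be binary")
  td <- tip_dates(tree, dates)
  draw <- function() {
    ntip <- length(tree$tip.label)
    ages <- numeric(ntip + tree$Nnode)
    ages[seq_len(ntip)] <- runif(ntip, td$lad, td$fad)  # randObs tip ages
    hazard <- gap_hazard(rates)
    po <- rev(postorder_nodes(tree))
    children <- split(tree$edge[, 2], tree$edge[, 1])
    for (v in po) {
      if (v <= ntip) next
      kids <- children[[as.character(v)]]
      if (length(kids) == 0)
        stop("node age search window empty for clade at node ", v)
      gap <- draw_discrete_gap(hazard, step, max_gap)
      ages[v] <- max(ages[kids]) + gap
    }
    out <- dated_tree(tree, ages, td)
    fix_zlb(out)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# hazard of the unobserved gap ending: sampling of the lineage itself, or
# a branching event whose daughter clade is ever sampled
gap_hazard <- function(rates) {
  la <- rates$branching; mu <- rates$extinction; psi <- rates$sampling
  # P(lineage leaves no sampled descendant), t -> infinity limit of the
  # birth-death-sampling extinction probability
  p0 <- (la + mu + psi - sqrt((la + mu + psi)^2 - 4 * la * mu)) / (2 * la)
  psi + la * (1 - p0)
}

# draw from the discretized truncated exponential: cell k (k = 0, 1, ...)
# has mass prop to exp(-h k s) (1 - exp(-h s)); inverse-cdf in O(1)
draw_discrete_gap <- function(hazard, step, max_gap) {
  k_max <- floor(max_gap / step)
  u <- runif(1)
  # truncated geometric with q = exp(-h s)
  q <- exp(-hazard * step)
  # P(K <= k) = (1 - q^(k+1)) / (1 - q^(k_max+1))
  z <- u * (1 - q^(k_max + 1))
  k <- floor(log1p(-z) / log(q)) # smallest k with 1 - q^(k+1) >= z, minus 1
  k <- min(max(k, 0), k_max)
  k * step
}

#' Replace zero-length branches by a small positive duration
#'
#' Comparative methods require strictly positive branch durations; branches
#' of length zero are set to `epsilon` (default 0.0001 Myr = 100 yr), all
#' others are untouched.
#'
#' @param tree a `phylo` with branch lengths.
#' @param epsilon positive duration in Myr.
#' @return the corrected tree (ages recomputed if present).
#' @export
fix_zlb <- function(tree, epsilon = 0.0001) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (is.null(tree$ages)) {
    zero <- tree$edge.length == 0
    if (any(zero)) tree$edge.length[zero] <- epsilon
    return(tree)
  }
  # dated tree: keep tip ages anchored and push parents rootward where a
  # branch collapses to zero; cascades are resolved by iterating
  ages <- tree$ages
  repeat {
    len <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
    zero <- len <= 0
    if (!any(zero)) break
    for (e in which(zero)) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      ages[par] <- max(ages[par], ages[chi] + epsilon)
    }
  }
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree$ages <- ages
  tree$tip_ages <- setNames(ages[seq_along(tree$tip.label)], tree$tip.label)
  tree
}

#' Generate a set of time-scaled trees
#'
#' Draws `n_trees` cal3-style time-scalings, each with its own sampling
#' rate drawn from [draw_sampling_rate()] and birth/death rates derived
#' via [rates_from_sampling()], after randomly resolving polytomies.
#'
#' @param tree `phylo` topology (polytomies allowed).
#' @param dates date table.
#' @param n_trees number of draws (default 100).
#' @param seed integer seed.
#' @param multiplier passed to [rates_from_sampling()].
#' @param sampling_bounds passed to [draw_sampling_rate()].
#' @return list with `trees` (list of dated `phylo`) and `provenance`
#'   (per-tree seed and rates).
#' @export
timescale_tree_set <- function(tree, dates, n_trees = 100L, seed = 1L,
                               multiplier = 1,
                               sampling_bounds = c(0.018, 0.18)) {
  with_seed(seed, {
    prov <- vector("list", n_trees)
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      psi <- draw_sampling_rate(seed = NULL, bounds = sampling_bounds)
      rates <- rates_from_sampling(psi, multiplier)
      bin <- resolve_polytomies_inline(tree)
      trees[[i]] <- cal3_timescale(bin, dates, rates, seed = NULL)
      prov[[i]] <- list(index = i, sampling = psi,
                        branching = rates$branching,
                        extinction = rates$extinction)
    }
    list(trees = trees, provenance = prov, seed = seed)
  })
}

# polytomy resolution drawing from the current RNG stream
resolve_polytomies_inline <- function(tree) {
  if (ape::is.binary.phylo(tree)) { tree$edge.length <- NULL; return(tree) }
  ape::read.tree(text = resolve_newick(tree))
}
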