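#' Simulate a fossil tree under birth-death-sampling
#'
#' Forward birth-death simulation conditioned on `n_tips` sampled tips.
#' Lineages branch at rate `branching` and go extinct at rate `extinction`
#' (both per lineage Myr).  Fossil occurrences accrue along each terminal
#' branch as a Poisson process at rate `sampling`; a tip is *sampled* when
#' it has at least one occurrence, and its first/last occurrences give its
#' FAD and LAD.  Unsampled tips are pruned; simulation retries (growing the
#' total clade size) until exactly `n_tips` sampled tips remain.  True
#' divergence times are returned as ground truth for calibration tests.
#'
#' @param n_tips integer >= 2, number of sampled tips required.
#' @param branching,extinction,sampling rates in lineage/Myr; branching and
#'   sampling must be > 0, extinction >= 0.
#' @param seed integer seed.
#' @param origin_age age (Ma) assigned to the root divergence of the
#'   simulated clade.
#' @param max_try rejection-loop cap.
#' @return list with `tree` (dated `phylo`, branch lengths in Myr),
#'   `dates` (species/fad/lad table), `true_ages` (true ages in Ma for all
#'   nodes of `tree`, tips first), `root_age` (true age of the pruned
#'   tree's root divergence) and `extant` (logical per tip).
#' @export
simulate_fossil_tree <- function(n_tips, branching = 0.1, extinction = 0.05,
                                 sampling = 0.1, seed = 1L,
                                 origin_age = 250, max_try = 1000L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (branching <= 0 || sampling <= 0 || extinction < 0)
    stop("rates must be positive (extinction may be 0)")
  with_seed(seed, {
    target_total <- n_tips
    for (attempt in seq_len(max_try)) {
      sim <- sim_bd_once(target_total, branching, extinction)
      if (is.null(sim)) next              # clade died before reaching size
      occ <- lapply(seq_len(nrow(sim$tips)), function(i) {
        dur <- sim$tips$t_end[i] - sim$tips$t_start[i]
        k <- rpois(1, sampling * dur)
        if (k == 0 || dur == 0) numeric(0) else
          sort(runif(k, sim$tips$t_start[i], sim$tips$t_end[i]))
      })
      sampled <- which(lengths(occ) > 0)
      if (length(sampled) == n_tips)
        return(build_fossil_result(sim, occ, sampled, origin_age))
      target_total <- max(n_tips, target_total + n_tips - length(sampled))
    }
    stop("could not obtain ", n_tips, " sampled tips in ", max_try,
         " attempts; increase the sampling rate")
  })
}

# One forward birth-death run stopped when the eventual tip count (extinct
# tips + alive lineages) reaches n_total.  Returns NULL if the clade dies
# first.  Forward time runs from 0 at the root divergence.
sim_bd_once <- function(n_total, lambda, mu) {
  parent <- c(NA_integer_, NA_integer_)
  t_start <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  alive <- c(1L, 2L)
  t <- 0
  n_tips_now <- 2L
  while (n_tips_now < n_total) {
    if (length(alive) == 0) return(NULL)
    t <- t + rexp(1, length(alive) * (lambda + mu))
    who <- alive[sample.int(length(alive), 1)]
    if (runif(1) < lambda / (lambda + mu)) {     # branching
      id1 <- length(parent) + 1L
      parent <- c(parent, who, who)
      t_start <- c(t_start, t, t)
      t_end <- c(t_end, NA_real_, NA_real_)
      t_end[who] <- t
      alive <- c(setdiff(alive, who), id1, id1 + 1L)
      n_tips_now <- n_tips_now + 1L
    } else {                                     # extinction
      t_end[who] <- t
      alive <- setdiff(alive, who)
    }
  }
  if (length(alive) > 0) t_end[alive] <- t       # stop clock at last event
  is_tip <- !(seq_along(parent) %in% parent)
  list(parent = parent, t_start = t_start, t_end = t_end,
       tips = data.frame(id = which(is_tip),
                         t_start = t_start[is_tip],
                         t_end = t_end[is_tip],
                         extant = which(is_tip) %in% alive),
       stop_time = t)
}

# Convert lineage records to an ape phylo.  Each lineage record is an edge
# from its parent's end (or the root divergence at t = 0) to its own end.
bd_records_to_phylo <- function(sim, tip_labels) {
  n_rec <- length(sim$parent)
  is_tip <- !(seq_len(n_rec) %in% sim$parent)
  tip_ids <- which(is_tip)
  int_ids <- which(!is_tip)                      # records that branched
  ntip <- length(tip_ids)
  # phylo node numbering: tips 1..ntip; root = ntip+1; then other internals
  node_of <- integer(n_rec)
  node_of[tip_ids] <- seq_len(ntip)
  node_of[int_ids] <- ntip + 1L + seq_along(int_ids)
  parent_node <- ifelse(is.na(sim$parent), ntip + 1L, node_of[sim$parent])
  edge <- cbind(parent_node, node_of)
  edge_len <- sim$t_end - sim$t_start
  phy <- list(edge = unname(edge), edge.length = unname(edge_len),
              tip.label = tip_labels, Nnode = length(int_ids) + 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

build_fossil_result <- function(sim, occ, sampled, origin_age) {
  labs <- paste0("t", seq_len(nrow(sim$tips)))
  phy <- bd_records_to_phylo(sim, labs)
  keep <- labs[sampled]
  # forward time of the pruned tree's root = MRCA of the retained tips
  root_t <- mrca_time(sim, sim$tips$id[sampled])
  dropped <- setdiff(labs, keep)
  if (length(dropped) > 0)
    phy <- ape::drop.tip(phy, dropped, collapse.singles = TRUE)
  depths <- ape::node.depth.edgelength(phy)
  true_ages <- origin_age - (root_t + depths)
  fad <- vapply(occ[sampled], function(o) origin_age - o[1], numeric(1))
  lad <- vapply(occ[sampled],
                function(o) origin_age - o[length(o)], numeric(1))
  ord <- match(phy$tip.label, keep)
  dates <- data.frame(species = phy$tip.label, fad = fad[ord], lad = lad[ord],
                      stringsAsFactors = FALSE)
  list(tree = phy, dates = dates, true_ages = true_ages,
       root_age = origin_age - root_t,
       extant = sim$tips$extant[sampled][ord])
}

# forward time of the MRCA divergence of a set of lineage records
mrca_time <- function(sim, ids) {
  anc_path <- function(id) {
    path <- integer(0)
    while (!is.na(id)) { path <- c(path, id); id <- sim$parent[id] }
    path
  }
  common <- Reduce(intersect, lapply(ids, anc_path))
  if (length(common) == 0) return(0)            # MRCA is the root divergence
  # paths are ordered tip -> root, so common[1] is the most tipward shared
  # ancestor record; the MRCA divergence is the branching at its end time
  sim$t_end[common[1]]
}
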