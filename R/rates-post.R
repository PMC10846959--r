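#' Edge bipartition keys of a rooted tree
#'
#' Each edge is identified by the sorted set of tip labels in the clade
#' below it, so scalars can be matched across trees that share clades but
#' differ elsewhere.
#'
#' @param tree a `phylo`.
#' @return character vector, one key per edge (tree$edge order).
#' @export
edge_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  po <- postorder_edges(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  for (v in po$nodes)
    desc[[v]] <- sort(unlist(desc[children[[as.character(v)]]]))
  vapply(tree$edge[, 2], function(ch) paste(desc[[ch]], collapse = "|"),
         character(1))
}

#' Mean rate scalars on the shared edges of a tree set
#'
#' Averages each tree's per-branch posterior-mean scalars over the edges
#' (identified by tip bipartition) present in every tree; edges absent
#' from any tree are omitted and counted.
#'
#' @param results list of `rates_result`, one per tree.
#' @return list with `scalars` (named numeric, key = bipartition),
#'   `n_trees` and `omitted` (number of non-universal edges).
#' @export
consensus_scalars <- function(results) {
  keysets <- lapply(results, function(r) r$edge_keys)
  shared <- Reduce(intersect, keysets)
  all_keys <- unique(unlist(keysets))
  out <- vapply(shared, function(k) {
    mean(vapply(results, function(r)
      r$mean_scalar[match(k, r$edge_keys)], numeric(1)))
  }, numeric(1))
  list(scalars = out, n_trees = length(results),
       omitted = length(all_keys) - length(shared))
}

#' Consensus tree with rate-rescaled branch lengths
#'
#' Builds the strict consensus topology of the tree set and gives each of
#' its edges the mean, over trees, of branch duration times that tree's
#' posterior-mean scalar.  Edges not present in all trees are dropped by
#' the strict consensus itself.  The result is the input for
#' rate-heterogeneity-aware ancestral-state estimation.
#'
#' @param results list of `rates_result` (each carries its tree).
#' @return a `phylo` with rescaled branch lengths.
#' @export
consensus_rates_tree <- function(results) {
  trees <- lapply(results, function(r) r$tree)
  cons <- ape::consensus(trees, p = 1, rooted = TRUE)
  cons_keys <- edge_bipartitions(cons)
  lens <- matrix(NA_real_, length(results), length(cons_keys))
  for (i in seq_along(results)) {
    r <- results[[i]]
    m <- match(cons_keys, r$edge_keys)
    lens[i, ] <- (r$tree$edge.length * r$mean_scalar)[m]
  }
  cons$edge.length <- colMeans(lens)
  if (anyNA(cons$edge.length))
    stop("consensus edge missing from a tree's edge set")
  cons
}

#' Detect positive phenotypic selection on branches
#'
#' A branch is flagged when, in *every* tree of the set, its modal rate
#' scalar exceeds the magnitude threshold (default 2) and its scaling
#' frequency exceeds the certainty threshold (default 0.95): phenotypic
#' change on the branch then outpaces the Brownian background in more
#' than 95% of the posterior, consistently across topologies and
#' time-scalings.
#'
#' @param results list of `rates_result`, one per tree.
#' @param magnitude modal-scalar threshold (default 2).
#' @param certainty scaling-frequency threshold (default 0.95).
#' @return data frame keyed by edge bipartition: per-tree minima of the
#'   modal scalar and scaling frequency, and `flagged`.
#' @export
detect_positive_selection <- function(results, magnitude = 2,
                                      certainty = 0.95) {
  keys <- Reduce(intersect, lapply(results, function(r) r$edge_keys))
  rows <- lapply(keys, function(k) {
    ms <- vapply(results, function(r)
      r$modal_scalar[match(k, r$edge_keys)], numeric(1))
    fr <- vapply(results, function(r)
      r$scaling_frequency[match(k, r$edge_keys)], numeric(1))
    data.frame(edge = k, min_modal_scalar = min(ms),
               min_scaling_frequency = min(fr),
               flagged = all(ms > magnitude) && all(fr > certainty),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Body-size covariate for the rate regression
#'
#' Log10 body-size proxy from femur and tibia lengths: by default the
#' geometric mean `sqrt(femur * tibia)`; alternatively their sum.  Taxa
#' lacking a tibia get `NA` and should be dropped before the regression.
#'
#' @param records a `limb_records` data frame.
#' @param method `"geometric_mean"` (default) or `"sum"`.
#' @return named numeric vector (species names).
#' @export
body_size_covariate <- function(records,
                                method = c("geometric_mean", "sum")) {
  method <- match.arg(method)
  fe <- records$femur
  ti <- if ("tibia" %in% names(records)) records$tibia else NA_real_
  v <- switch(method,
              geometric_mean = sqrt(fe * ti),
              sum = fe + ti)
  setNames(log10(v), records$species)
}
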