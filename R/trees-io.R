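#' Read a set of phylogenies with stratigraphic tip dates
#'
#' Reads one or more Newick files (each may contain one or many trees) and
#' attaches first/last appearance ages to every tip from a date table.
#' Order of trees is preserved across files.
#'
#' @param paths character vector of Newick file paths.
#' @param dates data frame with columns `species`, `fad`, `lad` (Ma).
#' @return list with elements `trees` (a list of `phylo` objects) and
#'   `dates` (the validated date table).  Every tip of every tree has a
#'   date row; unmatched tips raise an error naming them.
#' @export
read_tree_set <- function(paths, dates) {
  req <- c("species", "fad", "lad")
  miss <- setdiff(req, names(dates))
  if (length(miss) > 0)
    stop("date table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(dates$fad < dates$lad))
    stop("fad < lad for species: ",
         paste(dates$species[dates$fad < dates$lad], collapse = ", "))
  trees <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("tree file not found: ", p)
    tr <- ape::read.tree(p)
    if (inherits(tr, "phylo")) tr <- list(tr)
    trees <- c(trees, tr)
  }
  for (i in seq_along(trees)) {
    missing_tips <- setdiff(trees[[i]]$tip.label, dates$species)
    if (length(missing_tips) > 0)
      stop("tree ", i, " has tip(s) without dates: ",
           paste(missing_tips, collapse = ", "))
  }
  list(trees = trees, dates = dates)
}

#' Tip date lookup helper
#'
#' @param tree a `phylo` object.
#' @param dates date table as in [read_tree_set()].
#' @return data frame with one row per tip, in `tip.label` order.
#' @keywords internal
tip_dates <- function(tree, dates) {
  m <- match(tree$tip.label, dates$species)
  if (anyNA(m))
    stop("tip(s) without dates: ",
         paste(tree$tip.label[is.na(m)], collapse = ", "))
  data.frame(species = tree$tip.label, fad = dates$fad[m], lad = dates$lad[m],
             stringsAsFactors = FALSE)
}

#' Node ages of a dated tree
#'
#' @param tree a rooted `phylo` with branch lengths in Myr.
#' @param youngest_tip_age age (Ma) of the youngest tip; anchors the tree in
#'   absolute time.
#' @return numeric vector of ages (Ma) indexed by node number (tips first).
#' @export
node_ages <- function(tree, youngest_tip_age = 0) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths + youngest_tip_age
}
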