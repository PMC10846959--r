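#' Principal component ordination of aligned shapes
#'
#' Eigen-decomposition of the specimen covariance (n - 1 denominator) of
#' the flattened aligned coordinates.  Axis signs are fixed so that each
#' axis's largest-magnitude loading is positive, which makes ordinations
#' reproducible across platforms.
#'
#' @param alignment a `procrustes_alignment` from [gpa_align()].
#' @return object of class `shape_ordination` with `scores` (n x k),
#'   `eigenvalues` (non-increasing, >= 0), `variance_fractions` (sum 1),
#'   `loadings` (94 x k orthonormal), `center` (consensus as flat vector),
#'   `axis_shapes` (per axis, consensus +/- the extreme observed score)
#'   and `specimen_ids`.
#' @export
shape_pca <- function(alignment) {
  stopifnot(inherits(alignment, "procrustes_alignment"))
  n <- length(alignment$aligned)
  if (n < 3) stop("need at least 3 specimens for an ordination")
  X <- t(vapply(alignment$aligned, function(m) as.numeric(m),
                numeric(length(alignment$aligned[[1]]))))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1L)
  eig_all <- eig
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xc %*% loadings
  # sign convention: largest-|loading| entry positive per axis
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total <- sum(eig_all)
  axis_shapes <- lapply(seq_len(k), function(j) {
    lo <- min(scores[, j]); hi <- max(scores[, j])
    list(low = matrix(ctr + lo * loadings[, j], ncol = 2),
         high = matrix(ctr + hi * loadings[, j], ncol = 2))
  })
  structure(list(scores = scores,
                 eigenvalues = eig_all[seq_len(k)],
                 variance_fractions = eig_all[seq_len(k)] / total,
                 all_eigenvalues = eig_all,
                 loadings = loadings,
                 center = ctr,
                 axis_shapes = axis_shapes,
                 specimen_ids = alignment$specimen_ids,
                 element = alignment$element),
            class = "shape_ordination")
}

#' @export
print.shape_ordination <- function(x, ...) {
  cat("<shape_ordination>", nrow(x$scores), "specimens,",
      ncol(x$scores), "axes\n")
  vf <- round(100 * x$variance_fractions[seq_len(min(4, ncol(x$scores)))], 2)
  cat("  variance:", paste0("PC", seq_along(vf), " = ", vf, "%",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Convex hull areas per group in a 2D morphospace
#'
#' @param scores two-column matrix (e.g. PC1/PC2 scores).
#' @param labels group label per row.
#' @return data frame with `group`, `n`, `area`, and `degenerate` (TRUE
#'   when fewer than 3 points or all collinear, in which case area is 0).
#' @export
hull_area <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  groups <- unique(labels)
  res <- lapply(groups, function(g) {
    pts <- scores[labels == g, , drop = FALSE]
    if (nrow(pts) < 3) return(data.frame(group = g, n = nrow(pts), area = 0,
                                         degenerate = TRUE))
    h <- chull(pts)
    a <- polygon_area(pts[h, , drop = FALSE])
    data.frame(group = g, n = nrow(pts), area = a,
               degenerate = a <= .Machine$double.eps)
  })
  out <- do.call(rbind, res)
  if (any(out$degenerate))
    warning("degenerate hull (collinear or < 3 points) for group(s): ",
            paste(out$group[out$degenerate], collapse = ", "))
  out
}

# shoelace formula on hull vertices (any orientation)
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}
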