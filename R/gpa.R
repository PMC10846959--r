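#' Centre and scale a landmark configuration
#'
#' Translates the centroid to the origin and scales to unit centroid size
#' (the root of the summed squared distances of the points from their
#' centroid).  This removes position and size prior to rotation fitting.
#'
#' @param config a `landmark_config` or a k x 2 coordinate matrix.
#' @return same type as the input, normalized.
#' @export
center_and_scale <- function(config) {
  pts <- if (inherits(config, "landmark_config")) config$points else
    as.matrix(config)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  cs <- sqrt(sum(pts^2))
  if (cs < 1e-12) stop("degenerate shape: all points coincident")
  pts <- pts / cs
  if (inherits(config, "landmark_config")) {
    config$points <- pts
    config
  } else pts
}

centroid_size <- function(pts) {
  pts <- sweep(as.matrix(pts), 2, colMeans(pts))
  sqrt(sum(pts^2))
}

#' Optimal rotation of one configuration onto a target
#'
#' Finds the proper rotation (determinant +1; reflections disallowed, since
#' lateral-view bones have handedness) minimizing the summed squared
#' distance to the target.  Both configurations should already be centred
#' and scaled.
#'
#' @param config,target k x 2 coordinate matrices (or `landmark_config`s).
#' @return the rotated configuration, same type as `config`.
#' @export
optimal_rotation <- function(config, target) {
  pts <- if (inherits(config, "landmark_config")) config$points else
    as.matrix(config)
  tgt <- if (inherits(target, "landmark_config")) target$points else
    as.matrix(target)
  sv <- svd(crossprod(tgt, pts))          # 2x2
  s <- diag(c(1, det(sv$u %*% t(sv$v))))
  R <- sv$v %*% s %*% t(sv$u)
  rotated <- pts %*% R
  if (inherits(config, "landmark_config")) {
    config$points <- rotated
    config
  } else rotated
}

#' Slide semi-landmarks along their chords toward a reference
#'
#' Chord-based minimum-d2 sliding: each semi-landmark may move only along
#' its local chord direction (the unit vector between its two neighbours on
#' the curve; curve endpoints use the single chord to their one neighbour),
#' by the closed-form projection that minimizes its squared distance to the
#' corresponding reference point.  Fixed landmarks never move, and sliding
#' never increases the Procrustes distance to the reference.
#'
#' @param config a `landmark_config` (superimposed on `reference`).
#' @param reference 47 x 2 matrix (or `landmark_config`), usually the
#'   current consensus.
#' @return the slid `landmark_config` (not re-normalized).
#' @export
slide_semilandmarks <- function(config, reference) {
  stopifnot(inherits(config, "landmark_config"))
  ref <- if (inherits(reference, "landmark_config")) reference$points else
    as.matrix(reference)
  pts <- config$points
  new_pts <- pts
  for (curve in config$curves) {
    m <- length(curve)
    if (m < 3) stop("curve with fewer than 3 points cannot be slid")
    for (j in seq_len(m)) {
      i <- curve[j]
      nb <- if (j == 1) pts[curve[2], ] - pts[curve[1], ]
            else if (j == m) pts[curve[m], ] - pts[curve[m - 1], ]
            else pts[curve[j + 1], ] - pts[curve[j - 1], ]
      len <- sqrt(sum(nb^2))
      if (len < 1e-12) next                      # degenerate chord: stay put
      u <- nb / len
      t_opt <- sum(u * (ref[i, ] - pts[i, ]))
      new_pts[i, ] <- pts[i, ] + t_opt * u
    }
  }
  config$points <- new_pts
  config
}

#' Generalized Procrustes alignment with optional semi-landmark sliding
#'
#' Iterates superimposition on the consensus, optional chord min-d2 sliding
#' of semi-landmarks, and consensus recomputation until the consensus
#' changes by less than `tol` (root summed squared difference) or
#' `max_iter` is reached.  All configurations must be of the same element.
#'
#' @param configs list of `landmark_config` objects (>= 2).
#' @param slide logical; slide semi-landmarks against the consensus.
#' @param tol convergence tolerance on the consensus.
#' @param max_iter iteration cap.
#' @param max_slide_rounds sliding rounds per iteration.
#' @return object of class `procrustes_alignment` with fields `aligned`
#'   (list of 47 x 2 matrices, centred with unit centroid size),
#'   `consensus` (arithmetic mean of the aligned configurations),
#'   `centroid_sizes` (original sizes), `specimen_ids`, `element`,
#'   `iterations_used` and `converged`.
#' @export
gpa_align <- function(configs, slide = TRUE, tol = 1e-8, max_iter = 100L,
                      max_slide_rounds = 5L) {
  if (length(configs) < 2) stop("need at least 2 configurations")
  els <- unique(vapply(configs, function(cf) cf$element, character(1)))
  if (length(els) > 1)
    stop("mixed elements cannot be aligned together: ",
         paste(els, collapse = ", "))
  sizes <- vapply(configs, function(cf) centroid_size(cf$points), numeric(1))
  work <- lapply(configs, center_and_scale)
  # phase 1: plain GPA to convergence; its consensus does not depend on
  # input order, which keeps the later sliding order-invariant too
  consensus <- work[[1]]$points
  converged <- FALSE
  iters <- 0L
  superimpose <- function(work, consensus) {
    for (it2 in seq_len(max_iter)) {
      iters <<- iters + 1L
      ref <- center_and_scale(consensus)
      work <- lapply(work, optimal_rotation, target = ref)
      new_consensus <- Reduce(`+`, lapply(work, function(cf) cf$points)) /
        length(work)
      delta <- sqrt(sum((new_consensus - consensus)^2))
      consensus <- new_consensus
      if (delta < tol) { converged <<- TRUE; break }
      converged <<- FALSE
    }
    list(work = work, consensus = consensus)
  }
  st <- superimpose(work, consensus)
  work <- st$work; consensus <- st$consensus
  # phase 2: alternate chord min-d2 sliding with re-superimposition
  if (slide) {
    for (round in seq_len(max_slide_rounds)) {
      ref <- center_and_scale(consensus)
      work <- lapply(work, function(cf)
        center_and_scale(slide_semilandmarks(cf, ref)))
      old <- consensus
      st <- superimpose(work, consensus)
      work <- st$work; consensus <- st$consensus
      if (sqrt(sum((consensus - old)^2)) < tol) break
    }
  }
  # canonical orientation (order-invariant): rotate everything so the
  # landmark-1 -> landmark-2 direction of the consensus lies along +x
  v <- consensus[2, ] - consensus[1, ]
  th <- atan2(v[2], v[1])
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  work <- lapply(work, function(cf) { cf$points <- cf$points %*% R; cf })
  consensus <- consensus %*% R
  structure(list(
    aligned = lapply(work, function(cf) cf$points),
    consensus = consensus,
    centroid_sizes = sizes,
    specimen_ids = vapply(configs, function(cf) cf$specimen_id, character(1)),
    element = els,
    curves = configs[[1]]$curves,
    iterations_used = iters,
    converged = converged), class = "procrustes_alignment")
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat("<procrustes_alignment>", length(x$aligned), x$element,
      "configurations;", x$iterations_used, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}
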