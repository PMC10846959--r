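#' Shape parameters for synthetic long-bone outlines
#'
#' Controls the three interpretable deformations of the template outline:
#' signed curvature of the shaft, relative width of the proximal epiphysis,
#' and prominence of a proximo-anterior crest (a deltopectoral/fourth
#' trochanter analogue), plus isotropic landmark jitter.
#'
#' @param shaft_curvature signed real; positive bows the shaft anteriorly.
#' @param head_width positive real; 1 = template epiphysis width.
#' @param crest_prominence non-negative real; 0 = no crest.
#' @param noise_sd non-negative landmark jitter (shape units).
#' @return list of class `shape_params`.
#' @export
shape_params <- function(shaft_curvature = 0, head_width = 1,
                         crest_prominence = 0, noise_sd = 0) {
  if (head_width <= 0) stop("head_width must be > 0")
  if (crest_prominence < 0) stop("crest_prominence must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shaft_curvature = shaft_curvature, head_width = head_width,
                 crest_prominence = crest_prominence, noise_sd = noise_sd),
            class = "shape_params")
}

# Half-width profile of the template bone: wide epiphyses joined by a
# narrow shaft.  t runs 0 (proximal) to 1 (distal).
bone_half_width <- function(t, head_width = 1) {
  0.08 + 0.10 * head_width * exp(-((t - 0) / 0.16)^2) +
    0.10 * exp(-((t - 1) / 0.16)^2)
}

# Localised bump for the anterior crest, peaking at 30% of bone length.
crest_bump <- function(t) exp(-((t - 0.3) / 0.08)^2)

#' Generate a synthetic 47-point long-bone outline
#'
#' Deforms a fixed template outline (two epiphyses joined by a shaft, long
#' axis along x) smoothly by the three shape parameters and adds isotropic
#' Gaussian jitter.  Landmark 1 sits on the proximal head; landmarks 2 and 3
#' on the anterior and posterior distal condyles.  Curve 1 (18 points) runs
#' along the anterior margin, curve 2 (18 points) along the posterior
#' margin, curve 3 (8 points) around the distal end.  Increasing
#' `crest_prominence` strictly increases the area enclosed between curve 1
#' and the shaft chord; negating `shaft_curvature` mirrors the outline
#' about the chord axis (anterior and posterior margins exchange roles).
#'
#' @param params a [shape_params()] object.
#' @param seed integer seed for the jitter (ignored when `noise_sd = 0`
#'   except for reproducibility bookkeeping).
#' @param specimen_id,element passed to [landmark_config()].
#' @return a `landmark_config`.
#' @export
make_bone_outline <- function(params = shape_params(), seed = 1L,
                              specimen_id = "synthetic", element = "femur") {
  stopifnot(inherits(params, "shape_params"))
  c1_t <- seq(0.05, 0.95, length.out = 18)   # anterior margin
  c2_t <- seq(0.95, 0.05, length.out = 18)   # posterior margin (returning)
  c3_t <- seq_len(8) / 9                      # distal cap parameter

  w1 <- bone_half_width(c1_t, params$head_width)
  w2 <- bone_half_width(c2_t, params$head_width)

  bend <- function(t) params$shaft_curvature * sin(pi * t)

  fixed <- rbind(c(0, 0),          # proximal head centre
                 c(1, 0.12),       # distal anterior condyle
                 c(1, -0.12))
  fixed[2, 2] <- fixed[2, 2] + bend(1)
  fixed[3, 2] <- fixed[3, 2] + bend(1)

  curve1 <- cbind(c1_t, w1 + bend(c1_t) +
                          params$crest_prominence * 0.15 * crest_bump(c1_t))
  curve2 <- cbind(c2_t, -w2 + bend(c2_t))
  # distal cap: half-ellipse joining the two condyles beyond x = 1
  ang <- pi / 2 - pi * c3_t                   # from +90 deg to -90 deg
  curve3 <- cbind(1 + 0.06 * cos(ang), 0.12 * sin(ang) + bend(1))

  pts <- rbind(fixed, curve1, curve2, curve3)
  if (params$noise_sd > 0) {
    pts <- with_seed(seed, pts + matrix(rnorm(length(pts), 0, params$noise_sd),
                                        ncol = 2))
  }
  landmark_config(pts, specimen_id = specimen_id, element = element)
}

#' Area between curve 1 and the shaft chord
#'
#' Numerical (trapezoid) area between the anterior margin curve and the
#' chord from the proximal head to the anterior distal condyle.  Used to
#' verify the monotone response of the crest deformation.
#'
#' @param config a `landmark_config`.
#' @return non-negative area (shape units squared).
#' @export
crest_area <- function(config) {
  p <- config$points
  c1 <- p[config$curves[[1]], , drop = FALSE]
  chord_from <- p[1, ]; chord_to <- p[2, ]
  # signed distance of each curve point above the chord line
  d <- chord_to - chord_from
  d <- d / sqrt(sum(d^2))
  nvec <- c(-d[2], d[1])
  h <- (sweep(c1, 2, chord_from) %*% nvec)[, 1]
  s <- (sweep(c1, 2, chord_from) %*% d)[, 1]
  ord <- order(s)
  sum(diff(s[ord]) * (h[ord][-1] + h[ord][-length(h)]) / 2)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
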