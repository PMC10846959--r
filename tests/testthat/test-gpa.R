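test_that("centering and scaling normalize position and size", {
  sq <- matrix(c(4, 4, 6, 4, 6, 6, 4, 6), ncol = 2, byrow = TRUE)
  z <- center_and_scale(sq)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(z^2)), 1, tolerance = 1e-12)
  expect_equal(center_and_scale(z), z, tolerance = 1e-12)  # idempotent
  expect_error(center_and_scale(matrix(1, 47, 2)), "degenerate")
})

test_that("optimal rotation recovers known rotations without reflection", {
  cfg <- center_and_scale(make_bone_outline(seed = 2)$points)
  R90 <- matrix(c(0, 1, -1, 0), 2, 2)
  rot <- optimal_rotation(cfg %*% R90, cfg)
  expect_lt(sum((rot - cfg)^2), 1e-20)
  expect_equal(optimal_rotation(cfg, cfg), cfg, tolerance = 1e-12)
})

test_that("fitted rotation beats every brute-force 1-degree rotation", {
  for (s in 1:5) {
    a <- center_and_scale(matrix(rnorm(94), 47, 2))
    b <- center_and_scale(matrix(rnorm(94), 47, 2))
    fit <- sum((optimal_rotation(a, b) - b)^2)
    brute <- vapply(seq(0, 359) * pi / 180, function(th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sum((a %*% R - b)^2)
    }, numeric(1))
    expect_lte(fit, min(brute) + 1e-10)
  }
})

test_that("GPA aligns similarity-transformed copies to near-zero spread", {
  base <- make_bone_outline(shape_params(crest_prominence = 1), seed = 4)
  configs <- lapply(1:6, function(s) {
    cf <- base
    cf$points <- random_similarity(base$points, seed = s)
    cf$specimen_id <- paste0("c", s)
    cf
  })
  aln <- gpa_align(configs, slide = FALSE)
  expect_true(aln$converged)
  for (m in aln$aligned) {
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sqrt(sum(sweep(m, 2, colMeans(m))^2)), 1,
                 tolerance = 1e-9)
    expect_lt(sqrt(sum((m - aln$aligned[[1]])^2)), 1e-8)
  }
  # consensus is the arithmetic mean of the aligned configurations
  expect_equal(aln$consensus,
               Reduce(`+`, aln$aligned) / length(aln$aligned),
               tolerance = 1e-12)
})

test_that("GPA consensus is invariant to input order", {
  configs <- lapply(1:5, function(s)
    make_bone_outline(shape_params(shaft_curvature = 0.02 * s,
                                   crest_prominence = 0.3 * s,
                                   noise_sd = 0.01), seed = s,
                      specimen_id = paste0("c", s)))
  a <- gpa_align(configs, slide = TRUE)
  b <- gpa_align(rev(configs), slide = TRUE)
  expect_lt(sqrt(sum((a$consensus - b$consensus)^2)), 1e-6)
})

test_that("two-shape consensus is the Procrustes midpoint", {
  c1 <- make_bone_outline(shape_params(shaft_curvature = 0.05), seed = 1)
  c2 <- make_bone_outline(shape_params(shaft_curvature = -0.05), seed = 1)
  aln <- gpa_align(list(c1, c2), slide = FALSE)
  mid <- (aln$aligned[[1]] + aln$aligned[[2]]) / 2
  expect_equal(aln$consensus, mid, tolerance = 1e-10)
  # each aligned shape is optimally rotated onto the consensus already
  r1 <- optimal_rotation(aln$aligned[[1]],
                         center_and_scale(aln$consensus))
  expect_equal(r1, aln$aligned[[1]], tolerance = 1e-6)
})

test_that("mixed elements are rejected", {
  f <- make_bone_outline(seed = 1, element = "femur")
  h <- make_bone_outline(seed = 1, element = "humerus")
  expect_error(gpa_align(list(f, h)), "mixed")
})

test_that("sliding projects offsets along chords and never hurts", {
  ref <- make_bone_outline(shape_params(), seed = 1)
  refn <- center_and_scale(ref)
  # no offset: nothing moves
  slid <- slide_semilandmarks(refn, refn$points)
  expect_equal(slid$points, refn$points, tolerance = 1e-12)

  # an offset purely along the chord is removed entirely
  cfg <- refn
  i <- cfg$curves[[1]][7]
  nb <- cfg$points[cfg$curves[[1]][8], ] - cfg$points[cfg$curves[[1]][6], ]
  u <- nb / sqrt(sum(nb^2))
  cfg$points[i, ] <- cfg$points[i, ] + 0.01 * u
  slid <- slide_semilandmarks(cfg, refn$points)
  expect_lt(sum((slid$points[i, ] - refn$points[i, ])^2), 1e-10)
})

test_that("sliding matches a 201-step brute-force line search per point", {
  ref <- center_and_scale(make_bone_outline(shape_params(), seed = 2))
  cfg <- ref
  set.seed(42)
  cfg$points <- cfg$points + matrix(rnorm(94, 0, 0.004), 47, 2)
  slid <- slide_semilandmarks(cfg, ref$points)
  d_pre <- sum((cfg$points - ref$points)^2)
  d_post <- sum((slid$points - ref$points)^2)
  expect_lte(d_post, d_pre)
  for (curve in cfg$curves) {
    m <- length(curve)
    for (j in seq_along(curve)) {
      i <- curve[j]
      nb <- if (j == 1) cfg$points[curve[2], ] - cfg$points[curve[1], ]
      else if (j == m) cfg$points[curve[m], ] - cfg$points[curve[m - 1], ]
      else cfg$points[curve[j + 1], ] - cfg$points[curve[j - 1], ]
      u <- nb / sqrt(sum(nb^2))
      ts <- seq(-0.05, 0.05, length.out = 201)
      d <- vapply(ts, function(t)
        sum((cfg$points[i, ] + t * u - ref$points[i, ])^2), numeric(1))
      best <- min(d)
      got <- sum((slid$points[i, ] - ref$points[i, ])^2)
      expect_lte(got, best + 1e-6)
    }
  }
  # fixed landmarks never move
  expect_equal(slid$points[1:3, ], cfg$points[1:3, ], tolerance = 0)
})
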