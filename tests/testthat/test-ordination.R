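ord_fixture <- function(n = 8, noise = 0.01, seed0 = 100) {
  configs <- lapply(seq_len(n), function(s)
    make_bone_outline(shape_params(shaft_curvature = 0.03 * (s - n / 2),
                                   crest_prominence = 0.2 * s,
                                   noise_sd = noise),
                      seed = seed0 + s, specimen_id = paste0("c", s)))
  gpa_align(configs, slide = FALSE)
}

test_that("ordination invariants: fractions, ordering, orthogonality", {
  ord <- shape_pca(ord_fixture())
  expect_equal(sum(ord$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  G <- crossprod(ord$loadings)
  expect_equal(G, diag(ncol(ord$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: largest-|loading| entry positive on every axis
  for (j in seq_len(ncol(ord$loadings)))
    expect_gt(ord$loadings[which.max(abs(ord$loadings[, j])), j], 0)
  expect_error(shape_pca(gpa_align(list(make_bone_outline(seed = 1),
                                        make_bone_outline(seed = 1)))),
               "3 specimens")
})

test_that("duplicating every specimen leaves variance fractions unchanged", {
  aln <- ord_fixture(6)
  dup <- aln
  dup$aligned <- c(aln$aligned, aln$aligned)
  dup$specimen_ids <- c(aln$specimen_ids, aln$specimen_ids)
  dup$centroid_sizes <- c(aln$centroid_sizes, aln$centroid_sizes)
  a <- shape_pca(aln); b <- shape_pca(dup)
  k <- min(4, length(a$variance_fractions), length(b$variance_fractions))
  expect_equal(a$variance_fractions[1:k], b$variance_fractions[1:k],
               tolerance = 1e-9)
})

test_that("a single deformation axis yields one nonzero eigenvalue", {
  configs <- lapply(1:6, function(s)
    make_bone_outline(shape_params(crest_prominence = 0.3 * s),
                      seed = 1, specimen_id = paste0("c", s)))
  # skip superimposition noise: identical position/scale already
  aln <- gpa_align(configs, slide = FALSE, tol = 1e-12)
  ord <- shape_pca(aln)
  rel <- ord$all_eigenvalues / ord$all_eigenvalues[1]
  expect_gt(ord$variance_fractions[1], 0.99)
  expect_true(all(rel[-1] < 1e-2))
})

test_that("score distances equal aligned-shape distances (isometry)", {
  aln <- ord_fixture(7)
  ord <- shape_pca(aln)
  flat <- t(vapply(aln$aligned, as.numeric, numeric(94)))
  for (i in 1:6) for (j in (i + 1):7) {
    d_shape <- sqrt(sum((flat[i, ] - flat[j, ])^2))
    d_score <- sqrt(sum((ord$scores[i, ] - ord$scores[j, ])^2))
    expect_equal(d_score, d_shape, tolerance = 1e-8)
  }
})

test_that("similarity transforms of the inputs do not move the ordination", {
  configs <- lapply(1:6, function(s)
    make_bone_outline(shape_params(shaft_curvature = 0.02 * s,
                                   noise_sd = 0.01), seed = s,
                      specimen_id = paste0("c", s)))
  transformed <- lapply(seq_along(configs), function(s) {
    cf <- configs[[s]]
    cf$points <- random_similarity(cf$points, seed = 50 + s)
    cf
  })
  o1 <- shape_pca(gpa_align(configs, slide = FALSE))
  o2 <- shape_pca(gpa_align(transformed, slide = FALSE))
  expect_equal(o1$variance_fractions, o2$variance_fractions,
               tolerance = 1e-8)
  expect_equal(abs(o1$scores), abs(o2$scores), tolerance = 1e-6)
})

test_that("hull areas: square, collinear and brute-force oracle", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  res <- hull_area(sq, rep("g", 4))
  expect_equal(res$area, 1)

  coll <- cbind(1:3, 2 * (1:3))
  expect_warning(res <- hull_area(coll, rep("g", 3)), "degenerate")
  expect_equal(res$area, 0)

  set.seed(8)
  pts <- matrix(rnorm(40), ncol = 2)
  res <- suppressWarnings(hull_area(pts, rep("g", 20)))
  # brute force: max over all triangles cannot exceed hull area; the hull
  # area equals the area of the polygon over extreme points, computed
  # independently via the triangle-fan from the centroid of hull vertices
  h <- chull(pts)
  v <- pts[h, ]
  ctr <- colMeans(v)
  fan <- sum(vapply(seq_len(nrow(v)), function(i) {
    j <- if (i == nrow(v)) 1 else i + 1
    abs((v[i, 1] - ctr[1]) * (v[j, 2] - ctr[2]) -
          (v[j, 1] - ctr[1]) * (v[i, 2] - ctr[2])) / 2
  }, numeric(1)))
  expect_equal(res$area, fan, tolerance = 1e-10)
})
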