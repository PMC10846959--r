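test_that("binary trees pass through polytomy resolution unchanged", {
  tr <- fixture_tree()
  out <- resolve_polytomies(tr, seed = 1)
  expect_true(ape::is.binary.phylo(out))
  expect_equal(as.numeric(phangorn::RF.dist(tr, out)), 0)
})

test_that("a 4-way polytomy resolves uniformly over the 15 topologies", {
  poly <- ape::read.tree(text = "(A,B,C,D);")
  draws <- vapply(1:3000, function(s) {
    out <- resolve_polytomies(poly, seed = s)
    # canonical string: sorted newick of the rooted topology
    canonical_topology(out)
  }, character(1))
  tab <- table(draws)
  expect_equal(length(tab), 15)
  p <- chisq.test(as.numeric(tab))$p.value
  expect_gt(p, 0.01)
  # determinism
  expect_identical(canonical_topology(resolve_polytomies(poly, seed = 7)),
                   canonical_topology(resolve_polytomies(poly, seed = 7)))
})

test_that("MBL time-scaling matches the hand-traced two-tip case", {
  tr <- ape::read.tree(text = "(A,B);")
  dates <- data.frame(species = c("A", "B"), fad = c(250, 240),
                      lad = c(249, 239))
  out <- mbl_timescale(tr, dates, mbl = 0.1)
  ages <- out$ages
  expect_equal(unname(ages[3]), 250.1)
  expect_setequal(round(out$edge.length, 6), c(0.1, 10.1))
  expect_error(mbl_timescale(tr, dates, mbl = 0), "> 0")
})

test_that("equal tip ages give every branch exactly the minimum", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  dates <- data.frame(species = LETTERS[1:4], fad = 230, lad = 229)
  out <- mbl_timescale(tr, dates, mbl = 0.1)
  inner <- out$edge.length[out$edge[, 2] > 4]
  tips <- out$edge.length[out$edge[, 2] <= 4]
  expect_true(all(abs(tips - 0.1) < 1e-12))
  expect_true(all(abs(inner - 0.1) < 1e-12))
})

test_that("sampling-rate draws respect bounds and the analytic mean", {
  r <- vapply(1:1e5, function(i) NA_real_, numeric(1))
  set.seed(1)
  r <- runif(0)  # placeholder to keep the stream explicit below
  draws <- with_seed2(2, vapply(1:1e5, function(i)
    draw_sampling_rate(seed = NULL), numeric(1)))
  expect_gte(min(draws), 0.018)
  expect_lte(max(draws), 0.18)
  expect_equal(mean(draws), 0.099, tolerance = 0.002 / 0.099)
  expect_identical(draw_sampling_rate(seed = 5), draw_sampling_rate(seed = 5))
  custom <- draw_sampling_rate(seed = 1, bounds = c(0.5, 0.6))
  expect_true(custom >= 0.5 && custom <= 0.6)
  expect_error(draw_sampling_rate(bounds = c(0.2, 0.1)), "bounds")
})

test_that("zero-length branches get exactly the 0.0001 Myr fix", {
  tr <- ape::read.tree(text = "(A:0,B:2.5);")
  out <- fix_zlb(tr)
  expect_setequal(out$edge.length, c(0.0001, 2.5))
  tr2 <- ape::read.tree(text = "(A:1,B:2.5);")
  expect_identical(fix_zlb(tr2), tr2)
  expect_error(fix_zlb(tr, epsilon = 0), "> 0")
})

test_that("cal3 draws keep tips inside [LAD, FAD] and branches positive", {
  tr <- random_tree(8, seed = 20)
  tr$edge.length <- NULL
  dates <- data.frame(species = tr$tip.label,
                      fad = seq(250, 236, length.out = 8),
                      lad = seq(248, 234, length.out = 8))
  rates <- cal3_rates(0.1, 0.05, 0.1)
  with_seed2(21, {
    for (i in 1:1000) {
      out <- cal3_timescale(tr, dates, rates, seed = NULL)
      ta <- out$tip_ages[dates$species]
      if (!all(ta >= dates$lad - 1e-9 & ta <= dates$fad + 1e-9))
        fail("tip age outside its stratigraphic range")
      if (!all(out$edge.length > 0)) fail("non-positive branch duration")
      if (!all(out$ages[out$edge[, 1]] > out$ages[out$edge[, 2]]))
        fail("parent not older than child")
    }
  })
  succeed("all 1000 draws satisfied the dating invariants")
})

test_that("higher sampling rates shrink the nodal gaps", {
  tr <- ape::read.tree(text = "(A,B);")
  dates <- data.frame(species = c("A", "B"), fad = c(245, 244),
                      lad = c(244, 243))
  gap_root <- function(rates, seed) {
    out <- cal3_timescale(tr, dates, rates, seed = seed)
    out$ages[3] - max(out$tip_ages)
  }
  lo <- vapply(1:500, function(s)
    gap_root(rates_from_sampling(0.018), seed = s), numeric(1))
  hi <- vapply(1:500, function(s)
    gap_root(rates_from_sampling(10), seed = s), numeric(1))
  expect_lt(median(hi), median(lo))
  expect_lt(median(hi), 0.1)
})

test_that("a tree set records provenance and is reproducible", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  dates <- data.frame(species = LETTERS[1:5],
                      fad = c(250, 247, 244, 241, 238),
                      lad = c(248, 245, 242, 239, 236))
  s1 <- timescale_tree_set(tr, dates, n_trees = 5, seed = 3)
  s2 <- timescale_tree_set(tr, dates, n_trees = 5, seed = 3)
  expect_identical(lapply(s1$trees, ape::write.tree),
                   lapply(s2$trees, ape::write.tree))
  expect_length(s1$provenance, 5)
  expect_true(all(vapply(s1$provenance, function(p)
    p$sampling >= 0.018 && p$sampling <= 0.18, logical(1))))
})
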