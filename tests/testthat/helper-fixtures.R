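# Shared fixtures built in code.

# small valid measurement table
fixture_records <- function() {
  limb_records(
    species = c("Alpha_one", "Beta_two", "Gamma_three", "Delta_four"),
    group = c("dinosaur", "dinosaur", "pseudosuchian", "pseudosuchian"),
    fad = c(230, 225, 228, 210), lad = c(228, 220, 224, 205),
    femur = c(100, 80, 120, 60), tibia = c(90, 70, 100, 50),
    humerus = c(50, 45, 80, 40), radius = c(40, 35, 70, 30),
    metatarsal3 = c(55, 40, 45, 20))
}

# a dated binary phylo written directly from newick
fixture_tree <- function(txt = "((A:1,B:1):1,(C:1,D:1):1);")
  ape::read.tree(text = txt)

# random dated binary tree with strictly positive branch lengths
random_tree <- function(n, seed) {
  with_seed2(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.1
    tr
  })
}

with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# random similarity transform of a 47x2 configuration
random_similarity <- function(pts, seed) {
  with_seed2(seed, {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    s <- runif(1, 0.2, 5)
    tr <- rnorm(2, 0, 10)
    sweep(s * pts %*% R, 2, tr, `+`)
  })
}

# full REML log-likelihood of BM from the covariance matrix (independent
# oracle for the contrasts implementation)
gls_reml_oracle <- function(tree, x, sigma2, scalars = NULL) {
  if (is.null(scalars)) scalars <- rep(1, nrow(tree$edge))
  tr <- tree
  tr$edge.length <- tree$edge.length * scalars
  V <- ape::vcv(tr)
  x <- x[rownames(V)]
  S <- sigma2 * V
  n <- length(x)
  one <- rep(1, n)
  Si <- solve(S)
  XtSX <- as.numeric(t(one) %*% Si %*% one)
  beta <- as.numeric(t(one) %*% Si %*% x) / XtSX
  r <- x - beta
  as.numeric(-0.5 * ((n - 1) * log(2 * pi) +
                       as.numeric(determinant(S, logarithm = TRUE)$modulus) +
                       log(XtSX) + as.numeric(t(r) %*% Si %*% r)))
}

# canonical form of a rooted topology (label-sorted nested parentheses)
canonical_topology <- function(tr) {
  ntip <- length(tr$tip.label)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  rec <- function(v) {
    if (v <= ntip) return(tr$tip.label[v])
    kids <- sort(vapply(children[[as.character(v)]], rec, character(1)))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  rec(ntip + 1L)
}
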