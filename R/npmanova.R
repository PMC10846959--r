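#' Permutational MANOVA on Euclidean distances
#'
#' One-way permutational (non-parametric) MANOVA of multivariate scores
#' against a grouping factor, using Euclidean distances on all supplied
#' axes.  The pseudo-F statistic partitions the total squared distance
#' into among- and within-group components; significance comes from random
#' permutation of the group labels, with
#' `p = (1 + #[F_perm >= F_obs]) / (n_perm + 1)`, so p can never fall
#' below `1 / (n_perm + 1)`.  Pairwise group comparisons repeat the test
#' on each pair of groups and are Bonferroni-adjusted (`p_adj = min(1,
#' p_raw * n_pairs)`).
#'
#' @param scores n x k numeric matrix.
#' @param labels group label per row; >= 2 groups with >= 2 members each
#'   for the global test.  Pairwise tests involving a group with < 2
#'   members are skipped with a warning.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param pairwise compute pairwise comparisons (default TRUE).
#' @return object of class `npmanova_result`: `f_stat`, `p_global`,
#'   `n_permutations`, and `pairwise` (data frame with raw and
#'   Bonferroni-adjusted p per pair, or NULL).
#' @export
npmanova <- function(scores, labels, n_perm = 9999L, seed = 1L,
                     pairwise = TRUE) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) != length(labels))
    stop("labels must match the rows of scores")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 members for the global test")
  d2 <- as.matrix(dist(scores))^2
  res <- with_seed(seed, perm_f_test(d2, labels, n_perm))
  pw <- NULL
  if (pairwise && length(tab) > 2 || pairwise && length(tab) == 2) {
    pairs <- combn(names(tab), 2)
    n_pairs <- ncol(pairs)
    rows <- with_seed(seed + 1L, lapply(seq_len(n_pairs), function(k) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      if (tab[g1] < 2 || tab[g2] < 2) {
        warning("pairwise test ", g1, " vs ", g2,
                " skipped (group with < 2 members)")
        return(data.frame(group1 = g1, group2 = g2, f = NA_real_,
                          p_raw = NA_real_, p_bonf = NA_real_))
      }
      sel <- labels %in% c(g1, g2)
      sub <- perm_f_test(d2[sel, sel, drop = FALSE], labels[sel], n_perm)
      data.frame(group1 = g1, group2 = g2, f = sub$f,
                 p_raw = sub$p, p_bonf = min(1, sub$p * n_pairs))
    }))
    pw <- do.call(rbind, rows)
  }
  structure(list(f_stat = res$f, p_global = res$p, n_permutations = n_perm,
                 pairwise = pw), class = "npmanova_result")
}

# pseudo-F from a squared-distance matrix and its permutation p-value
perm_f_test <- function(d2, labels, n_perm) {
  n <- nrow(d2)
  g <- length(unique(labels))
  f_obs <- pseudo_f(d2, labels)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    if (pseudo_f(d2, perm) >= f_obs - 1e-12) count <- count + 1L
  }
  list(f = f_obs, p = (count + 1) / (n_perm + 1))
}

pseudo_f <- function(d2, labels) {
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(labels)) {
    sel <- labels == g
    ng <- sum(sel)
    ssw <- ssw + sum(d2[sel, sel]) / (2 * ng)
  }
  ssb <- sst - ssw
  g <- length(unique(labels))
  (ssb / (g - 1)) / (ssw / (n - g))
}

#' Exhaustive two-group permutational MANOVA
#'
#' Enumerates all distinct assignments of the observed group sizes to the
#' rows instead of sampling permutations; `p` is the fraction of labelings
#' whose pseudo-F is at least the observed one (the observed labeling
#' included).  Only practical for small samples.
#'
#' @inheritParams npmanova
#' @return list with `f_stat`, `p`, `n_labelings`.
#' @export
npmanova_exhaustive <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) stop("exhaustive test supports exactly 2 groups")
  n <- length(labels)
  n1 <- sum(labels == groups[1])
  d2 <- as.matrix(dist(scores))^2
  f_obs <- pseudo_f(d2, labels)
  sets <- combn(n, n1)
  fs <- apply(sets, 2, function(ii) {
    lab <- rep(groups[2], n)
    lab[ii] <- groups[1]
    pseudo_f(d2, lab)
  })
  list(f_stat = f_obs, p = mean(fs >= f_obs - 1e-12),
       n_labelings = ncol(sets))
}

#' @export
print.npmanova_result <- function(x, ...) {
  cat(sprintf("<npmanova_result> F = %.4g, p = %.4g (%d permutations)\n",
              x$f_stat, x$p_global, x$n_permutations))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
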