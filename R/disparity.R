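#' Assign species to time bins by range overlap
#'
#' A species is assigned to every bin its stratigraphic range overlaps,
#' with bins treated as half-open on their younger edge so a range that
#' only touches a bin's older boundary does not enter it.  Species whose
#' ranges fall entirely outside the scheme are excluded with a warning.
#'
#' @param records a `limb_records` data frame (needs `species`, `fad`,
#'   `lad`).
#' @param scheme a `time_bins` data frame, contiguous, oldest first.
#' @return named list mapping bin label to character vector of species.
#' @export
assign_to_bins <- function(records, scheme) {
  if (nrow(scheme) == 0) stop("empty bin scheme")
  out <- setNames(vector("list", nrow(scheme)), scheme$label)
  assigned <- rep(FALSE, nrow(records))
  for (b in seq_len(nrow(scheme))) {
    hit <- records$fad > scheme$end[b] & records$lad < scheme$start[b]
    out[[b]] <- records$species[hit]
    assigned <- assigned | hit
  }
  if (any(!assigned) && nrow(records) > 0)
    warning("species outside the bin scheme excluded: ",
            paste(records$species[!assigned], collapse = ", "))
  out
}

#' Merge bins with too few species
#'
#' Any bin holding fewer than `min_n` species is combined with its younger
#' neighbour (the youngest bin, having no younger neighbour, merges with
#' its older one), repeating until every bin satisfies `min_n` or a single
#' bin remains.  Species sets are unioned; merged labels are joined with
#' `"+"`.
#'
#' @param binned named list from [assign_to_bins()], ordered oldest first.
#' @param min_n minimum species per bin (default 2).
#' @param scheme optional `time_bins` matching `binned`; if supplied, the
#'   merged scheme is returned alongside.
#' @return list with `bins` (merged named list) and, when `scheme` is
#'   given, `scheme` (merged `time_bins`).
#' @export
merge_sparse_bins <- function(binned, min_n = 2L, scheme = NULL) {
  bins <- binned
  sch <- scheme
  repeat {
    counts <- lengths(bins)
    if (length(bins) <= 1 || all(counts >= min_n)) break
    i <- which(counts < min_n)[1]                 # oldest offending bin
    j <- if (i == length(bins)) i - 1L else i + 1L
    lo <- min(i, j); hi <- max(i, j)
    merged <- union(bins[[lo]], bins[[hi]])
    lab <- paste(names(bins)[lo], names(bins)[hi], sep = "+")
    bins[[lo]] <- merged
    names(bins)[lo] <- lab
    bins[[hi]] <- NULL
    if (!is.null(sch)) {
      sch$end[lo] <- sch$end[hi]
      sch$label[lo] <- lab
      sch <- sch[-hi, ]
      rownames(sch) <- NULL
    }
  }
  if (is.null(scheme)) list(bins = bins) else list(bins = bins, scheme = sch)
}

#' Sum of variances of an ordination-score matrix
#'
#' Disparity as the total sample variance (n - 1 denominator) summed over
#' axes; equal to the trace of the sample covariance matrix.
#'
#' @param scores n x k numeric matrix, n >= 2.
#' @return non-negative scalar.
#' @export
sum_of_variances <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("sum of variances needs at least 2 rows")
  sum(apply(scores, 2, var))
}

#' Bootstrapped sum-of-variances disparity
#'
#' Resamples rows with replacement at the original sample size and reports
#' the percentile interval of the bootstrap distribution of the plain SoV
#' (no rarefaction).
#'
#' @param scores n x k matrix, n >= 2.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf central interval mass (default 0.95).
#' @param bin optional bin label carried through to the result.
#' @return object of class `disparity_estimate`: `bin`, `n_species`,
#'   `sov`, `bootstrap_values`, `ci_low`, `ci_high`.
#' @export
bootstrap_disparity <- function(scores, n_boot = 2000L, seed = 1L,
                                conf = 0.95, bin = NA_character_) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2) stop("bootstrap disparity needs at least 2 rows")
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(idx, 2, function(ii) sum_of_variances(scores[ii, , drop = FALSE]))
  })
  a <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(a, 1 - a)))
  structure(list(bin = bin, n_species = n, sov = sum_of_variances(scores),
                 bootstrap_values = boot, ci_low = ci[1], ci_high = ci[2]),
            class = "disparity_estimate")
}

#' @export
print.disparity_estimate <- function(x, ...) {
  cat(sprintf("<disparity_estimate> %s: n = %d, SoV = %.4g [%.4g, %.4g]\n",
              if (is.na(x$bin)) "(unbinned)" else x$bin,
              x$n_species, x$sov, x$ci_low, x$ci_high))
  invisible(x)
}

#' Disparity through time
#'
#' Convenience wrapper: assigns species to bins, merges sparse bins, and
#' bootstraps the SoV per bin.
#'
#' @param scores matrix with rownames = species.
#' @param records `limb_records` covering the rownames of `scores`.
#' @param scheme a `time_bins` scheme.
#' @param min_n minimum species per bin before merging.
#' @inheritParams bootstrap_disparity
#' @return data frame with one row per (merged) bin: `bin`, `start`, `end`,
#'   `n`, `sov`, `ci_low`, `ci_high`.
#' @export
disparity_through_time <- function(scores, records, scheme = stage_table(),
                                   min_n = 2L, n_boot = 2000L, seed = 1L) {
  binned <- assign_to_bins(records, scheme)
  merged <- merge_sparse_bins(binned, min_n = min_n, scheme = scheme)
  res <- lapply(seq_along(merged$bins), function(i) {
    sp <- intersect(merged$bins[[i]], rownames(scores))
    if (length(sp) < 2) return(NULL)
    est <- bootstrap_disparity(scores[sp, , drop = FALSE], n_boot = n_boot,
                               seed = seed + i,
                               bin = names(merged$bins)[i])
    data.frame(bin = est$bin, start = merged$scheme$start[i],
               end = merged$scheme$end[i], n = est$n_species, sov = est$sov,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), res))
}
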