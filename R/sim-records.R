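#' Simulate limb-measurement tables with planted locomotor-index means
#'
#' Element lengths are back-solved from sampled index values so that the
#' quadrupedality index (humerus + radius) / (femur + tibia) and the
#' cursoriality index metatarsal III / femur recover the planted group
#' means in expectation.  Femur lengths are lognormal to emulate the broad
#' body-size spread of the clade; the tibia is a fixed fraction of the
#' femur and the forelimb is split humerus:radius = 55:45.
#'
#' @param n_per_group integer, species per group (0 allowed).
#' @param group_effects named list mapping group names to
#'   `c(quadrupedality = , cursoriality = )` means, each in (0, 3).
#' @param seed integer seed.
#' @param index_sd standard deviation of the sampled index values.
#' @param age_range `c(oldest, youngest)` Ma; species ranges are placed
#'   uniformly inside it with short durations.
#' @return a `limb_records` data frame.
#' @export
make_limb_records <- function(n_per_group,
                              group_effects = default_group_effects(),
                              seed = 1L, index_sd = 0.1,
                              age_range = c(252, 180)) {
  stopifnot(n_per_group >= 0)
  means <- do.call(rbind, group_effects)
  if (any(means <= 0) || any(means >= 3))
    stop("index means must lie in (0, 3)")
  if (n_per_group == 0)
    return(validate_limb_records(
      data.frame(species = character(0), group = character(0),
                 fad = numeric(0), lad = numeric(0),
                 flying = logical(0), aquatic = logical(0))))
  with_seed(seed, {
    rows <- list()
    for (g in names(group_effects)) {
      q_mu <- group_effects[[g]][["quadrupedality"]]
      c_mu <- group_effects[[g]][["cursoriality"]]
      femur <- rlnorm(n_per_group, log(300), 0.5)       # mm
      q <- truncnorm_pos(n_per_group, q_mu, index_sd)
      cu <- truncnorm_pos(n_per_group, c_mu, index_sd)
      tibia <- 0.85 * femur
      fore <- q * (femur + tibia)
      fad <- runif(n_per_group, age_range[2] + 5, age_range[1])
      dur <- runif(n_per_group, 1, 5)
      rows[[g]] <- data.frame(
        species = paste0(g, "_", seq_len(n_per_group)),
        group = g,
        femur = femur, tibia = tibia, fibula = 0.8 * femur,
        humerus = 0.55 * fore, radius = 0.45 * fore,
        ulna = 0.47 * fore, metatarsal3 = cu * femur,
        fad = fad, lad = pmax(age_range[2], fad - dur),
        flying = FALSE, aquatic = FALSE,
        stringsAsFactors = FALSE)
    }
    validate_limb_records(do.call(rbind, c(rows, make.row.names = FALSE)))
  })
}

#' @rdname make_limb_records
#' @export
default_group_effects <- function() {
  list(non_archosaurian_archosauromorph = c(quadrupedality = 0.9,
                                            cursoriality = 0.45),
       other_avemetatarsalian = c(quadrupedality = 0.7, cursoriality = 0.65),
       dinosaur = c(quadrupedality = 0.6, cursoriality = 0.55),
       pseudosuchian = c(quadrupedality = 0.95, cursoriality = 0.35))
}

# positive draws by resampling the rare non-positive values
truncnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
  x
}
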