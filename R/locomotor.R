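#' Combine specimens of one species onto its largest individual
#'
#' Where several specimens exist for a species, the largest (by femur
#' length, falling back to the longest element shared with the others) is
#' kept and elements known only from smaller specimens are scaled up to it
#' isometrically, using the ratio of a shared element's lengths.
#'
#' @param specimens data frame of one species' specimens: element columns
#'   from [LIMB_ELEMENTS], one row per specimen; other columns are taken
#'   from the largest specimen.
#' @return one-row data frame of merged, scaled element lengths.
#' @export
scale_to_largest <- function(specimens) {
  specimens <- as.data.frame(specimens)
  els <- intersect(LIMB_ELEMENTS, names(specimens))
  if (nrow(specimens) == 1) return(specimens)
  shared <- els[colSums(!is.na(specimens[els])) == nrow(specimens)]
  if (length(shared) == 0)
    stop("no element shared across all specimens; elements present: ",
         paste(els, collapse = ", "))
  ref_el <- if ("femur" %in% shared) "femur"
  else shared[which.max(vapply(shared,
                               function(e) max(specimens[[e]], na.rm = TRUE),
                               numeric(1)))]
  big <- which.max(specimens[[ref_el]])
  out <- specimens[big, , drop = FALSE]
  for (el in els) {
    if (is.na(out[[el]])) {
      donor <- which(!is.na(specimens[[el]]) & !is.na(specimens[[ref_el]]))
      donor <- setdiff(donor, big)
      if (length(donor) > 0) {
        d <- donor[1]
        ratio <- specimens[[ref_el]][big] / specimens[[ref_el]][d]
        out[[el]] <- specimens[[el]][d] * ratio
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Quadrupedality index: (humerus + radius) / (femur + tibia)
#'
#' Relative forelimb to hindlimb length; lower values suggest a more
#' bipedal stance.  `NA` when any of the four elements is missing.
#'
#' @param record one-row data frame or list with element lengths.
#' @return positive scalar or `NA`.
#' @export
quadrupedality_index <- function(record) {
  need <- c("humerus", "radius", "femur", "tibia")
  v <- vapply(need, function(e) {
    x <- record[[e]]
    if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x[1])
  }, numeric(1))
  if (anyNA(v)) return(NA_real_)
  unname((v["humerus"] + v["radius"]) / (v["femur"] + v["tibia"]))
}

#' Cursoriality index: metatarsal III / femur
#'
#' Higher values suggest better running adaptation.  `NA` when either
#' element is missing.
#'
#' @inheritParams quadrupedality_index
#' @return positive scalar or `NA`.
#' @export
cursoriality_index <- function(record) {
  mt <- record[["metatarsal3"]]; fe <- record[["femur"]]
  if (is.null(mt) || is.null(fe) || length(mt) == 0 || length(fe) == 0 ||
      is.na(mt[1]) || is.na(fe[1])) return(NA_real_)
  as.numeric(mt[1]) / as.numeric(fe[1])
}

#' Drop flying and fully aquatic species
#'
#' The locomotor indices only make sense for terrestrial taxa.
#'
#' @param records a `limb_records` data frame.
#' @return filtered records, with an `excluded` attribute listing dropped
#'   species.
#' @export
filter_locomotor_sample <- function(records) {
  drop <- records$flying | records$aquatic
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- records$species[drop]
  out
}

#' Body-size proxy: log10 femur length (mm)
#'
#' @inheritParams quadrupedality_index
#' @return scalar or `NA` when the femur is missing.
#' @export
body_size_proxy <- function(record) {
  fe <- record[["femur"]]
  if (is.null(fe) || length(fe) == 0 || is.na(fe[1])) return(NA_real_)
  log10(as.numeric(fe[1]))
}

#' Locomotor indices for a whole record table
#'
#' @param records a `limb_records` data frame.
#' @param filter drop flying/aquatic species first (default TRUE).
#' @return data frame: `species`, `group`, `quadrupedality`,
#'   `cursoriality`, `body_size` (log10 femur), `age_mid`.
#' @export
locomotor_indices <- function(records, filter = TRUE) {
  if (filter) records <- filter_locomotor_sample(records)
  n <- nrow(records)
  data.frame(
    species = records$species,
    group = records$group,
    quadrupedality = vapply(seq_len(n), function(i)
      quadrupedality_index(records[i, ]), numeric(1)),
    cursoriality = vapply(seq_len(n), function(i)
      cursoriality_index(records[i, ]), numeric(1)),
    body_size = vapply(seq_len(n), function(i)
      body_size_proxy(records[i, ]), numeric(1)),
    age_mid = (records$fad + records$lad) / 2,
    stringsAsFactors = FALSE)
}
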