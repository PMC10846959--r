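#' Landmark configuration for a single limb bone
#'
#' The landmarking scheme places 3 fixed landmarks (proximal head, anterior
#' and posterior distal condyles) and 47 - 3 = 44 semi-landmarks arranged in
#' three ordered curves of 18, 18 and 8 points.  Semi-landmarks are allowed
#' to slide along their outline curve during superimposition.
#'
#' @param points numeric 47 x 2 matrix of digitised coordinates, all finite.
#' @param specimen_id character scalar.
#' @param element one of [LIMB_ELEMENTS].
#' @param curves list of integer vectors partitioning the semi-landmark
#'   indices (1-based rows of `points`) into ordered curves; defaults to
#'   the standard scheme `4:21`, `22:39`, `40:47`.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(points, specimen_id = "specimen",
                            element = "femur", curves = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != 47L || ncol(points) != 2L)
    stop("a landmark configuration must be a 47 x 2 matrix, got ",
         nrow(points), " x ", ncol(points))
  if (!all(is.finite(points))) stop("non-finite landmark coordinates")
  if (is.null(curves)) curves <- default_curves()
  sizes <- vapply(curves, length, integer(1))
  if (!identical(sizes, c(18L, 18L, 8L)))
    stop("curve sizes must be (18, 18, 8), got (",
         paste(sizes, collapse = ", "), ")")
  idx <- sort(unlist(curves))
  if (!identical(idx, 4:47))
    stop("curves must partition semi-landmark indices 4..47")
  structure(list(specimen_id = as.character(specimen_id),
                 element = match.arg(element, LIMB_ELEMENTS),
                 points = unname(points),
                 fixed = 1:3,
                 curves = lapply(curves, as.integer)),
            class = "landmark_config")
}

default_curves <- function() list(4:21, 22:39, 40:47)

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config>", x$specimen_id, "(", x$element, "): 47 points,",
      "3 fixed + curves of", paste(lengths(x$curves), collapse = "/"), "\n")
  invisible(x)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect written by common digitising tools: records start
#' with `LM=47` (or `LM3=`, read as 2D by dropping any third column),
#' followed by one coordinate pair per line; optional `CURVES=`/`POINTS=`
#' blocks define the sliding curves, and `SCALE=` lines are applied
#' multiplicatively.  `ID=` or `IMAGE=` lines name the specimen.
#'
#' @param path path to a TPS file.
#' @param element element name attached to every configuration.
#' @return list of `landmark_config` objects.
#' @export
read_tps <- function(path, element = "femur") {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines)
  if (length(starts) == 0) stop("no LM= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    nlm <- as.integer(sub("^LM3?=", "", chunk[1]))
    if (is.na(nlm) || nlm != 47L)
      stop("record ", k, " in ", path, " has LM=", chunk[1],
           "; expected LM=47")
    is3d <- grepl("^LM3=", chunk[1])
    coord_lines <- chunk[2:(1 + nlm)]
    coords <- lapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[[:space:]]+")[[1]]))
      if (anyNA(v)) stop("non-numeric coordinate line in ", path, ": ", l)
      v
    })
    ncol_expect <- if (is3d) 3L else 2L
    if (any(vapply(coords, length, integer(1)) < 2L))
      stop("coordinate line with fewer than 2 values in ", path)
    pts <- do.call(rbind, lapply(coords, function(v) v[1:min(ncol_expect, length(v))]))
    pts <- pts[, 1:2, drop = FALSE]
    rest <- if (ends[k] >= starts[k] + nlm + 1)
      chunk[(nlm + 2):length(chunk)] else character(0)
    id <- sub("^ID=", "", grep("^ID=", rest, value = TRUE))
    img <- sub("^IMAGE=", "", grep("^IMAGE=", rest, value = TRUE))
    sc <- grep("^SCALE=", rest, value = TRUE)
    if (length(sc) > 0) {
      s <- as.numeric(sub("^SCALE=", "", sc[1]))
      if (is.na(s)) stop("non-numeric SCALE= line in ", path)
      pts <- pts * s
    }
    curves <- NULL
    cl <- grep("^CURVES=", rest, value = TRUE)
    if (length(cl) > 0) {
      pl <- as.integer(sub("^POINTS=", "", grep("^POINTS=", rest, value = TRUE)))
      if (length(pl) == as.integer(sub("^CURVES=", "", cl[1]))) {
        stops <- 3L + cumsum(pl)
        startsc <- c(4L, head(stops, -1) + 1L)
        curves <- Map(seq, startsc, stops)
      }
    }
    sid <- if (length(id) > 0) id[1] else if (length(img) > 0) img[1]
           else paste0("specimen_", k)
    out[[k]] <- landmark_config(pts, specimen_id = sid, element = element,
                                curves = curves)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Emits `LM=47` records with full-precision coordinates, `CURVES=`/
#' `POINTS=` blocks and `ID=` lines, so that [read_tps()] round-trips the
#' coordinates.
#'
#' @param configs a `landmark_config` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    writeLines(sprintf("LM=%d", nrow(cfg$points)), con)
    writeLines(sprintf("%.10f %.10f", cfg$points[, 1], cfg$points[, 2]), con)
    writeLines(sprintf("CURVES=%d", length(cfg$curves)), con)
    writeLines(sprintf("POINTS=%d", lengths(cfg$curves)), con)
    writeLines(sprintf("ID=%s", cfg$specimen_id), con)
  }
  invisible(path)
}
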