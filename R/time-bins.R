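#' Time bins and the packaged stage table
#'
#' Ages are in Ma before present throughout: every interval is written
#' `[start, end]` with `start > end`, so ages decrease toward the present.
#'
#' @param label character labels.
#' @param start,end numeric boundary ages (Ma), `start > end` per bin.
#' @return data frame of class `time_bins` with columns `label`, `start`,
#'   `end`, ordered oldest to youngest.
#' @export
time_bins <- function(label, start, end) {
  df <- data.frame(label = as.character(label), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$start <= df$end))
    stop("each bin must have start > end (ages decrease toward present)")
  df <- df[order(-df$start), ]
  if (nrow(df) > 1) {
    gaps <- abs(df$end[-nrow(df)] - df$start[-1])
    if (any(gaps > 1e-9))
      stop("bins must be contiguous and non-overlapping")
  }
  rownames(df) <- NULL
  class(df) <- unique(c("time_bins", class(df)))
  df
}

#' Geological stage bins, Changhsingian to Toarcian
#'
#' Boundary ages follow the 2019/05 International Chronostratigraphic
#' Chart.  Covers the study interval from the latest Permian through the
#' Early Jurassic (259.1-174.1 Ma); the Changhsingian is extended to the
#' Lopingian base so that the oldest taxa fall inside the scheme.
#'
#' @return a `time_bins` data frame of 13 stages.
#' @export
stage_table <- function() {
  time_bins(
    label = c("Wuchiapingian", "Changhsingian", "Induan", "Olenekian",
              "Anisian", "Ladinian", "Carnian", "Norian", "Rhaetian",
              "Hettangian", "Sinemurian", "Pliensbachian", "Toarcian"),
    start = c(259.1, 254.14, 251.902, 251.2, 247.2, 242, 237, 227, 208.5,
              201.3, 199.3, 190.8, 182.7),
    end   = c(254.14, 251.902, 251.2, 247.2, 242, 237, 227, 208.5, 201.3,
              199.3, 190.8, 182.7, 174.1))
}
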