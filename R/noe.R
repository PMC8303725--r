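# NOESY cross-peak calibration: relative volumes and the isolated-spin-pair
# (r^-6) distance calibration against a reference proton pair.

#' Cross-peak volume as a percentage of the reference volume
#'
#' @param volume cross-peak volume (> 0).
#' @param ref_volume reference cross-peak volume (> 0).
#' @return `100 * volume / ref_volume`.
#' @export
relative_volume_percent <- function(volume, ref_volume) {
  if (any(volume <= 0) || ref_volume <= 0)
    stop("invalid input: cross-peak volumes must be positive")
  100 * volume / ref_volume
}

#' ISPA distance calibration
#'
#' Under the isolated-spin-pair approximation the NOE cross-peak volume
#' scales as r^-6, so a pair's distance follows from the reference pair of
#' known separation: r = r_ref * (V_ref / V)^(1/exponent).
#'
#' @param V cross-peak volume (> 0); vectorised.
#' @param V_ref reference pair volume (> 0).
#' @param r_ref reference pair distance in Angstrom (default 2.47, the
#'   canonical ortho aromatic H-H separation).
#' @param exponent distance exponent (default 6).
#' @return calibrated distance(s) in Angstrom.
#' @export
ispa_distance <- function(V, V_ref, r_ref = 2.47, exponent = 6) {
  if (any(V <= 0) || V_ref <= 0)
    stop("invalid input: volumes must be positive")
  if (r_ref <= 0) stop("r_ref must be positive")
  r_ref * (V_ref / V)^(1 / exponent)
}

#' Read a cross-peak table
#'
#' Tab-separated columns `proton_a, proton_b, volume, is_reference,
#' r_ref_A`; exactly one row must be flagged as the reference pair.
#'
#' @param path TSV file path.
#' @return data frame of class `crosspeak_table` with attribute
#'   `reference` (row index).
#' @export
read_crosspeaks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("proton_a", "proton_b", "volume", "is_reference")
  if (!all(need %in% names(df)))
    stop("cross-peak table must have columns ",
         paste(need, collapse = ", "))
  ref <- which(as.logical(df$is_reference))
  if (length(ref) != 1L)
    stop("exactly one cross-peak must be flagged as the reference pair")
  if (any(df$volume <= 0)) stop("cross-peak volumes must be positive")
  attr(df, "reference") <- ref
  class(df) <- c("crosspeak_table", "data.frame")
  df
}

#' Calibrate every cross-peak in a table to a distance
#'
#' @param peaks a `crosspeak_table` from [read_crosspeaks()].
#' @param r_ref reference distance (Angstrom); defaults to the table's
#'   `r_ref_A` for the reference row, else 2.47.
#' @param exponent ISPA exponent.
#' @return the table with added columns `percent_of_ref` and
#'   `calibrated_distance_A`.
#' @export
calibrate_crosspeaks <- function(peaks, r_ref = NULL, exponent = 6) {
  ref <- attr(peaks, "reference")
  if (is.null(ref)) stop("table lacks a reference pair")
  if (is.null(r_ref)) {
    r_ref <- if ("r_ref_A" %in% names(peaks) &&
                 is.finite(peaks$r_ref_A[ref])) peaks$r_ref_A[ref] else 2.47
  }
  V_ref <- peaks$volume[ref]
  peaks$percent_of_ref <- relative_volume_percent(peaks$volume, V_ref)
  peaks$calibrated_distance_A <-
    ispa_distance(peaks$volume, V_ref, r_ref, exponent)
  peaks
}

#' Chemical-shift perturbation on complex formation
#'
#' Joins free and complexed shift tables on proton id and reports
#' delta_delta = delta_complex - delta_free; negative values (shielding,
#' consistent with aromatic stacking) are labelled low-frequency.
#'
#' @param free,complexed data frames with columns `proton` and `delta_ppm`.
#' @return data frame sorted by decreasing `abs(delta_delta)`, with columns
#'   `proton`, `delta_free`, `delta_complex`, `delta_delta`, `direction`.
#' @export
shift_perturbation <- function(free, complexed) {
  stopifnot(all(c("proton", "delta_ppm") %in% names(free)),
            all(c("proton", "delta_ppm") %in% names(complexed)))
  orphans <- c(setdiff(free$proton, complexed$proton),
               setdiff(complexed$proton, free$proton))
  if (length(orphans) > 0L)
    stop("proton id mismatch between tables: ",
         paste(unique(orphans), collapse = ", "))
  m <- merge(free, complexed, by = "proton",
             suffixes = c("_free", "_complex"))
  out <- data.frame(proton = m$proton,
                    delta_free = m$delta_ppm_free,
                    delta_complex = m$delta_ppm_complex,
                    delta_delta = m$delta_ppm_complex - m$delta_ppm_free)
  out$direction <- ifelse(out$delta_delta < 0, "low-frequency",
                          ifelse(out$delta_delta > 0, "high-frequency",
                                 "unchanged"))
  out[order(-abs(out$delta_delta)), , drop = FALSE]
}
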