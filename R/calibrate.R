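# Nitrogen-based calibration of image-derived protein fractions. Raw
# by-area fractions depend on staining and detection efficiency; a
# conversion factor computed from the chemically measured grain nitrogen
# rescales them so the area-weighted mean over zones equals the measured
# protein concentration. One factor per treatment x experimental replicate
# grouping (per section optionally).

#' Compute the nitrogen-based conversion factor
#'
#' The chemically measured protein fraction is
#' `nitrogen_pct * n_to_protein / 100` and the image-derived fraction is
#' total protein area over total endosperm area; the conversion factor is
#' their ratio, so that applying it to per-zone area fractions reproduces
#' the measured grain protein concentration on average. This orientation is
#' the only one that makes the factor compensate for differences in protein
#' detection efficiency between treatments.
#'
#' @param nitrogen_pct grain nitrogen, percent of dry matter (> 0).
#' @param zone_measurements data.frame from [measure_zones()] (one section,
#'   or several pooled within the calibration grouping).
#' @param n_to_protein multiplier converting nitrogen % to protein %;
#'   default 5.7, the standard factor for wheat. Set 1 when supplying
#'   protein % directly.
#' @return object of class `calibration_record` with fields
#'   `nitrogen_pct`, `n_to_protein`, `measured_protein_fraction`,
#'   `image_protein_fraction`, `conversion_factor`.
#' @export
compute_conversion_factor <- function(nitrogen_pct, zone_measurements,
                                      n_to_protein = 5.7) {
  if (!is.numeric(nitrogen_pct) || nitrogen_pct <= 0)
    stop("nitrogen_pct must be positive", call. = FALSE)
  tot_area <- sum(zone_measurements$zone_area_um2)
  tot_protein <- sum(zone_measurements$protein_area_um2)
  if (tot_area <= 0) stop("total zone area must be positive", call. = FALSE)
  if (tot_protein <= 0)
    stop("zero protein area: calibration undefined", call. = FALSE)
  measured <- nitrogen_pct * n_to_protein / 100
  image_fraction <- tot_protein / tot_area
  structure(list(nitrogen_pct = nitrogen_pct,
                 n_to_protein = n_to_protein,
                 measured_protein_fraction = measured,
                 image_protein_fraction = image_fraction,
                 conversion_factor = measured / image_fraction),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf(paste0("calibration_record: N %.3f%%, protein %.2f%%, ",
                     "image fraction %.4f, factor %.4f\n"),
              x$nitrogen_pct, 100 * x$measured_protein_fraction,
              x$image_protein_fraction, x$conversion_factor))
  invisible(x)
}

#' Apply a conversion factor to per-zone measurements
#'
#' Adds `calibrated_concentration` (percent area-equivalent protein) to the
#' zone table. By construction the area-weighted mean of the calibrated
#' concentrations over zones equals the chemically measured protein
#' percentage exactly; the positive scalar rescaling preserves zone
#' ordering and the sign of the gradient.
#'
#' @param record a [compute_conversion_factor()] result.
#' @param zone_measurements data.frame from [measure_zones()].
#' @return `zone_measurements` with `calibrated_concentration` added.
#' @export
apply_calibration <- function(record, zone_measurements) {
  stopifnot(inherits(record, "calibration_record"))
  zone_measurements$calibrated_concentration <-
    zone_measurements$raw_fraction * record$conversion_factor * 100
  zone_measurements
}
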