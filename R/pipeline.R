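# Batch orchestration: classify -> zones -> bodies -> calibrate -> gradient
# fits over a manifest of sections with replicated training sets. The
# manifest is a CSV (one row per section) pointing at image, mask and ROI
# files and carrying the grouping keys; nitrogen measurements arrive as a
# separate CSV keyed by the calibration grouping.

#' Process a single section with replicated training
#'
#' Runs classification once per training set, then zonation, per-zone
#' measurement and body extraction for every replicate.
#'
#' @param image a [section_image()].
#' @param mask an [endosperm_mask()].
#' @param trainings list of [training_set()] objects.
#' @param K zone count (default 5).
#' @param min_area_px body size filter (default 4).
#' @param regularisation covariance ridge for the classifier.
#' @param section_id identifier attached to all output rows; defaults to
#'   the image id.
#' @return list: `zones` (per-replicate per-zone table), `bodies`
#'   (per-replicate body table), `agreement` (pairwise replicate
#'   agreement, NULL for a single replicate), `partition`.
#' @export
run_section <- function(image, mask, trainings, K = 5L, min_area_px = 4L,
                        regularisation = 1e-3, section_id = NULL) {
  if (is.null(section_id)) section_id <- image$id
  masks <- classify_replicates(image, mask, trainings,
                               regularisation = regularisation)
  partition <- make_zones(mask, K)
  zones <- do.call(rbind, lapply(masks, function(pm) {
    zm <- measure_zones(partition, pm, image$scale)
    cbind(section_id = section_id, zm)
  }))
  bodies <- do.call(rbind, lapply(masks, function(pm) {
    b <- extract_bodies(pm, image$scale, min_area_px = min_area_px)
    b <- body_distances(b, mask, image$scale, partition)
    if (nrow(b) > 0L) cbind(section_id = section_id, b) else NULL
  }))
  agreement <- if (length(masks) >= 2L)
    replicate_agreement(masks, mask) else NULL
  list(zones = zones, bodies = bodies, agreement = agreement,
       partition = partition)
}

#' Run the full analysis over a manifest of sections
#'
#' The manifest needs columns `section_id`, `image`, `mask`, `rois`
#' (one or several ROI file paths separated by `;`, one per classification
#' replicate) plus the grouping columns. `nitrogen` maps each calibration
#' grouping to a grain nitrogen measurement (`nitrogen_pct`). One
#' conversion factor is computed per calibration grouping from the pooled
#' zone measurements of its sections and applied to all of them.
#'
#' Concentration gradients are fitted per analysis grouping on per-zone
#' calibrated concentrations averaged over classification replicates;
#' body-size gradients are fitted on pooled log body areas (replicate ids
#' retained in the exported table).
#'
#' @param manifest data.frame or path to the manifest CSV.
#' @param nitrogen data.frame or CSV path with calibration grouping
#'   columns and `nitrogen_pct`.
#' @param scale micrometres per pixel, applied to every section.
#' @param K zone count.
#' @param min_area_px body size filter.
#' @param n_to_protein nitrogen-to-protein multiplier (default 5.7).
#' @param calib_cols manifest columns defining the calibration grouping
#'   (default `c("treatment", "replicate")`, intersected with what the
#'   manifest has).
#' @param group_cols columns defining the gradient-fit grouping (default
#'   `"treatment"`).
#' @param regularisation classifier covariance ridge.
#' @return list with `per_zone`, `per_body`, `calibration`, `gradients`
#'   (table), `fits` (gradient_fit objects), `agreement`.
#' @export
run_batch <- function(manifest, nitrogen, scale, K = 5L, min_area_px = 4L,
                      n_to_protein = 5.7,
                      calib_cols = c("treatment", "replicate"),
                      group_cols = "treatment",
                      regularisation = 1e-3) {
  if (is.character(manifest)) manifest <- read_table(manifest)
  if (is.character(nitrogen)) nitrogen <- read_table(nitrogen)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  req <- c("section_id", "image", "mask", "rois")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  calib_cols <- intersect(calib_cols, names(manifest))
  if (length(calib_cols) == 0L)
    stop("no calibration grouping columns found in manifest", call. = FALSE)

  per_zone <- NULL; per_body <- NULL; agreement <- NULL
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    image <- load_section(row$image, scale, id = row$section_id)
    mask <- load_mask(row$mask, image_shape(image))
    roi_paths <- trimws(strsplit(row$rois, ";")[[1]])
    trainings <- lapply(seq_along(roi_paths), function(j)
      load_rois(roi_paths[j], image_shape(image), replicate_id = j))
    res <- tryCatch(
      run_section(image, mask, trainings, K = K,
                  min_area_px = min_area_px,
                  regularisation = regularisation,
                  section_id = row$section_id),
      error = function(e) stop("section '", row$section_id, "': ",
                               conditionMessage(e), call. = FALSE))
    meta <- row[, setdiff(names(manifest), req), drop = FALSE]
    rownames(meta) <- NULL
    per_zone <- rbind(per_zone, cbind(res$zones, meta, row.names = NULL))
    if (!is.null(res$bodies))
      per_body <- rbind(per_body, cbind(res$bodies, meta, row.names = NULL))
    if (!is.null(res$agreement))
      agreement <- rbind(agreement,
                         cbind(section_id = row$section_id, res$agreement))
  }

  # calibration: one conversion factor per calibration grouping
  calib_key <- interaction(per_zone[calib_cols], drop = TRUE)
  calibration <- NULL
  per_zone$calibrated_concentration <- NA_real_
  for (gk in levels(calib_key)) {
    rows <- calib_key == gk
    nmatch <- rep(TRUE, nrow(nitrogen))
    for (cc in calib_cols)
      nmatch <- nmatch & nitrogen[[cc]] == per_zone[[cc]][rows][1]
    if (sum(nmatch) == 0L)
      stop("no nitrogen entry for grouping ", gk, call. = FALSE)
    n_pct <- nitrogen$nitrogen_pct[nmatch][1]
    rec <- compute_conversion_factor(n_pct, per_zone[rows, ],
                                     n_to_protein = n_to_protein)
    per_zone$calibrated_concentration[rows] <-
      per_zone$raw_fraction[rows] * rec$conversion_factor * 100
    calibration <- rbind(calibration, data.frame(
      grouping = gk, nitrogen_pct = n_pct,
      image_protein_fraction = rec$image_protein_fraction,
      conversion_factor = rec$conversion_factor))
  }

  # gradient fits per analysis grouping
  group_cols <- intersect(group_cols, names(per_zone))
  fit_key <- interaction(per_zone[group_cols], drop = TRUE)
  fits <- list()
  for (gk in levels(fit_key)) {
    zrows <- per_zone[fit_key == gk, ]
    # average calibrated concentration over classification replicates
    agg <- stats::aggregate(
      calibrated_concentration ~ section_id + zone + mid_distance_um,
      data = zrows, FUN = mean)
    if (nrow(agg) >= 3L && length(unique(agg$mid_distance_um)) >= 2L) {
      f <- fit_gradient(data.frame(distance_um = agg$mid_distance_um,
                                   response = agg$calibrated_concentration),
                        group = gk, response = "concentration")
      if (nrow(agg) >= 4L) f <- quadratic_check(f)
      fits[[paste0(gk, ":concentration")]] <- f
    }
    if (!is.null(per_body)) {
      bkey <- interaction(per_body[group_cols], drop = TRUE)
      brows <- per_body[bkey == gk, ]
      if (nrow(brows) >= 3L &&
          length(unique(brows$distance_um)) >= 2L) {
        f <- fit_gradient(log_transform_areas(brows), group = gk,
                          response = "log_body_area")
        if (nrow(brows) >= 4L) f <- quadratic_check(f)
        fits[[paste0(gk, ":log_body_area")]] <- f
      }
    }
  }
  list(per_zone = per_zone, per_body = per_body,
       calibration = calibration,
       gradients = if (length(fits)) gradient_table(fits) else NULL,
       fits = fits, agreement = agreement)
}

#' Write batch results to a directory of CSV files
#'
#' @param results a [run_batch()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_batch_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(results$per_zone, file.path(dir, "per_zone.csv"))
  if (!is.null(results$per_body))
    write_table(results$per_body, file.path(dir, "per_body.csv"))
  write_table(results$calibration, file.path(dir, "calibration.csv"))
  if (!is.null(results$gradients))
    write_table(results$gradients, file.path(dir, "gradients.csv"))
  if (!is.null(results$agreement))
    write_table(results$agreement, file.path(dir, "agreement.csv"))
  invisible(dir)
}
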