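# Synthetic stained grain sections with exact ground truth. The generator
# emulates the structure of a Naphthol Blue Black stained wheat endosperm
# cross-section: a two-lobed outline with a crease indentation, an
# outer-to-inner gradient in by-area protein fraction, protein bodies whose
# log size decreases with inward distance, dark blue-black stain colour on
# a pale background with Gaussian RGB noise. Bodies are rendered as filled
# ellipses with hard pixel membership (no anti-aliasing), so ground-truth
# areas are exact pixel counts. Bodies are placed as discrete deposits with
# a one-pixel clearance (protein bodies are discrete at mid grain-filling);
# the ground-truth table is nevertheless derived from connected components
# of the rendered protein raster, so any touching deposits would be merged
# exactly as a segmenter sees them.

#' Configuration for a synthetic grain section
#'
#' The defaults describe the generator's standard study conditions: a
#' 1000 x 1500 px canvas at 1 um/px, five zones, a programmed by-area
#' protein fraction falling linearly from 0.20 at the outline to lower
#' values inward (slope -2e-4 per um), and log body area (um^2) falling
#' linearly with inward distance from log(30) (slope -1.5e-3 per um,
#' log-sd 0.5). Stain colours approximate dark blue-black protein on a
#' pale stained background.
#'
#' @param canvas c(H, W) in pixels.
#' @param scale micrometres per pixel.
#' @param K number of concentric zones.
#' @param lobe_radii c(row, col) outline half-axes as fractions of the
#'   canvas.
#' @param crease_depth fractional radial indentation of the crease (0--1).
#' @param crease_width angular width of the crease, radians.
#' @param fraction_intercept,fraction_slope programmed protein area
#'   fraction at the outline and its change per um of inward distance.
#' @param size_meanlog_intercept,size_meanlog_slope,size_sdlog log-normal
#'   body-size law: mean log area (um^2) at the outline, its change per um,
#'   and the log-sd.
#' @param protein_rgb,protein_sd,background_rgb,background_sd stain colour
#'   means (0--255) and per-channel Gaussian sd.
#' @param seed integer; fixes all randomness.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(canvas = c(1000L, 1500L), scale = 1, K = 5L,
                         lobe_radii = c(0.40, 0.45),
                         crease_depth = 0.45, crease_width = 0.35,
                         fraction_intercept = 0.20,
                         fraction_slope = -2e-4,
                         size_meanlog_intercept = log(30),
                         size_meanlog_slope = -1.5e-3,
                         size_sdlog = 0.5,
                         protein_rgb = c(45, 45, 90), protein_sd = 12,
                         background_rgb = c(205, 195, 185),
                         background_sd = 12,
                         seed = 1L) {
  stopifnot(length(canvas) == 2L, all(canvas >= 32), scale > 0, K >= 2,
            crease_depth >= 0, crease_depth < 1,
            size_sdlog >= 0, protein_sd >= 0, background_sd >= 0)
  if (fraction_intercept < 0 || fraction_intercept >= 1)
    stop("fraction_intercept must lie in [0, 1)", call. = FALSE)
  structure(list(canvas = as.integer(canvas), scale = scale,
                 K = as.integer(K),
                 lobe_radii = lobe_radii, crease_depth = crease_depth,
                 crease_width = crease_width,
                 fraction_intercept = fraction_intercept,
                 fraction_slope = fraction_slope,
                 size_meanlog_intercept = size_meanlog_intercept,
                 size_meanlog_slope = size_meanlog_slope,
                 size_sdlog = size_sdlog,
                 protein_rgb = protein_rgb, protein_sd = protein_sd,
                 background_rgb = background_rgb,
                 background_sd = background_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generator presets emulating the trial's treatment contrasts
#'
#' "control" uses a moderate negative gradient; "high_temperature" uses a
#' higher overall fraction and a steeper negative gradient in both
#' concentration and body size, mirroring the direction (not the
#' magnitude) of the temperature effect on endosperm protein distribution.
#'
#' @param treatment preset name.
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_treatment_config <- function(treatment = c("control",
                                                 "high_temperature"),
                                   ...) {
  treatment <- match.arg(treatment)
  args <- if (treatment == "control") {
    list(fraction_intercept = 0.18, fraction_slope = -2e-4,
         size_meanlog_slope = -1.2e-3)
  } else {
    list(fraction_intercept = 0.24, fraction_slope = -3.5e-4,
         size_meanlog_slope = -2.0e-3)
  }
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# Two-lobed endosperm outline: ellipse with a Gaussian radial indentation
# (the crease) centred on the +row direction, giving a concave polygon.
synth_outline <- function(config, n_vertices = 240L) {
  H <- config$canvas[1]; W <- config$canvas[2]
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  ar <- config$lobe_radii[1] * H; ac <- config$lobe_radii[2] * W
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  dip <- 1 - config$crease_depth *
    exp(-((theta - pi / 2) / config$crease_width)^2)
  cbind(cr + ar * sin(theta) * dip, cc + ac * cos(theta) * dip)
}

# k x k binary erosion (square structuring element), used when carving
# training ROIs strictly inside bodies/background.
binary_erode <- function(mask, k = 3L) {
  h <- (k - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L * h, W + 2L * h)
  pad[(h + 1L):(h + H), (h + 1L):(h + W)] <- mask
  out <- matrix(TRUE, H, W)
  for (dr in -h:h) for (dc in -h:h)
    out <- out & pad[(h + 1L + dr):(h + H + dr), (h + 1L + dc):(h + W + dc)]
  out
}

#' Generate a synthetic stained section with ground truth
#'
#' Builds the outline and mask, renders K zones, and fills each zone with
#' elliptical protein bodies until the zone's programmed area fraction is
#' reached. Body centres are drawn uniformly within the zone; each body's
#' area is log-normal with distance-dependent mean. Pixels are coloured
#' with Gaussian RGB noise (clipped to 0--255). Identical config and seed
#' give byte-identical output.
#'
#' @param config a [synth_config()].
#' @return list with `image` ([section_image()]), `mask`
#'   ([endosperm_mask()]), and `truth`: ground-truth body table (merged
#'   components), the true protein raster, programmed and realised
#'   per-zone fractions, the `zone_partition`, and the config.
#' @export
generate_section <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_section_impl(config))
}

generate_section_impl <- function(config) {
  H <- config$canvas[1]; W <- config$canvas[2]
  scale <- config$scale; K <- config$K
  poly <- synth_outline(config)
  mask <- endosperm_mask(rasterise_polygon(poly, c(H, W)), outline = poly)
  partition <- make_zones(mask, K)
  mid_um <- (seq_len(K) - 0.5) * partition$band_width * scale
  f_zone <- config$fraction_intercept + config$fraction_slope * mid_um
  if (any(f_zone < 0) || any(f_zone >= 1))
    stop("programmed per-zone fractions fall outside [0, 1)", call. = FALSE)
  zone_px <- tabulate(partition$zone[partition$zone > 0L], nbins = K)
  target <- round(f_zone * zone_px)
  truth <- matrix(FALSE, H, W)
  covered <- integer(K)
  zone_cells <- split(which(partition$zone > 0L),
                      partition$zone[partition$zone > 0L])
  # Bodies are discrete: a candidate ellipse is rejected unless it keeps a
  # one-pixel clearance from protein already placed, so ground-truth areas
  # follow the drawn size law rather than being clipped or merged away.
  # Placement is deficit-driven across zones, so a body straddling a zone
  # boundary counts toward both zones' programmed coverage.
  iter <- 0L
  max_iter <- 200L * max(1L, ceiling(sum(target) / 4))
  while (any(covered < target)) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("cannot reach programmed fractions: density too high",
           call. = FALSE)
    k <- which.max((target - covered) / zone_px)
    cells <- zone_cells[[as.character(k)]]
    centre <- cells[sample.int(length(cells), 1L)]
    cr <- ((centre - 1L) %% H) + 1L
    cc <- ((centre - 1L) %/% H) + 1L
    d_um <- partition$distance[centre] * scale
    area_um2 <- stats::rlnorm(1, config$size_meanlog_intercept +
                                config$size_meanlog_slope * d_um,
                              config$size_sdlog)
    px <- body_pixels(cr, cc, area_um2 / scale^2, H, W)
    px <- px[mask$region[px]]
    if (length(px) == 0L) next
    if (any(truth[clearance_pixels(px, H, W)])) next  # would touch a body
    truth[px] <- TRUE
    covered <- covered + tabulate(partition$zone[px], nbins = K)
  }
  image <- render_section(truth, mask, config)
  truth_pm <- structure(list(protein = truth, replicate_id = 0L),
                        class = "protein_mask")
  bodies <- extract_bodies(truth_pm, scale, min_area_px = 1L)
  bodies <- body_distances(bodies, mask, scale, partition)
  realised <- measure_zones(partition, truth_pm, scale)
  list(image = image, mask = mask,
       truth = list(bodies = bodies, protein = truth,
                    per_zone_fraction = data.frame(
                      zone = seq_len(K), mid_distance_um = mid_um,
                      programmed_fraction = f_zone,
                      realised_fraction = realised$raw_fraction),
                    zone_measurements = realised,
                    partition = partition, config = config))
}

# Linear indices of a pixel set plus its 8-neighbourhood (clipped to the
# canvas); used for the one-pixel clearance test between bodies.
clearance_pixels <- function(px, H, W) {
  r <- ((px - 1L) %% H) + 1L
  co <- ((px - 1L) %/% H) + 1L
  rr <- rep(r, 9L) + rep(c(-1L, -1L, -1L, 0L, 0L, 0L, 1L, 1L, 1L),
                         each = length(px))
  cc <- rep(co, 9L) + rep(c(-1L, 0L, 1L, -1L, 0L, 1L, -1L, 0L, 1L),
                          each = length(px))
  ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  unique((cc[ok] - 1L) * H + rr[ok])
}

# Pixel linear indices of a filled ellipse of given area (px^2) centred at
# (cr, cc), random aspect and orientation, hard pixel-centre membership.
body_pixels <- function(cr, cc, area_px, H, W) {
  r0 <- sqrt(max(area_px, 1) / pi)
  aspect <- exp(stats::runif(1, -0.35, 0.35))
  rx <- r0 * aspect; ry <- r0 / aspect
  phi <- stats::runif(1, 0, pi)
  h <- ceiling(max(rx, ry))
  off <- seq.int(-h, h)
  dr <- rep(off, times = length(off))
  dc <- rep(off, each = length(off))
  u <- (dr * cos(phi) + dc * sin(phi)) / ry
  v <- (-dr * sin(phi) + dc * cos(phi)) / rx
  keep <- u * u + v * v <= 1
  rr <- cr + dr[keep]; cols <- cc + dc[keep]
  ok <- rr >= 1L & rr <= H & cols >= 1L & cols <= W
  if (!any(ok)) return(integer(0))
  sort((cols[ok] - 1L) * H + rr[ok])
}

render_section <- function(truth, mask, config) {
  H <- nrow(truth); W <- ncol(truth)
  n <- H * W
  px <- array(0L, c(H, W, 3L))
  resin <- c(240, 238, 235)  # unstained resin outside the endosperm
  for (ch in 1:3) {
    base <- matrix(stats::rnorm(n, config$background_rgb[ch],
                                config$background_sd), H, W)
    base[!mask$region] <- resin[ch] +
      stats::rnorm(sum(!mask$region), 0, 3)
    base[truth] <- stats::rnorm(sum(truth), config$protein_rgb[ch],
                                config$protein_sd)
    px[, , ch] <- as.integer(pmin(255, pmax(0, round(base))))
  }
  section_image(px, config$scale,
                id = sprintf("synth_seed%d", config$seed))
}

#' Sample labelled training ROIs from a generated section
#'
#' Emulates the manual protocol of taking training samples from ~10
#' protein areas spread across the grain plus sufficient background areas:
#' protein ROIs are 3 x 3 squares carved strictly inside ground-truth
#' bodies, stratified over the K zones; background ROIs are 5 x 5 squares
#' strictly inside unstained in-mask background. Different seeds give
#' different (replicate) training sets.
#'
#' @param section a [generate_section()] result.
#' @param n_protein,n_background number of ROIs per class.
#' @param seed integer; a different seed per replicate emulates the
#'   triplicate training protocol.
#' @param replicate_id stored on the returned training set.
#' @param background_classes number of background subclass labels the
#'   background ROIs are cycled over (default 1).
#' @return a [training_set()].
#' @export
generate_training_rois <- function(section, n_protein = 10L,
                                   n_background = 10L, seed = 1L,
                                   replicate_id = 1L,
                                   background_classes = 1L) {
  truth <- section$truth$protein
  region <- section$mask$region
  partition <- section$truth$partition
  withr::with_seed(seed, {
    prot_core <- binary_erode(truth, 3L)
    if (!any(prot_core))
      stop("insufficient protein regions to sample ROIs", call. = FALSE)
    bg_core <- binary_erode(region & !truth, 5L)
    if (!any(bg_core))
      stop("insufficient background regions to sample ROIs", call. = FALSE)
    rois <- list()
    # protein ROIs, stratified over zones where possible
    cand <- which(prot_core)
    zones <- partition$zone[cand]
    picked <- 0L; used <- integer(0)
    zcycle <- split(cand, zones)
    zs <- rep(seq_along(zcycle), length.out = n_protein * 4L)
    for (z in zs) {
      if (picked >= n_protein) break
      pool <- zcycle[[z]]
      if (length(pool) == 0L) next
      centre <- pool[sample.int(length(pool), 1L)]
      if (centre %in% used) next
      used <- c(used, centre)
      H <- nrow(truth)
      cr <- ((centre - 1L) %% H) + 1L
      cc <- ((centre - 1L) %/% H) + 1L
      coords <- as.matrix(expand.grid(row = (cr - 1L):(cr + 1L),
                                      col = (cc - 1L):(cc + 1L)))
      picked <- picked + 1L
      rois[[length(rois) + 1L]] <- list(label = "protein", coords = coords)
    }
    if (picked < n_protein)
      stop("insufficient protein regions to sample ", n_protein, " ROIs",
           call. = FALSE)
    bg_cand <- which(bg_core)
    bg_pick <- sample(bg_cand, n_background)
    H <- nrow(truth)
    for (i in seq_len(n_background)) {
      cr <- ((bg_pick[i] - 1L) %% H) + 1L
      cc <- ((bg_pick[i] - 1L) %/% H) + 1L
      coords <- as.matrix(expand.grid(row = (cr - 2L):(cr + 2L),
                                      col = (cc - 2L):(cc + 2L)))
      lbl <- if (background_classes > 1L)
        sprintf("background_%d", ((i - 1L) %% background_classes) + 1L)
      else "background"
      rois[[length(rois) + 1L]] <- list(label = lbl, coords = coords)
    }
    training_set(rois, replicate_id = replicate_id)
  })
}

#' Write training ROIs to a structured-text file
#'
#' Each ROI's pixel block is stored as its bounding polygon so the file
#' round-trips through [load_rois()].
#'
#' @param training a [training_set()] whose ROIs carry coordinates.
#' @param path destination JSON file.
#' @export
write_rois <- function(training, path) {
  stopifnot(inherits(training, "training_set"))
  out <- list()
  for (r in training$rois) {
    co <- r$coords
    poly <- list(c(min(co[, 1]), min(co[, 2])),
                 c(min(co[, 1]), max(co[, 2])),
                 c(max(co[, 1]), max(co[, 2])),
                 c(max(co[, 1]), min(co[, 2])))
    out[[r$label]] <- c(out[[r$label]], list(poly))
  }
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Run the full pipeline on a generated section and score recovery
#'
#' Generates a section, samples `n_replicates` training sets, classifies,
#' measures zones (averaged over replicates) and bodies (first replicate),
#' and reports how well the programmed ground truth is recovered:
#' per-zone fraction errors, body recall/precision under midpoint matching
#' within `match_px` pixels, and relative errors of the fitted
#' concentration-gradient and log-size-gradient slopes.
#'
#' @param config a [synth_config()].
#' @param n_replicates classification replicates (default 3).
#' @param min_area_px body size filter in pixels (default 4).
#' @param match_px midpoint matching tolerance in pixels (default 2).
#' @return list of recovery metrics (see details in the fields themselves):
#'   `zone_table`, `max_zone_fraction_error`, `recall`, `precision`,
#'   `conc_slope_fitted`, `conc_slope_programmed`, `conc_slope_rel_error`,
#'   `size_slope_fitted`, `size_slope_programmed`, `size_slope_rel_error`,
#'   `agreement`, plus the underlying fits.
#' @export
end_to_end_recovery <- function(config, n_replicates = 3L,
                                min_area_px = 4L, match_px = 2) {
  gen <- generate_section(config)
  partition <- gen$truth$partition
  scale <- config$scale
  trainings <- lapply(seq_len(n_replicates), function(i)
    generate_training_rois(gen, seed = (config$seed + 7919L * i) %%
                             2147483647L, replicate_id = i))
  masks <- classify_replicates(gen$image, gen$mask, trainings)
  zms <- lapply(masks, measure_zones, partition = partition, scale = scale)
  avg_fraction <- rowMeans(vapply(zms, function(z) z$raw_fraction,
                                  numeric(partition$K)))
  zone_table <- gen$truth$per_zone_fraction
  zone_table$measured_fraction <- avg_fraction
  zone_table$abs_error <- abs(avg_fraction - zone_table$programmed_fraction)

  bodies <- extract_bodies(masks[[1]], scale, min_area_px = min_area_px)
  bodies <- body_distances(bodies, gen$mask, scale, partition)
  truth_bodies <- gen$truth$bodies
  truth_f <- truth_bodies[truth_bodies$n_px >= min_area_px, , drop = FALSE]
  m <- match_midpoints(truth_f, bodies, match_px)

  conc_fit <- fit_gradient(data.frame(
    distance_um = zone_table$mid_distance_um, response = avg_fraction),
    response = "concentration")
  size_fit <- fit_gradient(log_transform_areas(bodies),
                           response = "log_body_area")
  agr <- if (n_replicates >= 2L)
    mean(replicate_agreement(masks, gen$mask)$agreement) else NA_real_
  list(zone_table = zone_table,
       max_zone_fraction_error = max(zone_table$abs_error),
       recall = m$matched / max(1L, nrow(truth_f)),
       precision = m$matched / max(1L, nrow(bodies)),
       n_truth = nrow(truth_f), n_detected = nrow(bodies),
       conc_slope_fitted = conc_fit$slope,
       conc_slope_programmed = config$fraction_slope,
       conc_slope_rel_error = abs(conc_fit$slope - config$fraction_slope) /
         abs(config$fraction_slope),
       size_slope_fitted = size_fit$slope,
       size_slope_programmed = config$size_meanlog_slope,
       size_slope_rel_error = abs(size_fit$slope -
                                    config$size_meanlog_slope) /
         abs(config$size_meanlog_slope),
       agreement = agr,
       conc_fit = conc_fit, size_fit = size_fit,
       section = gen, protein_masks = masks)
}

# One-to-one nearest matching of body midpoints within `tol` pixels, using
# a coarse grid so the pairing stays near-linear in the body count.
match_midpoints <- function(truth, detected, tol = 2) {
  if (nrow(truth) == 0L || nrow(detected) == 0L)
    return(list(matched = 0L))
  cell <- max(tol, 1)
  key <- function(r, c) paste(floor(r / cell), floor(c / cell))
  det_key <- key(detected$midpoint_row, detected$midpoint_col)
  buckets <- split(seq_len(nrow(detected)), det_key)
  used <- logical(nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth$midpoint_row[i]; tc <- truth$midpoint_col[i]
    cand <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(floor(tr / cell) + dr, floor(tc / cell) + dc)
      cand <- c(cand, buckets[[k]])
    }
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) next
    d <- sqrt((detected$midpoint_row[cand] - tr)^2 +
                (detected$midpoint_col[cand] - tc)^2)
    j <- which.min(d)
    if (d[j] <= tol) {
      used[cand[j]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(matched = matched)
}
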