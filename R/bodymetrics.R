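# Individual protein bodies: 8-connected components of the classified
# protein mask. Each body's area (um^2), pixel-centroid midpoint, and the
# shortest Euclidean distance from that midpoint to the endosperm outline
# are measured; bodies are assigned to the concentric zone their midpoint
# distance falls in.

#' Extract protein bodies from a classified mask
#'
#' Connected components under 8-connectivity (diagonally touching stained
#' pixels belong to one body, reflecting section continuity at 1 um
#' thickness). Components smaller than `min_area_px` pixels are discarded
#' as classification noise; the default of 4 is deliberately permissive
#' because small bodies are abundant in stained sections.
#'
#' @param protein a `protein_mask` (or logical raster).
#' @param scale micrometres per pixel.
#' @param min_area_px minimum component size kept, in pixels; 1 disables
#'   filtering.
#' @return data.frame with columns `body_id`, `n_px`, `area_um2`,
#'   `midpoint_row`, `midpoint_col`, `replicate_id`. Empty mask gives zero
#'   rows.
#' @export
extract_bodies <- function(protein, scale, min_area_px = 4L) {
  pr <- if (inherits(protein, "protein_mask")) protein$protein else protein
  rep_id <- if (inherits(protein, "protein_mask"))
    protein$replicate_id else NA_integer_
  lab <- label_components(pr)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(body_id = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), midpoint_row = numeric(0),
                      midpoint_col = numeric(0), replicate_id = integer(0)))
  idx <- which(pr)
  lb <- lab[idx]
  H <- nrow(pr)
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  npx <- tabulate(lb, nbins = n)
  out <- data.frame(
    body_id = seq_len(n),
    n_px = npx,
    area_um2 = npx * scale^2,
    midpoint_row = rowsum(as.numeric(r), lb)[, 1] / npx,
    midpoint_col = rowsum(as.numeric(co), lb)[, 1] / npx,
    replicate_id = rep_id)
  out <- out[out$n_px >= min_area_px, , drop = FALSE]
  rownames(out) <- NULL
  out$body_id <- seq_len(nrow(out))
  out
}

#' Shortest distance from each body midpoint to the endosperm outline
#'
#' The distance is the minimum over the outline polygon's segments of the
#' point-to-segment Euclidean distance, converted to micrometres. When a
#' zone partition is supplied, each body is also assigned the zone whose
#' band its midpoint distance falls in.
#'
#' @param bodies data.frame from [extract_bodies()].
#' @param mask an [endosperm_mask()] providing the outline.
#' @param scale micrometres per pixel.
#' @param partition optional [make_zones()] result for zone assignment.
#' @return `bodies` with added `distance_um` (and `zone` if `partition`
#'   given).
#' @export
body_distances <- function(bodies, mask, scale, partition = NULL) {
  stopifnot(inherits(mask, "endosperm_mask"))
  if (nrow(bodies) == 0L) {
    bodies$distance_um <- numeric(0)
    if (!is.null(partition)) bodies$zone <- integer(0)
    return(bodies)
  }
  d_px <- dist_to_polygon(bodies$midpoint_row, bodies$midpoint_col,
                          mask$outline)
  # midpoints must lie inside the outline; allow sub-pixel excursions,
  # since an outline traced through boundary pixel centres can leave the
  # centroid of a boundary-hugging body marginally outside the polygon
  ok <- point_in_polygon(bodies$midpoint_row, bodies$midpoint_col,
                         mask$outline) | d_px <= 1
  if (!all(ok))
    stop(sum(!ok), " body midpoint(s) fall outside the endosperm outline",
         call. = FALSE)
  bodies$distance_um <- d_px * scale
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "zone_partition"))
    bodies$zone <- pmin(partition$K,
                        floor(d_px / partition$band_width) + 1L)
  }
  bodies
}

#' Per-zone histograms of protein body size
#'
#' Counts bodies per (zone, size bin). Default bins are 12 log-spaced
#' intervals spanning the observed size range, reflecting the typical
#' abundance of small bodies and scarcity of large ones.
#'
#' @param bodies data.frame with `area_um2` and `zone` columns.
#' @param K number of zones (zones with no bodies still appear).
#' @param bin_edges strictly increasing numeric vector of bin boundaries in
#'   um^2; default log-spaced over the observed range.
#' @param n_bins number of default bins when `bin_edges` is NULL.
#' @return data.frame with columns `zone`, `bin_low`, `bin_high`, `count`.
#' @export
body_size_histograms <- function(bodies, K, bin_edges = NULL, n_bins = 12L) {
  stopifnot(nrow(bodies) == 0L || all(c("area_um2", "zone") %in%
                                        names(bodies)))
  if (is.null(bin_edges)) {
    if (nrow(bodies) == 0L) stop("no bodies and no bin edges", call. = FALSE)
    rng <- range(bodies$area_um2)
    if (rng[1] == rng[2]) rng <- rng * c(0.999, 1.001)
    bin_edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1L))
    bin_edges[1] <- bin_edges[1] * (1 - 1e-9)  # include the smallest body
  }
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with >= 2 values",
         call. = FALSE)
  nb <- length(bin_edges) - 1L
  grid <- expand.grid(bin = seq_len(nb), zone = seq_len(K))
  counts <- integer(nrow(grid))
  if (nrow(bodies) > 0L) {
    bin <- cut(bodies$area_um2, breaks = bin_edges, labels = FALSE,
               include.lowest = TRUE, right = TRUE)
    keep <- !is.na(bin)
    tab <- table(factor(bodies$zone[keep], levels = seq_len(K)),
                 factor(bin[keep], levels = seq_len(nb)))
    counts <- as.integer(t(tab))
  }
  data.frame(zone = grid$zone,
             bin_low = bin_edges[grid$bin],
             bin_high = bin_edges[grid$bin + 1L],
             count = counts)
}
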