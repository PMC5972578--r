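# Reading and writing of section images, endosperm masks, training ROIs and
# result tables. All unit and coordinate conventions are owned here:
# (row, col), 1-based, pixel centres at integer coordinates; physical scale
# is micrometres per pixel and must always be supplied by the user (it is
# never parsed from image metadata).

#' Construct a section image
#'
#' An RGB raster of a stained grain section together with its physical
#' scale. Channel values are integers on 0--255.
#'
#' @param pixels numeric or integer H x W x 3 array, values in 0--255.
#' @param scale micrometres per pixel; positive.
#' @param id free-text section identifier.
#' @return object of class `section_image` with fields `pixels`, `scale`,
#'   `id`.
#' @export
section_image <- function(pixels, scale, id = "section") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("non-RGB image: expected an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("scale must be a positive number (micrometres per pixel)",
         call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must lie in 0..255", call. = FALSE)
  structure(list(pixels = pixels, scale = scale, id = as.character(id)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("section_image '%s': %d x %d px, %.4g um/px\n",
              x$id, d[1], d[2], x$scale))
  invisible(x)
}

#' Dimensions of a section image
#' @param image a `section_image`.
#' @return integer c(H, W).
#' @export
image_shape <- function(image) dim(image$pixels)[1:2]

#' Read a section image from PNG or TIFF
#'
#' @param path image file; format chosen by extension (.png, .tif, .tiff).
#' @param scale micrometres per pixel (always user-supplied).
#' @param id section identifier; defaults to the file name.
#' @return a [section_image()].
#' @export
load_section <- function(path, scale, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read_raster(path)
  if (length(dim(raw)) != 3L || dim(raw)[3] != 3L)
    stop("non-RGB image: ", path, call. = FALSE)
  px <- array(as.integer(round(raw * 255)), dim = dim(raw))
  section_image(px, scale, id = if (is.null(id)) basename(path) else id)
}

#' Write a section image to PNG or TIFF
#'
#' 8-bit lossless output; reading the file back reproduces the pixel values
#' exactly.
#'
#' @param image a `section_image`.
#' @param path destination; format chosen by extension.
#' @export
write_section <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  write_raster(image$pixels / 255, path)
  invisible(path)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  img
}

write_raster <- function(values, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(values, path),
    tif  = ,
    tiff = tiff::writeTIFF(values, path, bits.per.sample = 8L,
                           compression = "none"),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Construct an endosperm mask
#'
#' The region enclosed by the manually drawn outline (drawn just inside the
#' aleurone layer); the source of all inward distances. The region must be
#' one 8-connected component. When built from a polygon, the region is its
#' rasterisation under the pixel-centre-inside rule; when built from a label
#' image, the outline is traced along the region's boundary pixels.
#'
#' @param region logical H x W matrix, TRUE inside the outline.
#' @param outline polygon vertex matrix (row, col); optional when `region`
#'   is given directly, in which case it is traced from the region.
#' @return object of class `endosperm_mask` with fields `region`, `outline`.
#' @export
endosperm_mask <- function(region, outline = NULL) {
  stopifnot(is.matrix(region), is.logical(region))
  if (!any(region)) stop("empty region", call. = FALSE)
  lab <- label_components(region)
  if (max(lab) > 1L) stop("disconnected region", call. = FALSE)
  if (is.null(outline)) outline <- trace_outline(region)
  stopifnot(is.matrix(outline), ncol(outline) == 2)
  structure(list(region = region, outline = outline),
            class = "endosperm_mask")
}

#' @export
print.endosperm_mask <- function(x, ...) {
  cat(sprintf("endosperm_mask: %d x %d canvas, %d px inside, %d-vertex outline\n",
              nrow(x$region), ncol(x$region), sum(x$region), nrow(x$outline)))
  invisible(x)
}

# Boundary trace of a connected region, used when a mask arrives as a
# label image with no polygon: the closed 0.5-level contour of the binary
# raster (marching squares). The contour runs midway between foreground
# and background pixel centres, so every foreground centre lies strictly
# inside it.
trace_outline <- function(region) {
  H <- nrow(region); W <- ncol(region)
  z <- matrix(0, H + 2L, W + 2L)
  z[2:(H + 1L), 2:(W + 1L)] <- region
  cl <- grDevices::contourLines(x = 0:(H + 1L), y = 0:(W + 1L), z = z,
                                levels = 0.5)
  if (length(cl) == 0L) stop("empty region", call. = FALSE)
  best <- cl[[which.max(vapply(cl, function(s) length(s$x), numeric(1)))]]
  verts <- cbind(best$x, best$y)
  # contourLines repeats the first vertex at the end of a closed curve
  n <- nrow(verts)
  if (n > 1L && all(verts[1, ] == verts[n, ])) verts <- verts[-n, , drop = FALSE]
  verts
}

#' Read an endosperm mask from a polygon file or label image
#'
#' Polygon files are structured text (JSON or YAML) with a top-level
#' `vertices` list of `[row, col]` pairs. Label images are 8-bit PNG/TIFF
#' with 0 = outside, 255 (or any non-zero) = inside.
#'
#' @param path polygon (.json/.yaml/.yml) or label image (.png/.tif/.tiff).
#' @param shape canvas dimensions c(H, W); required for polygon input and
#'   checked against label-image input.
#' @return an [endosperm_mask()].
#' @export
load_mask <- function(path, shape) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "yaml", "yml")) {
    spec <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
            else yaml::read_yaml(path)
    verts <- spec$vertices
    if (is.list(verts)) verts <- do.call(rbind, lapply(verts, as.numeric))
    poly <- matrix(as.numeric(verts), ncol = 2)
    region <- rasterise_polygon(poly, shape)
    if (!any(region)) stop("empty region", call. = FALSE)
    endosperm_mask(region, outline = poly)
  } else {
    raw <- read_raster(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    if (!all(dim(raw) == shape)) stop("shape mismatch: mask is ",
      nrow(raw), " x ", ncol(raw), call. = FALSE)
    endosperm_mask(raw > 0.5)
  }
}

#' Write an endosperm mask
#'
#' Polygon masks are written as JSON (`vertices`); `.png`/`.tif` paths get a
#' 0/255 label image.
#' @param mask an `endosperm_mask`.
#' @param path destination file.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "endosperm_mask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(vertices = unname(
      lapply(seq_len(nrow(mask$outline)), function(i) mask$outline[i, ]))),
      path, auto_unbox = FALSE, digits = NA)
  } else {
    write_raster(matrix(as.numeric(mask$region), nrow(mask$region)), path)
  }
  invisible(path)
}

#' Construct a training set of labelled ROIs
#'
#' Each ROI carries a class label and a set of sampled pixels; pixels may be
#' given as (row, col) coordinates (colours are then read from the image at
#' fit time) or directly as RGB triples. Labels in `protein_labels` are
#' treated as stained protein; everything else is a background subclass.
#'
#' @param rois list of lists with fields `label` and either `coords`
#'   (n x 2 matrix, row/col) or `values` (n x 3 RGB matrix, 0--255).
#' @param replicate_id integer >= 1 identifying the training replicate.
#' @param protein_labels character; labels counted as protein. Defaults to
#'   labels starting with "protein".
#' @return object of class `training_set`.
#' @export
training_set <- function(rois, replicate_id = 1L, protein_labels = NULL) {
  stopifnot(is.list(rois), length(rois) >= 2L)
  labels <- vapply(rois, function(r) as.character(r$label), character(1))
  if (is.null(protein_labels))
    protein_labels <- unique(labels[startsWith(labels, "protein")])
  if (length(protein_labels) == 0L)
    stop("training set needs at least one protein ROI", call. = FALSE)
  if (!any(!labels %in% protein_labels))
    stop("training set needs at least one background ROI", call. = FALSE)
  for (r in rois) {
    np <- if (!is.null(r$coords)) nrow(r$coords) else nrow(r$values)
    if (is.null(np) || np < 1L)
      stop("every ROI needs at least one pixel", call. = FALSE)
  }
  structure(list(rois = rois, replicate_id = as.integer(replicate_id),
                 protein_labels = protein_labels),
            class = "training_set")
}

#' Read training ROIs from a structured-text file
#'
#' JSON/YAML mapping each class label to a list of polygons (each a list of
#' `[row, col]` vertices); polygons are rasterised to pixel coordinate sets
#' under the pixel-centre rule.
#'
#' @param path ROI file.
#' @param shape canvas dimensions c(H, W).
#' @param replicate_id training replicate identifier.
#' @return a [training_set()].
#' @export
load_rois <- function(path, shape, replicate_id = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
          else yaml::read_yaml(path)
  rois <- list()
  for (label in names(spec)) {
    polys <- spec[[label]]
    for (p in polys) {
      poly <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
      m <- rasterise_polygon(poly, shape)
      coords <- which(m, arr.ind = TRUE)
      if (nrow(coords) > 0L)
        rois[[length(rois) + 1L]] <- list(label = label, coords = coords)
    }
  }
  training_set(rois, replicate_id = replicate_id)
}

#' Write a result table to CSV
#'
#' UTF-8, header row, '.' decimal separator; numeric values keep full
#' precision so a read--write round trip is byte-identical.
#'
#' @param table data.frame.
#' @param path destination CSV.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(table, utf8, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, encoding = "UTF-8")
}
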