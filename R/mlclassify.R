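# Supervised maximum-likelihood classification of stained-section pixels.
# Each class (protein, or one of possibly several background subclasses) is
# modelled as a multivariate Gaussian over RGB; every in-mask pixel is
# assigned to the class with the largest prior-weighted log density, and the
# protein mask is the union of pixels assigned to protein-labelled classes.

#' Fit a Gaussian class model from labelled training ROIs
#'
#' Pools all ROI pixels sharing a label, computes the sample mean and
#' covariance per class, and regularises the covariance as
#' `cov + regularisation * I`. Priors are equal across classes (no class
#' abundance information is assumed).
#'
#' @param training a [training_set()].
#' @param image a [section_image()]; required when ROIs carry coordinates
#'   rather than RGB values.
#' @param regularisation small positive ridge added to each covariance
#'   diagonal, on the 0--255 intensity scale. Default 1e-3.
#' @return object of class `class_model`: per-class `label`, `mean`,
#'   `cov`, `prior`, plus `protein_labels` and `replicate_id`.
#' @export
fit_class_model <- function(training, image = NULL, regularisation = 1e-3) {
  stopifnot(inherits(training, "training_set"))
  if (regularisation < 0) stop("regularisation must be >= 0", call. = FALSE)
  labels <- vapply(training$rois, function(r) as.character(r$label),
                   character(1))
  ulab <- unique(labels)  # order of first appearance, also the tie order
  pix <- lapply(ulab, function(lb) {
    mats <- lapply(training$rois[labels == lb], function(r) {
      if (!is.null(r$values)) {
        matrix(as.numeric(r$values), ncol = 3)
      } else {
        if (is.null(image))
          stop("ROIs carry coordinates; an image is required", call. = FALSE)
        px <- image$pixels
        cbind(px[cbind(r$coords[, 1], r$coords[, 2], 1)],
              px[cbind(r$coords[, 1], r$coords[, 2], 2)],
              px[cbind(r$coords[, 1], r$coords[, 2], 3)])
      }
    })
    do.call(rbind, mats)
  })
  classes <- vector("list", length(ulab))
  for (i in seq_along(ulab)) {
    X <- pix[[i]]
    if (nrow(X) < 4L)
      stop("class '", ulab[i], "' has fewer than 4 training pixels",
           call. = FALSE)
    S <- stats::cov(X) + diag(regularisation, 3)
    if (regularisation == 0 && rcond_spd(S) < 1e-12)
      stop("degenerate training pixels for class '", ulab[i],
           "' and regularisation = 0", call. = FALSE)
    classes[[i]] <- list(label = ulab[i], mean = colMeans(X), cov = S,
                         prior = 1 / length(ulab))
  }
  structure(list(classes = classes,
                 protein_labels = training$protein_labels,
                 replicate_id = training$replicate_id),
            class = "class_model")
}

rcond_spd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("class_model: %d classes (%s protein), replicate %d\n",
              length(x$classes),
              paste(x$protein_labels, collapse = ", "), x$replicate_id))
  for (cl in x$classes)
    cat(sprintf("  %-14s mean (%5.1f, %5.1f, %5.1f)  prior %.3f\n",
                cl$label, cl$mean[1], cl$mean[2], cl$mean[3], cl$prior))
  invisible(x)
}

# Per-class Gaussian discriminant scores for an N x 3 RGB matrix:
# ln(prior) - 1/2 ln|Sigma| - 1/2 (x - m)' Sigma^-1 (x - m)
class_scores <- function(X, model) {
  scores <- matrix(NA_real_, nrow(X), length(model$classes))
  for (i in seq_along(model$classes)) {
    cl <- model$classes[[i]]
    R <- tryCatch(chol(cl$cov), error = function(e)
      stop("singular covariance for class '", cl$label,
           "': increase regularisation", call. = FALSE))
    logdet <- 2 * sum(log(diag(R)))
    Z <- backsolve(R, t(X) - cl$mean, transpose = TRUE)
    scores[, i] <- log(cl$prior) - 0.5 * logdet - 0.5 * colSums(Z^2)
  }
  scores
}

#' Classify in-mask pixels as protein or background
#'
#' Assigns every pixel inside the endosperm mask to the class with maximal
#' Gaussian discriminant score; ties go to the lowest class index. The
#' returned protein mask is TRUE where the winning class is one of the
#' model's protein labels, and always FALSE outside the endosperm mask.
#'
#' @param image a [section_image()].
#' @param mask an [endosperm_mask()] matching the image shape.
#' @param model a `class_model` from [fit_class_model()].
#' @return object of class `protein_mask`: logical `protein` raster and
#'   `replicate_id`.
#' @export
classify_pixels <- function(image, mask, model) {
  stopifnot(inherits(image, "section_image"),
            inherits(mask, "endosperm_mask"),
            inherits(model, "class_model"))
  shape <- image_shape(image)
  if (!all(dim(mask$region) == shape))
    stop("mask shape does not match image", call. = FALSE)
  idx <- which(mask$region)
  px <- image$pixels
  X <- cbind(as.numeric(px[, , 1][idx]),
             as.numeric(px[, , 2][idx]),
             as.numeric(px[, , 3][idx]))
  assigned <- max.col(class_scores(X, model), ties.method = "first")
  is_protein_class <- vapply(model$classes,
                             function(cl) cl$label %in% model$protein_labels,
                             logical(1))
  protein <- matrix(FALSE, shape[1], shape[2])
  protein[idx] <- is_protein_class[assigned]
  structure(list(protein = protein, replicate_id = model$replicate_id),
            class = "protein_mask")
}

#' @export
print.protein_mask <- function(x, ...) {
  cat(sprintf("protein_mask: %d protein px on %d x %d canvas (replicate %d)\n",
              sum(x$protein), nrow(x$protein), ncol(x$protein),
              x$replicate_id))
  invisible(x)
}

#' Classify with replicated training sets
#'
#' Runs the full fit-and-classify cycle once per training set, mirroring
#' the protocol of analysing each image several times with different
#' training samples.
#'
#' @inheritParams classify_pixels
#' @param trainings list of [training_set()] objects (>= 1).
#' @param regularisation passed to [fit_class_model()].
#' @return list of `protein_mask` objects, replicate ids preserved.
#' @export
classify_replicates <- function(image, mask, trainings,
                                regularisation = 1e-3) {
  stopifnot(length(trainings) >= 1L)
  lapply(trainings, function(tr) {
    model <- fit_class_model(tr, image, regularisation = regularisation)
    classify_pixels(image, mask, model)
  })
}

#' Pairwise agreement between replicate protein masks
#'
#' Descriptive quality-control statistic: for each pair of replicates, the
#' fraction of in-mask pixels on which the two classifications agree.
#'
#' @param masks list of `protein_mask` objects from [classify_replicates()].
#' @param mask the [endosperm_mask()] the replicates were classified under.
#' @return data.frame with columns `rep_a`, `rep_b`, `agreement`.
#' @export
replicate_agreement <- function(masks, mask) {
  stopifnot(length(masks) >= 2L)
  idx <- which(mask$region)
  pairs <- utils::combn(length(masks), 2)
  out <- data.frame(rep_a = integer(0), rep_b = integer(0),
                    agreement = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    agr <- mean(masks[[a]]$protein[idx] == masks[[b]]$protein[idx])
    out[j, ] <- list(masks[[a]]$replicate_id, masks[[b]]$replicate_id, agr)
  }
  out
}

#' Export a protein mask as a 0/255 image for visual checking
#' @param pmask a `protein_mask`.
#' @param path destination PNG/TIFF.
#' @export
write_protein_mask <- function(pmask, path) {
  write_raster(matrix(as.numeric(pmask$protein), nrow(pmask$protein)), path)
  invisible(path)
}
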