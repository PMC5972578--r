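# Independent brute-force oracles and fixture builders. Every oracle here
# is written from the definition, not by calling the code path it checks.

# --- fixtures ---------------------------------------------------------------

# filled disc mask: pixel centres within `radius` of the canvas centre
disc_mask <- function(radius, pad = 4L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  region <- (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
  # circle polygon for the outline
  th <- seq(0, 2 * pi, length.out = 361L)[-361L]
  endosperm_mask(region, outline = cbind(ctr + radius * sin(th),
                                         ctr + radius * cos(th)))
}

# random star-shaped (hence simple, often concave) polygon
random_polygon <- function(n_vertices = 8L, centre = c(16, 16),
                           r_range = c(4, 12)) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  cbind(centre[1] + r * sin(th), centre[2] + r * cos(th))
}

# random binary raster -- used for component labelling, not for masks
random_blob_mask <- function(H = 32L, W = 32L, p = 0.5) {
  matrix(stats::runif(H * W) < p, H, W)
}

# hand-built two-class model on the documented class_model structure
make_model <- function(means, covs, protein = 1L, priors = NULL) {
  k <- length(means)
  if (is.null(priors)) priors <- rep(1 / k, k)
  classes <- lapply(seq_len(k), function(i)
    list(label = if (i %in% protein) paste0("protein", i)
         else paste0("bg", i),
         mean = means[[i]], cov = covs[[i]], prior = priors[i]))
  structure(list(classes = classes,
                 protein_labels = vapply(classes[protein], `[[`,
                                         character(1), "label"),
                 replicate_id = 1L),
            class = "class_model")
}

random_spd <- function(d = 3L, jitter = 0.5) {
  A <- matrix(stats::rnorm(d * d), d, d)
  crossprod(A) + diag(jitter, d)
}

# --- oracles ----------------------------------------------------------------

# stack-based flood fill, 8-connectivity
flood_fill_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# per-pixel Gaussian log-density argmax, scalar arithmetic throughout
brute_classify <- function(X, model) {
  k <- length(model$classes)
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    best <- -Inf; arg <- 0L
    for (j in seq_len(k)) {
      cl <- model$classes[[j]]
      d <- X[i, ] - cl$mean
      s <- log(cl$prior) - 0.5 * log(det(cl$cov)) -
        0.5 * drop(t(d) %*% solve(cl$cov) %*% d)
      if (s > best + 1e-12) { best <- s; arg <- j }
    }
    out[i] <- arg
  }
  out
}

# minimum distance from each in-mask pixel centre to any outside pixel
# centre, the canvas border ring included
brute_distance <- function(region) {
  H <- nrow(region); W <- ncol(region)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- region
  bg <- which(!pad, arr.ind = TRUE)  # includes the border ring
  fg <- which(pad, arr.ind = TRUE)
  d <- matrix(0, H + 2L, W + 2L)
  for (i in seq_len(nrow(fg))) {
    d[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  d[2:(H + 1L), 2:(W + 1L)]
}

# minimum distance from a point to densely sampled boundary points
dense_poly_distance <- function(pr, pc, poly, n_per_edge = 20001L) {
  n <- nrow(poly)
  best <- rep(Inf, length(pr))
  j <- n
  for (i in seq_len(n)) {
    t <- seq(0, 1, length.out = n_per_edge)
    sy <- poly[j, 1] + t * (poly[i, 1] - poly[j, 1])
    sx <- poly[j, 2] + t * (poly[i, 2] - poly[j, 2])
    for (q in seq_along(pr))
      best[q] <- min(best[q], sqrt(min((sy - pr[q])^2 + (sx - pc[q])^2)))
    j <- i
  }
  best
}

# closed-form simple linear regression
ols_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
  sum((x - mean(x))^2)
ols_intercept <- function(x, y) mean(y) - ols_slope(x, y) * mean(x)

# quick protein_mask wrapper for logical rasters
as_pmask <- function(m, rep_id = 1L)
  structure(list(protein = m, replicate_id = rep_id),
            class = "protein_mask")

# small synthetic section shared by slower tests (built once per run)
small_section <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_section(synth_config(canvas = c(220L, 300L),
                                              seed = 42L))
    cache
  }
})
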