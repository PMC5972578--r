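# Low-level raster/vector geometry shared by the mask, zonation and body
# modules. One coordinate convention everywhere: (row, col), 1-based, the
# centre of matrix element (i, j) sits at coordinate (i, j). Polygon vertices
# live in the same frame and polygons are closed implicitly (last vertex
# joins the first).

#' Test whether points lie inside a closed polygon
#'
#' Even-odd (ray-crossing) rule with an inclusive boundary: a point whose
#' distance to the nearest polygon edge is (numerically) zero counts as
#' inside. Vectorised over points; the loop runs over edges.
#'
#' @param pr,pc numeric vectors of point row/col coordinates.
#' @param poly numeric matrix with two columns (row, col) of polygon
#'   vertices, in order, not repeated at the end.
#' @param eps tolerance for the on-edge test, in pixels.
#' @return logical vector, one element per point.
#' @keywords internal
point_in_polygon <- function(pr, pc, poly, eps = 1e-9) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  vy <- poly[, 1]; vx <- poly[, 2]
  inside <- logical(length(pr))
  on_edge <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; xi <- vx[i]; yj <- vy[j]; xj <- vx[j]
    # on-edge test against segment (i, j)
    dy <- yj - yi; dx <- xj - xi
    len2 <- dy * dy + dx * dx
    if (len2 > 0) {
      t <- ((pr - yi) * dy + (pc - xi) * dx) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (pr - (yi + t * dy))^2 + (pc - (xi + t * dx))^2
    } else {
      d2 <- (pr - yi)^2 + (pc - xi)^2
    }
    on_edge <- on_edge | d2 <= eps^2
    # crossing test (ray towards +col)
    crosses <- ((yi > pr) != (yj > pr))
    if (any(crosses)) {
      xcross <- xi + (pr - yi) / (yj - yi) * (xj - xi)
      inside <- xor(inside, crosses & pc < xcross)
    }
    j <- i
  }
  inside | on_edge
}

#' Shortest Euclidean distance from points to a closed polygon boundary
#'
#' Minimum over all polygon edges of the point-to-segment distance.
#' Vectorised over points.
#'
#' @inheritParams point_in_polygon
#' @return numeric vector of distances (same units as the coordinates).
#' @keywords internal
dist_to_polygon <- function(pr, pc, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 2)
  n <- nrow(poly)
  vy <- poly[, 1]; vx <- poly[, 2]
  best <- rep(Inf, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; xi <- vx[i]; yj <- vy[j]; xj <- vx[j]
    dy <- yj - yi; dx <- xj - xi
    len2 <- dy * dy + dx * dx
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((pr - yi) * dy + (pc - xi) * dx) / len2))
      d2 <- (pr - (yi + t * dy))^2 + (pc - (xi + t * dx))^2
    } else {
      d2 <- (pr - yi)^2 + (pc - xi)^2
    }
    best <- pmin(best, d2)
    j <- i
  }
  sqrt(best)
}

#' Rasterise a polygon onto a canvas under the pixel-centre-inside rule
#'
#' @param poly polygon vertex matrix (row, col).
#' @param shape integer vector c(H, W).
#' @return logical H x W matrix; TRUE where the pixel centre is inside the
#'   polygon (boundary inclusive).
#' @keywords internal
rasterise_polygon <- function(poly, shape) {
  H <- shape[1]; W <- shape[2]
  # restrict the point-in-polygon test to the polygon's bounding box
  r0 <- max(1L, floor(min(poly[, 1]))); r1 <- min(H, ceiling(max(poly[, 1])))
  c0 <- max(1L, floor(min(poly[, 2]))); c1 <- min(W, ceiling(max(poly[, 2])))
  out <- matrix(FALSE, H, W)
  if (r0 > r1 || c0 > c1) return(out)
  rr <- seq.int(r0, r1); cc <- seq.int(c0, c1)
  pts_r <- rep(rr, times = length(cc))
  pts_c <- rep(cc, each = length(rr))
  out[cbind(pts_r, pts_c)] <- point_in_polygon(pts_r, pts_c, poly)
  out
}

#' Label 8-connected components of a binary raster
#'
#' Components are connected through edge and corner adjacency
#' (8-connectivity), so two diagonally touching pixels form one component.
#' Labels are renumbered 1..n in order of each component's first pixel in
#' column-major order, for determinism.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background.
#' @keywords internal
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  n <- length(idx)
  if (n == 0L) return(lab)
  vid <- integer(H * W)
  vid[idx] <- seq_len(n)
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  edges <- vector("list", 4L)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    nr <- r + dr; nc <- co + dc
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nidx <- (nc[ok] - 1L) * H + nr[ok]
    hit <- vid[nidx] > 0L
    edges[[k]] <- cbind(vid[idx[ok]][hit], vid[nidx][hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  # renumber by first occurrence (column-major pixel order)
  first <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first]] <- seq_len(sum(first))
  lab[idx] <- renum[memb]
  lab
}
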