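# Protein-body extraction, distances and size histograms.

test_that("a 3x3 square is one body with area 9 and central midpoint", {
  m <- matrix(FALSE, 10, 10); m[4:6, 4:6] <- TRUE
  b <- extract_bodies(as_pmask(m), scale = 1, min_area_px = 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$area_um2, 9)
  expect_equal(c(b$midpoint_row, b$midpoint_col), c(5, 5))
  # area scales with scale^2
  b2 <- extract_bodies(as_pmask(m), scale = 0.5, min_area_px = 1L)
  expect_equal(b2$area_um2, 9 * 0.25)
})

test_that("diagonally touching pixels join into one body; min-area filters", {
  m <- matrix(FALSE, 6, 6); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  b <- extract_bodies(as_pmask(m), 1, min_area_px = 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_px, 2L)
  expect_equal(nrow(extract_bodies(as_pmask(m), 1, min_area_px = 4L)), 0L)
  expect_equal(nrow(extract_bodies(as_pmask(matrix(FALSE, 4, 4)), 1)), 0L)
})

test_that("component count and areas equal the flood-fill oracle", {
  set.seed(41)
  for (i in 1:10) {
    m <- random_blob_mask(24, 24, p = stats::runif(1, 0.2, 0.5))
    b <- extract_bodies(as_pmask(m), 1, min_area_px = 1L)
    want <- flood_fill_label(m)
    expect_equal(nrow(b), max(want), info = paste("case", i))
    expect_equal(sort(b$n_px), sort(as.integer(table(want[want > 0]))),
                 info = paste("areas", i))
    # conservation before filtering
    expect_equal(sum(b$n_px), sum(m))
  }
})

test_that("body distance at the centre of a disc equals the radius x scale", {
  disc <- disc_mask(100, pad = 2L)
  ctr <- 103  # centre pixel coordinate
  b <- data.frame(body_id = 1L, n_px = 1L, area_um2 = 0.25,
                  midpoint_row = ctr, midpoint_col = ctr,
                  replicate_id = 1L)
  out <- body_distances(b, disc, scale = 0.5)
  expect_equal(out$distance_um, 50, tolerance = 1e-3)
})

test_that("distances match the dense-sampling oracle; outside midpoints error", {
  set.seed(59)
  poly <- random_polygon(n_vertices = 7L)
  mask <- endosperm_mask(endograd:::rasterise_polygon(poly, c(32L, 32L)),
                         outline = poly)
  inside <- which(mask$region, arr.ind = TRUE)
  pick <- inside[sample.int(nrow(inside), 8L), ]
  b <- data.frame(body_id = 1:8, n_px = 1L, area_um2 = 1,
                  midpoint_row = pick[, 1], midpoint_col = pick[, 2],
                  replicate_id = 1L)
  out <- body_distances(b, mask, scale = 1.5)
  want <- dense_poly_distance(pick[, 1], pick[, 2], poly) * 1.5
  expect_equal(out$distance_um, want, tolerance = 1e-5)
  bad <- b; bad$midpoint_row[1] <- 1; bad$midpoint_col[1] <- 1
  expect_error(body_distances(bad, mask, 1), "outside")
})

test_that("zone assignment from distance agrees with band boundaries", {
  gen <- small_section()
  bodies <- gen$truth$bodies
  part <- gen$truth$partition
  d_px <- bodies$distance_um / gen$image$scale
  expect_equal(bodies$zone,
               pmin(part$K, floor(d_px / part$band_width) + 1))
  expect_true(all(bodies$distance_um >= 0 &
                    bodies$distance_um <= part$d_max * gen$image$scale))
})

test_that("size histograms conserve body counts per zone", {
  gen <- small_section()
  bodies <- gen$truth$bodies
  h <- body_size_histograms(bodies, K = 5L)
  expect_equal(sum(h$count), nrow(bodies))
  per_zone <- tapply(h$count, h$zone, sum)
  expect_equal(as.integer(per_zone),
               as.integer(table(factor(bodies$zone, levels = 1:5))))
  # one body per zone in one all-covering bin
  one <- data.frame(area_um2 = 1:5, zone = 1:5)
  h1 <- body_size_histograms(one, K = 5L, bin_edges = c(0, 10))
  expect_equal(h1$count, rep(1L, 5))
  expect_error(body_size_histograms(one, 5L, bin_edges = numeric(0)),
               "bin_edges")
  expect_error(body_size_histograms(one, 5L, bin_edges = c(3, 2, 1)),
               "bin_edges")
})

test_that("log size histograms on synthetic truth match the generator's bodies", {
  gen <- small_section()
  bodies <- gen$truth$bodies
  edges <- exp(seq(log(min(bodies$area_um2)) - 1e-9,
                   log(max(bodies$area_um2)) + 1e-9, length.out = 13))
  h <- body_size_histograms(bodies, K = 5L, bin_edges = edges)
  manual <- table(factor(bodies$zone, levels = 1:5),
                  cut(bodies$area_um2, edges))
  expect_equal(sum(h$count), sum(manual))
  expect_equal(as.integer(tapply(h$count, h$zone, sum)),
               as.integer(rowSums(manual)))
})
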