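# Distance transform, concentric zonation and per-zone measurement.

test_that("distance transform equals brute-force nearest-background scan", {
  set.seed(17)
  # disc, random polygon masks, and an all-true canvas
  masks <- list(disc_mask(6)$region,
                endograd:::rasterise_polygon(random_polygon(), c(32L, 32L)),
                matrix(TRUE, 5, 7))
  for (i in seq_along(masks)) {
    region <- masks[[i]]
    m <- endosperm_mask(region)
    expect_equal(distance_to_outline(m), brute_distance(region),
                 info = paste("mask", i))
  }
})

test_that("border rule and adjacency give distance 1", {
  m <- endosperm_mask(matrix(TRUE, 1, 1))
  expect_equal(distance_to_outline(m), matrix(1, 1, 1))
  disc <- disc_mask(5)
  d <- distance_to_outline(disc)
  edge <- disc$region & !endograd:::binary_erode(disc$region, 3L)
  expect_true(all(d[edge] >= 1 & d[edge] <= sqrt(2)))
})

test_that("disc centre distance is within a pixel of the radius", {
  disc <- disc_mask(20)
  d <- distance_to_outline(disc)
  expect_lt(abs(max(d) - 20), 1.5)
})

test_that("zones partition the mask into equal-width annuli", {
  disc <- disc_mask(50, pad = 3L)
  z <- make_zones(disc, 5L)
  expect_equal(sort(unique(as.vector(z$zone[disc$region]))), 1:5)
  expect_equal(sum(tabulate(z$zone[z$zone > 0], 5)), sum(disc$region))
  # analytic annulus areas: zone k of a disc radius R with bands R/K wide
  R <- z$d_max
  areas <- tabulate(z$zone[z$zone > 0], 5)
  analytic <- sapply(1:5, function(k)
    pi * ((R - (k - 1) * R / 5)^2 - (R - k * R / 5)^2))
  expect_equal(areas / sum(areas), analytic / sum(analytic),
               tolerance = 0.02)
  expect_true(all(diff(areas) < 0))  # strictly decreasing outward-in
  # zone index non-decreasing in distance
  d <- z$distance
  expect_true(all(diff(tapply(d[disc$region], z$zone[disc$region],
                              mean)) > 0))
})

test_that("degenerate zone requests are rejected", {
  disc <- disc_mask(10)
  expect_error(make_zones(disc, 1L), "K must be")
  expect_error(make_zones(disc, 5.5), "K must be")
})

test_that("full and empty protein masks give fractions 1 and 0", {
  disc <- disc_mask(15)
  z <- make_zones(disc, 4L)
  full <- measure_zones(z, as_pmask(disc$region), scale = 2)
  expect_equal(full$raw_fraction, rep(1, 4))
  expect_equal(sum(full$zone_area_um2), sum(disc$region) * 4)
  empty <- measure_zones(z, as_pmask(matrix(FALSE, nrow(disc$region),
                                            ncol(disc$region))), scale = 2)
  expect_equal(empty$raw_fraction, rep(0, 4))
  # mid distances follow (k - 1/2) * band_width * scale
  expect_equal(full$mid_distance_um,
               (1:4 - 0.5) * z$band_width * 2)
})

test_that("areas scale as scale^2 and distances as scale; fractions invariant", {
  disc <- disc_mask(12)
  z <- make_zones(disc, 3L)
  pm <- as_pmask(disc$region & matrix(stats::runif(length(disc$region)) < 0.3,
                                      nrow(disc$region)))
  a <- measure_zones(z, pm, scale = 1)
  b <- measure_zones(z, pm, scale = 2)
  expect_equal(b$mid_distance_um, 2 * a$mid_distance_um)
  expect_equal(b$zone_area_um2, 4 * a$zone_area_um2)
  expect_equal(b$raw_fraction, a$raw_fraction)
})

test_that("per-zone fraction and area conservation hold on synthetic truth", {
  gen <- small_section()
  z <- gen$truth$partition
  zm <- gen$truth$zone_measurements
  expect_equal(sum(zm$zone_area_um2),
               sum(gen$mask$region) * gen$image$scale^2)
  expect_equal(sum(zm$protein_area_um2),
               sum(gen$truth$protein) * gen$image$scale^2)
  expect_true(all(zm$raw_fraction >= 0 & zm$raw_fraction <= 1))
})

test_that("zone-count selection matches an exhaustive manual sweep", {
  set.seed(71)
  disc <- disc_mask(30)
  d <- distance_to_outline(disc)
  # distance-dependent random protein: decreasing fraction inward
  p <- pmax(0.05, 0.4 - 0.012 * d)
  pm <- as_pmask(disc$region &
                   matrix(stats::runif(length(d)) < p, nrow(d)))
  got <- choose_zone_count(disc, pm, candidates = 3:7)
  manual <- sapply(3:7, function(K) {
    zm <- measure_zones(make_zones(disc, K), pm, 1)
    x <- zm$mid_distance_um; y <- zm$raw_fraction
    1 - sum((y - (ols_intercept(x, y) + ols_slope(x, y) * x))^2) /
      sum((y - mean(y))^2)
  })
  expect_equal(as.integer(got), (3:7)[which.max(manual)])
  expect_equal(unname(attr(got, "scores")), manual, tolerance = 1e-10)
  # single candidate and the tie rule
  expect_equal(as.integer(choose_zone_count(disc, pm, candidates = 5L)), 5L)
  full <- as_pmask(disc$region)  # constant fractions: all scores tie at 0
  expect_equal(as.integer(choose_zone_count(disc, full)), 5L)
  expect_error(choose_zone_count(disc, pm, candidates = integer(0)),
               "empty candidate")
})
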