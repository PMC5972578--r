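# Gaussian maximum-likelihood pixel classification.

test_that("class means, regularisation and equal priors follow the fit rules", {
  vals <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  tr <- training_set(list(
    list(label = "protein", values = vals),
    list(label = "background", values = vals + 100)), replicate_id = 1L)
  m <- fit_class_model(tr, regularisation = 1e-3)
  expect_equal(m$classes[[1]]$mean, c(0.5, 0.5, 0.5))
  expect_equal(m$classes[[1]]$prior, 0.5)
  expect_equal(m$classes[[2]]$prior, 0.5)
  # single-colour class: covariance collapses to eps * I
  tr2 <- training_set(list(
    list(label = "protein", values = matrix(7, 5, 3)),
    list(label = "background", values = vals)), replicate_id = 1L)
  m2 <- fit_class_model(tr2, regularisation = 1e-3)
  expect_equal(m2$classes[[1]]$cov, diag(1e-3, 3))
  expect_error(fit_class_model(tr2, regularisation = 0), "degenerate")
  # too few pixels per class
  tr3 <- training_set(list(
    list(label = "protein", values = vals[1:3, ]),
    list(label = "background", values = vals)), replicate_id = 1L)
  expect_error(fit_class_model(tr3), "fewer than 4")
})

test_that("classification equals brute-force Gaussian log-density argmax", {
  set.seed(31)
  for (case in 1:12) {
    H <- 8L; W <- 8L
    px <- array(sample.int(256, H * W * 3, replace = TRUE) - 1L, c(H, W, 3))
    img <- section_image(px, 1)
    mask <- endosperm_mask(matrix(TRUE, H, W))
    k <- sample(2:4, 1)
    model <- make_model(
      means = lapply(seq_len(k), function(i) stats::runif(3, 0, 255)),
      covs = lapply(seq_len(k), function(i) random_spd(3, 50)),
      protein = 1L)
    got <- classify_pixels(img, mask, model)
    X <- cbind(as.numeric(px[, , 1]), as.numeric(px[, , 2]),
               as.numeric(px[, , 3]))
    want <- brute_classify(X, model) == 1L
    expect_equal(as.vector(got$protein), want, info = paste("case", case))
  }
})

test_that("pixel at a class mean is assigned there; ties go to the lowest index", {
  S <- diag(100, 3)
  model <- make_model(means = list(c(50, 50, 50), c(200, 200, 200)),
                      covs = list(S, S), protein = 1L)
  px <- array(0L, c(1, 2, 3))
  px[1, 1, ] <- c(50L, 50L, 50L)     # exactly the protein mean
  px[1, 2, ] <- c(125L, 125L, 125L)  # equidistant between the two means
  img <- section_image(px, 1)
  mask <- endosperm_mask(matrix(TRUE, 1, 2))
  got <- classify_pixels(img, mask, model)
  expect_true(got$protein[1, 1])
  expect_true(got$protein[1, 2])  # tie resolved toward class 1 (protein)
})

test_that("protein mask is always contained in the endosperm mask", {
  gen <- small_section()
  tr <- generate_training_rois(gen, seed = 5L)
  model <- fit_class_model(tr, gen$image)
  pm <- classify_pixels(gen$image, gen$mask, model)
  expect_false(any(pm$protein & !gen$mask$region))
})

test_that("replicated training produces one mask per set, ids preserved", {
  gen <- small_section()
  tr1 <- generate_training_rois(gen, seed = 1L, replicate_id = 1L)
  masks1 <- classify_replicates(gen$image, gen$mask, list(tr1))
  expect_length(masks1, 1L)
  trs <- lapply(1:3, function(i)
    generate_training_rois(gen, seed = 1L, replicate_id = i))
  masks <- classify_replicates(gen$image, gen$mask, trs)
  expect_equal(vapply(masks, `[[`, integer(1), "replicate_id"), 1:3)
  # identical training sets give identical masks
  expect_identical(masks[[1]]$protein, masks[[2]]$protein)
  expect_identical(masks[[1]]$protein, masks[[3]]$protein)
})

test_that("replicates with well-separated stain colours agree on >= 99% of pixels", {
  gen <- small_section()
  trs <- lapply(1:3, function(i)
    generate_training_rois(gen, seed = 100L + i, replicate_id = i))
  masks <- classify_replicates(gen$image, gen$mask, trs)
  agr <- replicate_agreement(masks, gen$mask)
  expect_true(all(agr$agreement >= 0.99))
})

test_that("increasing colour separation never decreases accuracy", {
  cfg0 <- synth_config(canvas = c(150L, 200L), seed = 9L)
  truth_ref <- NULL
  acc <- vapply(c(0.03, 0.1, 0.3, 1.0), function(s) {
    prot <- cfg0$background_rgb + s * (cfg0$protein_rgb - cfg0$background_rgb)
    cfg <- synth_config(canvas = c(150L, 200L), seed = 9L,
                        protein_rgb = prot)
    gen <- generate_section(cfg)
    if (is.null(truth_ref)) truth_ref <<- gen$truth$protein
    expect_identical(gen$truth$protein, truth_ref)  # same geometry
    tr <- generate_training_rois(gen, seed = 77L)
    pm <- classify_pixels(gen$image, gen$mask, fit_class_model(tr, gen$image))
    idx <- which(gen$mask$region)
    mean(pm$protein[idx] == gen$truth$protein[idx])
  }, numeric(1))
  expect_true(all(diff(acc) >= -1e-4))
  expect_gt(acc[4], 0.99)
})

test_that("classifier agrees with quadratic discriminant analysis", {
  skip_if_not_installed("MASS")
  set.seed(53)
  n <- 200L
  Xa <- matrix(stats::rnorm(n * 3, 60, 15), ncol = 3)
  Xb <- matrix(stats::rnorm(n * 3, 180, 25), ncol = 3)
  tr <- training_set(list(list(label = "protein", values = Xa),
                          list(label = "background", values = Xb)))
  model <- fit_class_model(tr, regularisation = 0)
  q <- MASS::qda(rbind(Xa, Xb),
                 grouping = rep(c("protein", "background"), each = n),
                 prior = c(0.5, 0.5))
  Xt <- matrix(stats::runif(300 * 3, 0, 255), ncol = 3)
  got <- max.col(endograd:::class_scores(Xt, model),
                 ties.method = "first") == 1L
  want <- predict(q, Xt)$class == "protein"
  expect_equal(got, as.vector(want))
})
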