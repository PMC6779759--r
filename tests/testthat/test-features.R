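test_that("cosine distance matches closed forms and rejects degenerate input", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 0)), 1 - 1 / sqrt(2))
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_distance(c(1, 1), c(1, 1, 1)), "length")
})

test_that("cosine distances on nonnegative vectors are a bounded semimetric", {
  set.seed(10)
  for (i in 1:100) {
    u <- runif(8); v <- runif(8)
    d <- cosine_distance(u, v)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, cosine_distance(v, u))
    expect_equal(d, bf_cosine(u, v), tolerance = 1e-12)
  }
  X <- rand_features(12, 6)
  D <- cosine_dist_matrix(X)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 12), ignore_attr = TRUE)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(D[i, j], bf_cosine(X[i, ], X[j, ]), tolerance = 1e-12)
  }
})

test_that("embeddings are deterministic and exactly mirror-invariant", {
  cfg <- tiny_config(n_species = 10, images_per_species = c(1, 1), seed = 41)
  ds <- generate_dataset(cfg)
  for (id in ds$metadata$image_id) {
    img <- ds$images[[id]]; pm <- ds$masks[[id]]
    v1 <- embed_specimen(img, part_mask = pm)
    expect_identical(v1, embed_specimen(img, part_mask = pm))
    v_mirror <- embed_specimen(mirror_image(img), part_mask = mirror_mask(pm))
    expect_equal(v1, v_mirror, tolerance = 1e-10)
    expect_true(all(v1 >= 0))
    expect_gt(sum(v1), 0)
  }
})

test_that("silhouette embeddings ignore colour; greyscale embeddings ignore hue", {
  cfg <- tiny_config(n_species = 2, images_per_species = c(1, 1), seed = 43,
                     pixel_noise_sd = 0)
  pool <- generate_species_pool(cfg)
  spec_a <- pool[1, ]
  spec_b <- spec_a
  spec_b$base_h <- (spec_a$base_h + 140) %% 360
  spec_b$base_v <- 0.25
  set.seed(1); ra <- render_specimen(spec_a, cfg)
  set.seed(1); rb <- render_specimen(spec_b, cfg)
  sa <- embed_specimen(ra$image, part_mask = ra$mask, variant = "silhouette")
  sb <- embed_specimen(rb$image, part_mask = rb$mask, variant = "silhouette")
  expect_equal(sa, sb, tolerance = 1e-12)  # same shape, different colours

  g1 <- embed_specimen(ra$image, part_mask = ra$mask, variant = "greyscale")
  g2 <- embed_specimen(rotate_hue(ra$image, 117), part_mask = ra$mask,
                       variant = "greyscale")
  expect_equal(g1, g2, tolerance = 1e-8)   # hue recolouring leaves V untouched
})

test_that("ridge elevation model recovers exact features and rejects noise", {
  # feature 1 equals elevation, everything else zero
  n <- 40
  y <- runif(n, 0, 2500)
  X <- cbind(y, matrix(0, n, 7))
  m <- fit_elevation_model(X, y, lambda = 1e-8)
  expect_lt(m$mse, 1e-6)
  expect_equal(m$r2, 1, tolerance = 1e-8)
  expect_equal(predict(m, X), y, tolerance = 1e-4)

  # permuted labels: held-out R^2 near zero on average
  set.seed(20)
  r2s <- replicate(20, {
    Xr <- matrix(runif(100 * 8), 100, 8)
    yr <- sample(runif(100, 0, 2500))
    fitm <- fit_elevation_model(Xr[1:70, ], yr[1:70], lambda = 1)
    pred <- predict(fitm, Xr[71:100, ])
    cor(pred, yr[71:100])^2
  })
  expect_lt(abs(mean(r2s)), 0.1)
  expect_error(fit_elevation_model(matrix(1, 1, 2), 1), "2 training rows")
})

test_that("planted melanism structure supports held-out elevation prediction", {
  r2 <- numeric(3)
  for (s in 1:3) {
    rep <- run_pipeline(paper_regime_config(seed = 300 + s),
                        boot_pairwise_reps = 0, boot_family_reps = 0,
                        fit_elevation = TRUE)
    r2[s] <- rep$elevation_model$r2_species
  }
  expect_true(all(r2 > 0.5))
})

test_that("species predictions average per-image predictions", {
  m <- structure(list(beta = c(1, 0), x_center = c(0, 0), y_center = 0,
                      lambda = 0, mse = 0, r2 = 1), class = "elevation_model")
  X <- rbind(c(100, 0), c(300, 0))
  expect_equal(predict_species_elevation(m, X), 200)
  expect_equal(predict_species_elevation(m, X[1, , drop = FALSE]), 100)
  expect_equal(predict_species_elevation(m, X[2:1, ]), 200)  # order invariant
})

test_that("representative image selection follows the closest-elevation rule", {
  expect_equal(representative_image(c("a", "b"), c(100, 500), 480), "b")
  expect_equal(representative_image("only", 700), "only")
  # tie at equal distance: lexicographically smallest id
  expect_equal(representative_image(c("z9", "a1"), c(90, 110), 100), "a1")
})

test_that("classical MDS reproduces Euclidean configurations", {
  set.seed(30)
  # collinear points: 1-D MDS recovers coordinates up to sign/shift
  x <- sort(runif(12, 0, 10))
  d <- as.matrix(dist(x))
  z <- mds_project(d, dims = 1)[, 1]
  z <- z - mean(z)
  xc <- x - mean(x)
  if (cor(z, xc) < 0) z <- -z
  expect_lt(sqrt(mean((z - xc)^2)), 1e-8)

  # planar points: embedded distances match the input to machine precision
  P <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(P))
  emb <- mds_project(d2, dims = 2)
  expect_equal(as.matrix(dist(emb)), d2, tolerance = 1e-9, ignore_attr = TRUE)

  # oracle: stats::cmdscale on the same matrix
  ora <- stats::cmdscale(d2, k = 2)
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(ora)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("MDS handles symmetry, duplicates, orientation and bad input", {
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  emb <- mds_project(d3, dims = 2)
  pd <- dist(emb)
  expect_equal(max(pd) - min(pd), 0, tolerance = 1e-9)  # equilateral

  d4 <- as.matrix(dist(c(0, 0, 3, 5)))   # duplicate pair embeds identically
  e4 <- mds_project(d4, dims = 1)
  expect_equal(e4[1, 1], e4[2, 1], tolerance = 1e-9, ignore_attr = TRUE)

  z <- mds_project(d4, dims = 1, orient_by = c(0, 0, 3, 5))[, 1]
  expect_gte(cor(z, c(0, 0, 3, 5)), 0)

  bad <- d4; bad[1, 2] <- 9
  expect_error(mds_project(bad, 1), "symmetric")
})
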