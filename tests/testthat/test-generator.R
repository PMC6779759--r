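test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_species = 0), "n_species")
  expect_error(sim_config(elevation_range = c(2000, 100)), "elevation_range")
  expect_error(sim_config(images_per_species = c(3, 1)), "images_per_species")
  expect_error(sim_config(within_species_sd = c(h = -1, s = 0.1, v = 0.1)),
               "within_species_sd")
  expect_error(sim_config(image_size = 32), "image_size")
  expect_error(sim_config(external_filter_strength = -0.1),
               "external_filter_strength")
})

test_that("null configuration plants no elevational brightness trend", {
  cfg <- sim_config(n_species = 500, melanism_slope_b = 0,
                    melanism_slope_s = 0, external_filter_strength = 0,
                    seed = 3)
  pool <- generate_species_pool(cfg)
  fit <- lm(base_v ~ mean_elev, data = pool)
  ci <- confint(fit)[2, ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("a planted melanism slope is recoverable from the pool", {
  neg <- 0
  for (s in 1:20) {
    pool <- generate_species_pool(sim_config(n_species = 200,
                                             melanism_slope_b = -0.2,
                                             seed = 100 + s))
    neg <- neg + (coef(lm(base_v ~ mean_elev, data = pool))[2] < 0)
  }
  expect_gte(neg, 19)
})

test_that("species pool is deterministic under a fixed seed", {
  cfg <- sim_config(n_species = 1, seed = 5)
  expect_identical(generate_species_pool(cfg), generate_species_pool(cfg))
  expect_equal(nrow(generate_species_pool(cfg)), 1)
  cfg2 <- tiny_config()
  expect_identical(generate_species_pool(cfg2), generate_species_pool(cfg2))
})

test_that("renders label the five parts plus background and are RNG-reproducible", {
  cfg <- tiny_config()
  pool <- generate_species_pool(cfg)
  set.seed(1); r1 <- render_specimen(pool[1, ], cfg)
  set.seed(1); r2 <- render_specimen(pool[1, ], cfg)
  expect_identical(r1, r2)
  expect_true(all(unique(as.vector(r1$mask)) %in% 0:5))
  expect_gt(sum(r1$mask == 1), 0)             # body present
  expect_true(all(1:5 %in% as.vector(r1$mask)))  # all five parts drawn
})

test_that("pattern-free wings are uniform up to the configured pixel noise", {
  cfg <- tiny_config(pixel_noise_sd = 0.01)
  pool <- generate_species_pool(cfg)
  spec <- pool[1, ]
  spec$n_spots <- 0
  spec$n_stripes <- 0
  set.seed(2)
  r <- render_specimen(spec, cfg)
  for (part in 1:5) {
    sel <- r$mask == part
    for (k in 1:3) {
      vals <- r$image[, , k][sel]
      expect_lte(sd(vals), 3 * cfg$pixel_noise_sd)
    }
  }
})

test_that("dataset respects image-count ranges and is byte-reproducible", {
  cfg <- tiny_config(n_species = 20, images_per_species = c(1, 5), seed = 11)
  ds <- generate_dataset(cfg)
  expect_gte(nrow(ds$metadata), 20)
  expect_lte(nrow(ds$metadata), 100)

  cfg3 <- tiny_config(n_species = 5, images_per_species = c(3, 3), seed = 12)
  ds3 <- generate_dataset(cfg3)
  expect_true(all(table(ds3$metadata$species_id) == 3))

  # identical seed => identical written bytes
  d1 <- file.path(tempdir(), "mothds1"); d2 <- file.path(tempdir(), "mothds2")
  write_dataset(ds3, d1)
  write_dataset(generate_dataset(cfg3), d2)
  f1 <- file.path(d1, "metadata.csv"); f2 <- file.path(d2, "metadata.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  img <- ds3$metadata$image_id[1]
  expect_identical(
    unname(tools::md5sum(file.path(d1, "images", paste0(img, ".png")))),
    unname(tools::md5sum(file.path(d2, "images", paste0(img, ".png")))))
  # masks survive the PNG round trip exactly
  expect_identical(read_mask(file.path(d1, "masks", paste0(img, ".png"))),
                   ds3$masks[[img]])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("temperature is an exact affine function of elevation", {
  cfg <- tiny_config(seed = 9)
  ds <- generate_dataset(cfg)
  expected <- cfg$sea_level_temp - cfg$lapse_rate * ds$metadata$elevation_m / 1000
  expect_identical(ds$metadata$temperature_c, expected)
})

test_that("stratified regime reproduces the gap structure exactly", {
  cfg <- paper_regime_config(seed = 21)
  ds <- generate_dataset(cfg)
  reps <- select_representatives(ds$metadata)
  bins <- bin_species(reps$mean_elev)
  expect_equal(length(unique(bins$bin_lo)), 19)
  expect_false(any(bins$bin_lo %in% cfg$elevation_gaps))
  expect_gte(min(table(bins$bin_lo)), 11)
})
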