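#' Generate a synthetic species pool
#'
#' Draws species mean elevations over the configured range (uniform, or
#' stratified across occupied 100-m bins when
#' \code{min_species_per_bin > 0}), then plants the thermal-melanism
#' structure: each species' base brightness V has expectation
#' \code{base_v + melanism_slope_b * elev_km} and its base saturation S
#' has expectation \code{base_s + melanism_slope_s * elev_km}, both
#' clipped to [0.05, 0.95]; the between-species scatter of the filtered
#' channels shrinks with elevation at rate
#' \code{external_filter_strength} per km. Hue is wrapped-normal with no
#' elevational signal. Wing shape and pattern parameters (spots,
#' stripes) are drawn per species.
#'
#' @param config A \code{\link{sim_config}} object. The config seed is
#'   applied, so the pool is deterministic.
#' @return A data.frame with one row per species: ids (species, genus,
#'   family), \code{mean_elev}, base colour (\code{base_h}, \code{base_s},
#'   \code{base_v}), and pattern parameters.
#' @export
generate_species_pool <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_species
  er <- config$elevation_range
  w <- config$bin_width
  all_lo <- seq(er[1], er[2] - w, by = w)
  gaps <- config$elevation_gaps
  allowed <- if (is.null(gaps)) all_lo else setdiff(all_lo, gaps)
  if (length(allowed) == 0L) {
    stop("invalid configuration field 'elevation_gaps': no bins remain")
  }

  if (config$min_species_per_bin > 0) {
    k <- length(allowed)
    base_count <- config$min_species_per_bin
    if (k * base_count > n) {
      stop("invalid configuration field 'n_species': too small for ",
           "min_species_per_bin x occupied bins")
    }
    # one bin is held at exactly the configured minimum (the regime fixes
    # the smallest assemblage size); extras spread over the other bins
    extra <- numeric(k)
    if (k > 1 && n > k * base_count) {
      min_bin <- sample.int(k, 1)
      extra[-min_bin] <- as.vector(
        stats::rmultinom(1, n - k * base_count, rep(1 / (k - 1), k - 1)))
    }
    counts <- base_count + extra
    bin_of <- rep(allowed, counts)
  } else {
    bin_of <- sample(allowed, n, replace = TRUE)
  }
  mean_elev <- bin_of + stats::runif(n) * w
  ord <- order(mean_elev)
  mean_elev <- mean_elev[ord]

  elev_km <- mean_elev / 1000
  shrink <- pmax(0.05, 1 - config$external_filter_strength * elev_km)
  bs <- config$between_species_sd
  sd_h <- if ("h" %in% config$filter_channels) bs[["h"]] * shrink else rep(bs[["h"]], n)
  sd_s <- if ("s" %in% config$filter_channels) bs[["s"]] * shrink else rep(bs[["s"]], n)
  sd_v <- if ("v" %in% config$filter_channels) bs[["v"]] * shrink else rep(bs[["v"]], n)

  base_h <- (config$hue_mean + stats::rnorm(n, 0, sd_h)) %% 360
  base_s <- clip01(config$base_s + config$melanism_slope_s * elev_km +
                     stats::rnorm(n, 0, sd_s), 0.05, 0.95)
  base_v <- clip01(config$base_v + config$melanism_slope_b * elev_km +
                     stats::rnorm(n, 0, sd_v), 0.05, 0.95)

  data.frame(
    species_id = sprintf("sp%04d", seq_len(n)),
    genus_id = sprintf("gen%03d", (seq_len(n) - 1L) %/% 3L + 1L),
    family_id = sprintf("fam%02d", (seq_len(n) - 1L) %% config$n_families + 1L),
    mean_elev = mean_elev,
    base_h = base_h, base_s = base_s, base_v = base_v,
    n_spots = sample(0:2, n, replace = TRUE),
    n_stripes = sample(0:2, n, replace = TRUE),
    wing_span = stats::runif(n, 0.28, 0.40),
    wing_sweep = stats::runif(n, 0, 0.06),
    hindwing_scale = stats::runif(n, 0.85, 1),
    body_width = stats::runif(n, 0.05, 0.08),
    spot_y = stats::runif(n, 0.24, 0.38),
    spot_r = stats::runif(n, 0.020, 0.035),
    stringsAsFactors = FALSE
  )
}

# Part labels used throughout: 0 background, 1 body, 2/3 forewing L/R,
# 4/5 hindwing L/R.
PART_LABELS <- c(background = 0L, body = 1L, forewing_l = 2L, forewing_r = 3L,
                 hindwing_l = 4L, hindwing_r = 5L)

#' Render one procedural moth specimen
#'
#' Draws a bilaterally symmetric moth (body ellipse, two forewing and two
#' hindwing quadrilaterals, optional dark wing spots and stripes) on a
#' uniform light-grey background, and returns the image together with the
#' ground-truth five-part mask. Individual colour = species base colour
#' plus a per-image within-species HSV deviation; consumes the current
#' RNG stream (seed upstream for reproducibility).
#'
#' @param spec One row of a \code{\link{generate_species_pool}} data.frame
#'   (or an equivalent list).
#' @param config A \code{\link{sim_config}} (supplies image size, noise
#'   levels, hindwing offsets and within-species SDs).
#' @return A list with \code{image} (size x size x 3 array, unit scale) and
#'   \code{mask} (integer matrix with labels 0--5).
#' @export
render_specimen <- function(spec, config) {
  size <- config$image_size
  if (size < 64) stop("invalid configuration field 'image_size': must be >= 64")
  spec <- as.list(spec)

  # pixel-centre coordinates in the unit square
  xs <- (seq_len(size) - 0.5) / size
  px <- rep(xs, each = size)    # column-major over a size x size matrix
  py <- rep(xs, times = size)
  # NB: matrix(m, size, size) has rows indexed by py (vertical), cols by px

  span <- spec$wing_span
  sweep <- spec$wing_sweep
  hs <- spec$hindwing_scale
  mask <- integer(size * size)

  # hindwings first, then forewings, then body (overlap priority)
  hw_r <- list(x = c(0.51, 0.5 + 0.75 * span * hs, 0.5 + 0.50 * span * hs, 0.52),
               y = c(0.50, 0.46, 0.76, 0.72))
  hw_l <- list(x = 1 - hw_r$x, y = hw_r$y)
  fw_r <- list(x = c(0.51, 0.52, 0.5 + span, 0.5 + 0.80 * span),
               y = c(0.46, 0.22, 0.14 + sweep, 0.48))
  fw_l <- list(x = 1 - fw_r$x, y = fw_r$y)

  mask[in_convex_polygon(px, py, hw_l$x, hw_l$y)] <- PART_LABELS[["hindwing_l"]]
  mask[in_convex_polygon(px, py, hw_r$x, hw_r$y)] <- PART_LABELS[["hindwing_r"]]
  mask[in_convex_polygon(px, py, fw_l$x, fw_l$y)] <- PART_LABELS[["forewing_l"]]
  mask[in_convex_polygon(px, py, fw_r$x, fw_r$y)] <- PART_LABELS[["forewing_r"]]
  body <- ((px - 0.5) / spec$body_width)^2 + ((py - 0.48) / 0.30)^2 <= 1
  mask[body] <- PART_LABELS[["body"]]

  # individual colour deviation (one draw per image)
  ws <- config$within_species_sd
  dh <- stats::rnorm(1, 0, ws[["h"]])
  ds <- stats::rnorm(1, 0, ws[["s"]])
  dv <- stats::rnorm(1, 0, ws[["v"]])
  h0 <- (spec$base_h + dh) %% 360
  s0 <- clip01(spec$base_s + ds)
  v0 <- clip01(spec$base_v + dv)

  hh <- rep(h0, size * size)
  ss <- numeric(size * size)
  vv <- numeric(size * size)
  fw <- mask %in% PART_LABELS[c("forewing_l", "forewing_r")]
  hw <- mask %in% PART_LABELS[c("hindwing_l", "hindwing_r")]
  bd <- mask == PART_LABELS[["body"]]
  ss[fw] <- s0; vv[fw] <- v0
  ss[bd] <- clip01(s0 * 0.9); vv[bd] <- clip01(v0 * 0.75)
  # hindwings track the species colour only partially (anchored coupling),
  # so melanism on the exposed parts shifts the B and S indices
  cpl <- config$hindwing_couple
  ss[hw] <- clip01(config$base_s + cpl * (s0 - config$base_s) +
                     config$hindwing_s_offset)
  vv[hw] <- clip01(config$base_v + cpl * (v0 - config$base_v) +
                     config$hindwing_v_offset)

  # dark spots on the forewings, mirrored; mask labels unchanged
  if (spec$n_spots > 0) {
    for (k in seq_len(spec$n_spots)) {
      cx <- 0.5 + span * (0.35 + 0.22 * (k - 1))
      cy <- spec$spot_y + 0.05 * (k - 1)
      spot <- fw & (((px - cx)^2 + (py - cy)^2 <= spec$spot_r^2) |
                      ((px - (1 - cx))^2 + (py - cy)^2 <= spec$spot_r^2))
      vv[spot] <- vv[spot] * 0.45
    }
  }
  # transverse stripes across both wing pairs
  if (spec$n_stripes > 0) {
    stripe <- (fw | hw) & ((py * 6 * spec$n_stripes) %% 1 < 0.3)
    vv[stripe] <- vv[stripe] * 0.72
  }

  fg <- mask > 0L
  rgb <- matrix(0.82, size * size, 3)  # light grey background
  if (any(fg)) {
    rgb[fg, ] <- hsv_to_rgb(cbind(hh[fg], ss[fg], vv[fg]), max_value = 1)
  }
  noise_sd <- ifelse(fg, config$pixel_noise_sd, config$pixel_noise_sd * 0.5)
  rgb <- clip01(rgb + matrix(stats::rnorm(length(rgb), 0, 1), ncol = 3) * noise_sd)

  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- matrix(rgb[, 1], size, size)
  img[, , 2] <- matrix(rgb[, 2], size, size)
  img[, , 3] <- matrix(rgb[, 3], size, size)
  list(image = img, mask = matrix(as.integer(mask), size, size))
}

#' Generate a full synthetic specimen dataset
#'
#' Runs \code{\link{generate_species_pool}}, draws per-species image
#' counts within the configured range, samples each specimen's elevation
#' from a truncated normal around its species mean, attaches climate
#' covariates (temperature is exactly
#' \code{sea_level_temp - lapse_rate * elevation / 1000}; precipitation is
#' a noisy hump over the gradient), and renders every specimen image and
#' ground-truth part mask. Fully deterministic under \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Optional output directory: writes \code{images/*.png} (8-bit
#'   RGB), \code{masks/*.png} (8-bit single channel, labels 0--5),
#'   \code{metadata.csv} and a JSON \code{manifest.json} recording the
#'   config and seed.
#' @return Invisibly (when \code{dir} given) or visibly, a
#'   \code{moth_dataset}: list with \code{metadata} (one row per image:
#'   image_id, species_id, genus_id, family_id, elevation_m,
#'   temperature_c, precip_mm), \code{images}, \code{masks},
#'   \code{pool}, \code{config}.
#' @export
generate_dataset <- function(config, dir = NULL) {
  validate_sim_config(config)
  pool <- generate_species_pool(config)  # seeds the stream with config$seed
  ips <- config$images_per_species
  n_sp <- nrow(pool)
  n_img <- ips[1] + sample.int(ips[2] - ips[1] + 1L, n_sp, replace = TRUE) - 1L

  sp_idx <- rep(seq_len(n_sp), n_img)
  er <- config$elevation_range
  if (config$min_species_per_bin > 0) {
    # stratified regime: a species' elevational niche is bounded by its
    # home bin, so the configured gap structure survives the sampling
    # noise and the species' observed mean stays in its bin
    home_lo <- floor(pool$mean_elev[sp_idx] / config$bin_width) * config$bin_width
    elev <- rtrunc_norm(length(sp_idx), pool$mean_elev[sp_idx],
                        config$sampling_sd, home_lo, home_lo + config$bin_width)
  } else {
    elev <- rtrunc_norm(length(sp_idx), pool$mean_elev[sp_idx],
                        config$sampling_sd, er[1], er[2])
  }
  temp <- config$sea_level_temp - config$lapse_rate * elev / 1000
  precip <- pmax(0, 2200 + 900 * sin(pi * elev / 2500) +
                   stats::rnorm(length(elev), 0, 250))

  img_seq <- sequence(n_img)
  image_id <- sprintf("%s_im%02d", pool$species_id[sp_idx], img_seq)
  metadata <- data.frame(
    image_id = image_id,
    species_id = pool$species_id[sp_idx],
    genus_id = pool$genus_id[sp_idx],
    family_id = pool$family_id[sp_idx],
    elevation_m = elev,
    temperature_c = temp,
    precip_mm = precip,
    stringsAsFactors = FALSE
  )

  images <- vector("list", length(sp_idx))
  masks <- vector("list", length(sp_idx))
  for (i in seq_along(sp_idx)) {
    r <- render_specimen(pool[sp_idx[i], ], config)
    images[[i]] <- r$image
    masks[[i]] <- r$mask
  }
  names(images) <- image_id
  names(masks) <- image_id

  ds <- structure(
    list(metadata = metadata, images = images, masks = masks,
         pool = pool, config = config),
    class = "moth_dataset"
  )
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a dataset to disk (PNG images/masks, CSV metadata, JSON manifest)
#'
#' @param dataset A \code{moth_dataset}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to directory: ", dir)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  for (id in dataset$metadata$image_id) {
    png::writePNG(dataset$images[[id]], file.path(dir, "images", paste0(id, ".png")))
    # labels 0..5 stored as exact multiples of 1/255 in an 8-bit grey PNG
    png::writePNG(dataset$masks[[id]] / 255, file.path(dir, "masks", paste0(id, ".png")))
  }
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  cfg <- dataset$config
  class(cfg) <- NULL
  manifest <- list(config = cfg, n_species = nrow(dataset$pool),
                   n_images = nrow(dataset$metadata))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a mask PNG written by \code{\link{write_dataset}}
#' @param path Path to an 8-bit single-channel mask PNG.
#' @return Integer matrix of part labels 0--5.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
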