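#' Configuration for the synthetic specimen generator
#'
#' Defines the study conditions the generator emulates: species spread
#' along an elevational gradient, several images per species, and
#' colour distributions whose brightness falls and saturation rises
#' with elevation (thermal melanism), with between-species colour
#' scatter optionally shrinking with elevation (external filtering).
#'
#' @param n_species Number of species in the pool.
#' @param images_per_species Integer range \code{c(lo, hi)} of images drawn
#'   per species.
#' @param elevation_range Metres, \code{c(lo, hi)} with lo < hi.
#' @param elevation_gaps Lower edges (m) of \code{bin_width}-wide intervals
#'   that hold no species (emulates elevations with no collection events).
#' @param min_species_per_bin If > 0, species mean elevations are allocated
#'   so that every non-gap bin receives at least this many species
#'   (stratified regime); 0 draws means uniformly over the allowed range.
#' @param bin_width Width (m) of the elevation bins used for stratified
#'   allocation (and by convention downstream assemblage binning).
#' @param n_families Families; species are assigned round-robin so every
#'   bin holds several families.
#' @param melanism_slope_b Change in mean species brightness V per km of
#'   elevation (negative = thermal melanism).
#' @param melanism_slope_s Change in mean species saturation S per km.
#' @param base_v,base_s Sea-level expectations of species brightness and
#'   saturation.
#' @param hue_mean Centre (degrees) of the wrapped-normal species hue
#'   distribution; hue carries no planted elevational signal.
#' @param between_species_sd Named numeric \code{c(h=, s=, v=)}: SD of
#'   species base colours around the elevational expectation (h in degrees).
#' @param within_species_sd Named numeric \code{c(h=, s=, v=)}: SD of
#'   individual colour around the species base colour.
#' @param external_filter_strength Per-km fractional shrinkage of the
#'   between-species colour scatter (0 = no filtering; 0.3 means the SD at
#'   1000 m is 70\% of the sea-level SD, floored at 5\%).
#' @param filter_channels Which HSV channels the external filter acts on
#'   (subset of \code{c("h", "s", "v")}).
#' @param sampling_sd SD (m) of the truncated normal from which each
#'   specimen's sampled elevation is drawn around its species mean.
#' @param lapse_rate Temperature lapse rate, degrees C per km.
#' @param sea_level_temp Temperature at 0 m, degrees C.
#' @param hindwing_v_offset,hindwing_s_offset Offsets of hindwing
#'   brightness/saturation relative to the anchored hindwing colour.
#' @param hindwing_couple Coupling in [0, 1] of the hindwing colour to the
#'   species base colour: hindwing V is
#'   \code{base_v + hindwing_couple * (V_species - base_v) + hindwing_v_offset}
#'   (analogously for S). Because the concealed hindwings track the
#'   species colour only partially, melanism expressed on the exposed
#'   parts (body + forewings) moves the relative-brightness index
#'   B = Bf/Bw down and the relative-saturation index S = Sf/Sw up, the
#'   contrast the indices are designed to capture.
#' @param image_size Square image side in pixels (>= 64).
#' @param pixel_noise_sd SD of per-pixel additive RGB noise (unit scale).
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return An object of class \code{moth_sim_config}.
#' @seealso \code{\link{paper_regime_config}}, \code{\link{generate_dataset}}
#' @export
sim_config <- function(n_species = 250,
                       images_per_species = c(2, 3),
                       elevation_range = c(0, 2500),
                       elevation_gaps = NULL,
                       min_species_per_bin = 0,
                       bin_width = 100,
                       n_families = 8,
                       melanism_slope_b = -0.2,
                       melanism_slope_s = 0.1,
                       base_v = 0.62,
                       base_s = 0.40,
                       hue_mean = 40,
                       between_species_sd = c(h = 40, s = 0.12, v = 0.12),
                       within_species_sd = c(h = 4, s = 0.03, v = 0.03),
                       external_filter_strength = 0.3,
                       filter_channels = c("s", "v"),
                       sampling_sd = 150,
                       lapse_rate = 6.5,
                       sea_level_temp = 23,
                       hindwing_v_offset = 0.18,
                       hindwing_s_offset = -0.05,
                       hindwing_couple = 0.4,
                       image_size = 64,
                       pixel_noise_sd = 0.012,
                       seed = 1) {
  cfg <- list(
    n_species = n_species, images_per_species = images_per_species,
    elevation_range = elevation_range, elevation_gaps = elevation_gaps,
    min_species_per_bin = min_species_per_bin, bin_width = bin_width,
    n_families = n_families, melanism_slope_b = melanism_slope_b,
    melanism_slope_s = melanism_slope_s, base_v = base_v, base_s = base_s,
    hue_mean = hue_mean, between_species_sd = between_species_sd,
    within_species_sd = within_species_sd,
    external_filter_strength = external_filter_strength,
    filter_channels = filter_channels, sampling_sd = sampling_sd,
    lapse_rate = lapse_rate, sea_level_temp = sea_level_temp,
    hindwing_v_offset = hindwing_v_offset,
    hindwing_s_offset = hindwing_s_offset,
    hindwing_couple = hindwing_couple,
    image_size = image_size, pixel_noise_sd = pixel_noise_sd, seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "moth_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)
  }
  is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
  if (!is_count(cfg$n_species)) bad("n_species", "must be a count >= 1")
  ips <- cfg$images_per_species
  if (length(ips) != 2L || any(!is.finite(ips)) || any(ips < 1) ||
      any(ips != round(ips)) || ips[1] > ips[2]) {
    bad("images_per_species", "must be an integer range c(lo, hi) with 1 <= lo <= hi")
  }
  er <- cfg$elevation_range
  if (length(er) != 2L || any(!is.finite(er)) || er[1] >= er[2] || er[1] < 0) {
    bad("elevation_range", "must be c(lo, hi) with 0 <= lo < hi")
  }
  if (!is_count(cfg$n_families)) bad("n_families", "must be a count >= 1")
  if (!is_count(cfg$bin_width)) bad("bin_width", "must be a positive width")
  for (f in c("between_species_sd", "within_species_sd")) {
    v <- cfg[[f]]
    if (length(v) != 3L || !all(c("h", "s", "v") %in% names(v)) || any(v < 0)) {
      bad(f, "must be a named nonnegative vector c(h=, s=, v=)")
    }
  }
  if (cfg$external_filter_strength < 0) {
    bad("external_filter_strength", "must be >= 0")
  }
  if (!all(cfg$filter_channels %in% c("h", "s", "v"))) {
    bad("filter_channels", "must be a subset of c('h','s','v')")
  }
  if (cfg$sampling_sd < 0) bad("sampling_sd", "must be >= 0")
  if (!(length(cfg$image_size) == 1L && cfg$image_size >= 64)) {
    bad("image_size", "must be >= 64 pixels")
  }
  if (cfg$pixel_noise_sd < 0) bad("pixel_noise_sd", "must be >= 0")
  if (cfg$hindwing_couple < 0 || cfg$hindwing_couple > 1) {
    bad("hindwing_couple", "must lie in [0, 1]")
  }
  if (cfg$base_v <= 0 || cfg$base_v >= 1) bad("base_v", "must lie in (0, 1)")
  if (cfg$base_s <= 0 || cfg$base_s >= 1) bad("base_s", "must lie in (0, 1)")
  if (!is.null(cfg$elevation_gaps)) {
    g <- cfg$elevation_gaps
    if (any(g < er[1]) || any(g + cfg$bin_width > er[2] + cfg$bin_width)) {
      bad("elevation_gaps", "gap bins must lie inside elevation_range")
    }
  }
  if (cfg$min_species_per_bin < 0) bad("min_species_per_bin", "must be >= 0")
  if (length(cfg$seed) != 1L || !is.finite(cfg$seed)) bad("seed", "must be a single integer")
  invisible(cfg)
}

#' Generator configuration mirroring the study's sampling regime
#'
#' Species mean elevations span 0--2500 m in 100-m bins with six empty
#' intervals, so exactly 19 assemblages form, and every occupied bin
#' receives at least 11 species, so the smallest assemblage contributes
#' choose(11, 2) = 55 pairwise distances. All other parameters keep the
#' \code{\link{sim_config}} defaults unless overridden via \code{...}.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to \code{\link{sim_config}}.
#' @return A \code{moth_sim_config}.
#' @export
paper_regime_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    n_species = 250,
    images_per_species = c(2, 3),
    elevation_range = c(0, 2500),
    elevation_gaps = c(400, 800, 1200, 1600, 1900, 2200),
    min_species_per_bin = 11,
    bin_width = 100
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
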