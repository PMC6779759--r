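# Colour-space constraint simulation: restricting colours to a darker
# HSV region (low brightness, high saturation) reduces the colour
# variation measurable in RGB space.

#' Sample random colours uniformly from an HSV region
#'
#' H, S and V are drawn independently and uniformly within their
#' intervals and converted to 8-bit-scale RGB.
#'
#' @param n Number of samples.
#' @param h_range Hue interval in degrees within [0, 360].
#' @param s_range,v_range Saturation/brightness intervals within [0, 1].
#' @param seed Optional seed (RNG state restored afterwards).
#' @return n x 3 matrix of RGB triples on the 0--255 scale.
#' @export
sample_hsv_region <- function(n, h_range = c(0, 360), s_range = c(0, 1),
                              v_range = c(0, 1), seed = NULL) {
  check_iv <- function(iv, lo, hi, nm) {
    if (length(iv) != 2 || iv[1] > iv[2] || iv[1] < lo || iv[2] > hi) {
      stop("empty or invalid interval for ", nm)
    }
  }
  check_iv(h_range, 0, 360, "h_range")
  check_iv(s_range, 0, 1, "s_range")
  check_iv(v_range, 0, 1, "v_range")
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    h <- stats::runif(n, h_range[1], h_range[2])
    s <- stats::runif(n, s_range[1], s_range[2])
    v <- stats::runif(n, v_range[1], v_range[2])
    hsv_to_rgb(cbind(h, s, v), max_value = 255)
  })
}

#' Total RGB colour variation of a sample
#'
#' Trace of the RGB covariance matrix (sum of per-channel variances,
#' denominator n): the simplest rotation-invariant scalar measure of
#' colour spread. In the greyscale limit (S = 0, V ~ U[0, c]) it has the
#' closed form 3 * (255 c)^2 / 12.
#'
#' @param samples n x 3 matrix of RGB triples (n >= 2).
#' @return Nonnegative scalar.
#' @export
rgb_variation <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("need at least 2 samples")
  n <- nrow(samples)
  sum(apply(samples, 2, function(ch) sum((ch - mean(ch))^2) / n))
}

#' Colour-variation surface under brightness/saturation constraints
#'
#' For each combination of a brightness ceiling c and a saturation floor
#' f, samples colours uniformly with V in [0, c], S in [f, 1] and the
#' full hue circle, and records the RGB variation. Darker regions
#' (smaller c, larger f) yield lower RGB variation.
#'
#' @param v_ceilings Grid of brightness ceilings in [0, 1].
#' @param s_floors Grid of saturation floors in [0, 1].
#' @param n Samples per grid cell (default 10000).
#' @param seed Seed (one stream for the whole grid; restored afterwards).
#' @return Long-format data.frame: v_ceiling, s_floor, variation, n.
#' @export
constraint_experiment <- function(v_ceilings = seq(0.1, 1, by = 0.1),
                                  s_floors = seq(0, 0.9, by = 0.1),
                                  n = 10000, seed = 1) {
  if (any(v_ceilings < 0 | v_ceilings > 1) || any(s_floors < 0 | s_floors > 1)) {
    stop("grids must lie within [0, 1]")
  }
  with_seed(seed, {
    grid <- expand.grid(v_ceiling = v_ceilings, s_floor = s_floors,
                        KEEP.OUT.ATTRS = FALSE)
    grid$variation <- vapply(seq_len(nrow(grid)), function(i) {
      c_ <- grid$v_ceiling[i]
      if (c_ == 0) return(0)  # all black
      rgb_variation(sample_hsv_region(n, s_range = c(grid$s_floor[i], 1),
                                      v_range = c(0, c_)))
    }, numeric(1))
    grid$n <- n
    grid
  })
}
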