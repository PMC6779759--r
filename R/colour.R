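#' Convert RGB colours to HSV
#'
#' Standard hexcone conversion: V = max(R, G, B) / max_value and
#' S = (max - min) / max (0 for black). Hue is reported in degrees in
#' \code{[0, 360)} and is set to 0 for achromatic pixels (S = 0), where
#' it is undefined.
#'
#' @param rgb A length-3 numeric vector or an n x 3 matrix of channels
#'   in \code{[0, max_value]}.
#' @param max_value Channel ceiling; 255 for 8-bit images, 1 for unit-scaled
#'   rasters.
#' @return An n x 3 matrix with columns \code{h} (degrees), \code{s}, \code{v}.
#' @examples
#' rgb_to_hsv(c(255, 0, 0))   # pure red: h = 0, s = 1, v = 1
#' @export
rgb_to_hsv <- function(rgb, max_value = 255) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  if (ncol(rgb) != 3L) stop("rgb must have three channels")
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > max_value)) {
    stop("rgb channels must lie in [0, ", max_value, "]")
  }
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = max_value))
  out <- cbind(h = hsv[, 1] * 360, s = hsv[, 2], v = hsv[, 3])
  dimnames(out) <- list(NULL, c("h", "s", "v"))
  # rgb2hsv leaves an arbitrary hue for achromatic colours; pin it to 0
  out[out[, "s"] == 0, "h"] <- 0
  out
}

#' Convert HSV colours to RGB
#'
#' Inverse hexcone conversion, vectorized; the numeric inverse of
#' \code{\link{rgb_to_hsv}} (round trip exact to within 1/255 per channel
#' on 8-bit input).
#'
#' @param hsv A length-3 vector \code{c(h, s, v)} or an n x 3 matrix;
#'   h in degrees, s and v in \code{[0, 1]}.
#' @param max_value Output channel ceiling (default 255).
#' @return An n x 3 matrix with columns \code{r}, \code{g}, \code{b}.
#' @export
hsv_to_rgb <- function(hsv, max_value = 255) {
  if (is.null(dim(hsv))) hsv <- matrix(hsv, nrow = 1)
  if (ncol(hsv) != 3L) stop("hsv must have three components")
  h <- hsv[, 1] %% 360
  s <- hsv[, 2]
  v <- hsv[, 3]
  if (any(s < 0 | s > 1) || any(v < 0 | v > 1)) stop("s and v must lie in [0, 1]")
  c_ <- v * s
  hp <- h / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  sector <- floor(hp) %% 6
  r <- g <- b <- numeric(length(h))
  idx <- sector == 0; r[idx] <- c_[idx]; g[idx] <- x[idx]
  idx <- sector == 1; r[idx] <- x[idx]; g[idx] <- c_[idx]
  idx <- sector == 2; g[idx] <- c_[idx]; b[idx] <- x[idx]
  idx <- sector == 3; g[idx] <- x[idx]; b[idx] <- c_[idx]
  idx <- sector == 4; r[idx] <- x[idx]; b[idx] <- c_[idx]
  idx <- sector == 5; r[idx] <- c_[idx]; b[idx] <- x[idx]
  cbind(r = (r + m) * max_value, g = (g + m) * max_value, b = (b + m) * max_value)
}

# Per-pixel HSV (h degrees, s, v) for masked pixels of a unit-scale
# H x W x 3 raster. `sel` is a logical/0-1 matrix.
pixels_hsv <- function(image, sel = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 array")
  }
  if (is.null(sel)) sel <- matrix(TRUE, nrow(image), ncol(image))
  keep <- which(sel > 0)
  n <- length(keep)
  px <- cbind(image[, , 1][keep], image[, , 2][keep], image[, , 3][keep])
  rgb_to_hsv(px, max_value = 1)
}
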