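#' Melanism colour indices of one specimen
#'
#' Converts the specimen to HSV and computes mean saturation and
#' brightness over (i) the whole specimen (all five parts: S_w, B_w) and
#' (ii) the parts exposed at rest, body + both forewings (S_f, B_f).
#' The brightness index is the ratio B = B_f / B_w and the saturation
#' index S = S_f / S_w; values below 1 mean the exposed parts are darker
#' (respectively less saturated) than the specimen as a whole. Means are
#' arithmetic over pixels in linear channel space.
#'
#' @param image H x W x 3 array, unit scale.
#' @param part_mask Integer matrix with labels 0 (background), 1 (body),
#'   2/3 (forewings), 4/5 (hindwings).
#' @return A one-row data.frame: S_w, B_w, S_f, B_f, B_index, S_index.
#' @export
specimen_indices <- function(image, part_mask) {
  if (!identical(dim(image)[1:2], dim(part_mask)[1:2])) {
    stop("image and part_mask extents differ")
  }
  whole <- part_mask > 0
  fore <- part_mask %in% c(1L, 2L, 3L)
  if (sum(whole) == 0) stop("empty region: whole specimen")
  if (sum(fore) == 0) stop("empty region: body and forewings")
  hsv_w <- pixels_hsv(image, whole)
  hsv_f <- pixels_hsv(image, matrix(fore, nrow(part_mask), ncol(part_mask)))
  S_w <- mean(hsv_w[, "s"]); B_w <- mean(hsv_w[, "v"])
  S_f <- mean(hsv_f[, "s"]); B_f <- mean(hsv_f[, "v"])
  if (B_w <= 0) stop("zero denominator: whole-specimen brightness")
  if (S_w <= 0) stop("zero denominator: whole-specimen saturation")
  data.frame(S_w = S_w, B_w = B_w, S_f = S_f, B_f = B_f,
             B_index = B_f / B_w, S_index = S_f / S_w)
}

#' Assemblage-level mean colour indices
#'
#' Unweighted species means of the brightness and saturation indices
#' within one assemblage.
#'
#' @param indices Data.frame of member species' indices (needs
#'   \code{B_index} and \code{S_index} columns).
#' @return Named numeric: \code{mean_B}, \code{mean_S}.
#' @export
assemblage_indices <- function(indices) {
  if (is.null(indices) || nrow(indices) == 0) stop("empty assemblage")
  c(mean_B = mean(indices$B_index), mean_S = mean(indices$S_index))
}
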