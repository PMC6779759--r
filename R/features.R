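#' Deterministic colour-and-shape feature embedding of one specimen
#'
#' Produces a nonnegative length-\code{D} feature vector from the
#' foreground pixels: (a) a soft joint hue x saturation histogram
#' (16 x 4 bins, hue circular), (b) a soft brightness (V) histogram
#' (16 bins), (c) a soft saturation x brightness histogram (4 x 4),
#' (d) mean saturation and brightness per part group (body, pooled
#' forewings, pooled hindwings — pooling the left/right wings makes the
#' vector exactly mirror-invariant), and (e) a shape block: a 24-bin
#' histogram of centroid distances of foreground pixels plus the
#' foreground area fraction. Histogram blocks each sum to one; the
#' vector is zero-padded (or truncated) to length \code{D}.
#'
#' Variants mirror retraining on reduced images: \code{"greyscale"}
#' keeps only brightness-derived blocks (b, the V components of d, e);
#' \code{"silhouette"} keeps only the shape block (e).
#'
#' @param image H x W x 3 array, unit scale.
#' @param mask Binary foreground mask; if NULL, derived from
#'   \code{part_mask > 0}.
#' @param part_mask Optional integer part mask (labels 0--5) for the
#'   per-part means; NULL zeroes that block.
#' @param variant One of \code{"colour"}, \code{"greyscale"},
#'   \code{"silhouette"}.
#' @param D Embedding length (default 256).
#' @return Numeric vector of length \code{D}, nonnegative, not all zero.
#' @export
embed_specimen <- function(image, mask = NULL, part_mask = NULL,
                           variant = c("colour", "greyscale", "silhouette"),
                           D = 256) {
  variant <- match.arg(variant)
  if (is.null(mask)) {
    if (is.null(part_mask)) stop("either mask or part_mask is required")
    mask <- part_mask > 0
  }
  sel <- which(mask > 0)
  if (length(sel) == 0L) stop("empty foreground")

  hsv <- pixels_hsv(image, mask)
  h <- hsv[, "h"]; s <- hsv[, "s"]; v <- hsv[, "v"]

  block_hs <- soft_hist2(h, s, 16, 4, 0, 360, 0, 1, x_circular = TRUE)
  block_v <- soft_hist(v, 16)
  block_sv <- soft_hist2(s, v, 4, 4)

  block_parts <- numeric(6)
  if (!is.null(part_mask)) {
    pm <- part_mask[sel]
    groups <- list(body = 1L, forewing = c(2L, 3L), hindwing = c(4L, 5L))
    for (gi in seq_along(groups)) {
      in_g <- pm %in% groups[[gi]]
      if (any(in_g)) {
        block_parts[2 * gi - 1] <- mean(s[in_g])
        block_parts[2 * gi] <- mean(v[in_g])
      }
    }
  }

  # shape: distribution of pixel distances from the foreground centroid
  rows <- (sel - 1L) %% nrow(image) + 1L
  cols <- (sel - 1L) %/% nrow(image) + 1L
  cy <- mean(rows); cx <- mean(cols)
  r <- sqrt((rows - cy)^2 + (cols - cx)^2)
  rmax <- max(r)
  rn <- if (rmax > 0) r / rmax else r
  block_shape <- c(soft_hist(rn, 24), length(sel) / length(mask))

  if (variant == "greyscale") {
    block_hs[] <- 0
    block_sv[] <- 0
    block_parts[c(1, 3, 5)] <- 0  # drop saturation means, keep V means
  } else if (variant == "silhouette") {
    block_hs[] <- 0
    block_v[] <- 0
    block_sv[] <- 0
    block_parts[] <- 0
  }
  vec <- c(block_hs, block_v, block_sv, block_parts, block_shape)
  if (length(vec) >= D) vec[seq_len(D)] else c(vec, numeric(D - length(vec)))
}

#' Embed every image of a dataset
#'
#' @param dataset A \code{moth_dataset} (or a list with \code{images} and
#'   \code{masks}).
#' @param variant Embedding variant, see \code{\link{embed_specimen}}.
#' @param D Embedding length.
#' @param masks Optional named list of binary foreground masks overriding
#'   the dataset's ground-truth masks (e.g. output of
#'   \code{\link{segment_dataset}}); part means still use the ground-truth
#'   part masks.
#' @return Numeric matrix, one row per image (rownames = image ids).
#' @export
embed_dataset <- function(dataset, variant = "colour", D = 256, masks = NULL) {
  ids <- dataset$metadata$image_id
  X <- matrix(0, length(ids), D, dimnames = list(ids, NULL))
  for (id in ids) {
    pm <- dataset$masks[[id]]
    fg <- if (is.null(masks)) pm > 0 else masks[[id]] > 0
    X[id, ] <- embed_specimen(dataset$images[[id]], mask = fg, part_mask = pm,
                              variant = variant, D = D)
  }
  X
}

#' Cosine distance between two feature vectors
#'
#' \eqn{1 - u \cdot v / (\|u\| \|v\|)}; lies in [0, 1] for nonnegative
#' vectors (and [0, 2] for signed external embeddings).
#'
#' @param u,v Numeric vectors of equal length, neither all-zero.
#' @return A single distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for a zero vector")
  max(0, 1 - sum(u * v) / (nu * nv))
}

#' Pairwise cosine distance matrix
#'
#' @param X Numeric matrix, one feature vector per row.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
cosine_dist_matrix <- function(X) {
  if (any(rowSums(X^2) == 0)) stop("cosine distance undefined for a zero vector")
  Xn <- X / sqrt(rowSums(X^2))
  D <- 1 - tcrossprod(Xn)
  D[D < 0] <- 0
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Ridge-regularized linear elevation model
#'
#' Fits a linear map from feature vectors to elevation by minimizing the
#' penalized mean squared error between actual and predicted elevations;
#' ridge regularization (default lambda = 1) keeps the fit defined when
#' the embedding dimension exceeds the number of training images.
#'
#' @param X Training feature matrix (rows = images).
#' @param y Elevations (m), one per row of \code{X}.
#' @param lambda Ridge penalty (>= 0).
#' @return An \code{elevation_model} with coefficients, centring
#'   constants, training \code{mse} (mean of squared residuals) and
#'   training \code{r2}.
#' @export
fit_elevation_model <- function(X, y, lambda = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training rows")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  xc <- colMeans(X)
  yc <- mean(y)
  Xc <- sweep(X, 2, xc)
  beta <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, y - yc))
  fitted <- drop(Xc %*% beta) + yc
  mse <- mean((y - fitted)^2)
  r2 <- if (stats::var(y) > 0) 1 - mse / mean((y - yc)^2) else NA_real_
  structure(list(beta = drop(beta), x_center = xc, y_center = yc,
                 lambda = lambda, mse = mse, r2 = r2),
            class = "elevation_model")
}

#' @export
predict.elevation_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  drop(sweep(X, 2, object$x_center) %*% object$beta) + object$y_center
}

#' Species-level elevation prediction
#'
#' Predicts every image of a species and averages the per-image
#' predictions into the species estimate.
#'
#' @param model An \code{elevation_model}.
#' @param X Feature matrix of all images of one species (>= 1 row).
#' @return Predicted mean elevation (m).
#' @export
predict_species_elevation <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("need at least one image")
  mean(predict(model, X))
}

#' Representative image of a species
#'
#' The image whose sampled elevation is closest to the species' mean
#' elevation; ties break to the lexicographically smallest image id.
#'
#' @param image_ids Character vector of image ids.
#' @param elevations Sampled elevation (m) of each image.
#' @param mean_elevation Species mean elevation; defaults to
#'   \code{mean(elevations)}.
#' @return The selected image id.
#' @export
representative_image <- function(image_ids, elevations,
                                 mean_elevation = mean(elevations)) {
  if (length(image_ids) < 1) stop("need at least one image")
  d <- abs(elevations - mean_elevation)
  ord <- order(d, image_ids)
  image_ids[ord[1]]
}

#' Representative image and mean elevation per species
#'
#' @param metadata Data.frame with \code{image_id}, \code{species_id} and
#'   \code{elevation_m} columns (e.g. from a \code{moth_dataset}). The
#'   species mean elevation is the mean over its images.
#' @return Data.frame: species_id, mean_elev, rep_image.
#' @export
select_representatives <- function(metadata) {
  sp <- split(metadata, metadata$species_id)
  out <- lapply(sp, function(d) {
    me <- mean(d$elevation_m)
    data.frame(species_id = d$species_id[1], mean_elev = me,
               rep_image = representative_image(d$image_id, d$elevation_m, me),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$species_id), ]
}

#' Classical multidimensional scaling
#'
#' Torgerson's method: double-centre the squared-distance matrix
#' (B = -J D^2 J / 2), eigendecompose, and embed on the top
#' \code{dims} eigenpairs; negative eigenvalues (possible for
#' non-Euclidean cosine distances) are truncated to zero. Axis signs are
#' fixed so each coordinate correlates nonnegatively with
#' \code{orient_by} when given (a reporting convention — e.g. orient the
#' trait axis uphill), otherwise so the largest-magnitude loading is
#' positive.
#'
#' @param d Symmetric distance matrix (or \code{dist}).
#' @param dims Number of output dimensions (1 or 2 typical).
#' @param orient_by Optional numeric vector (length n) used to fix axis
#'   signs.
#' @return n x dims coordinate matrix.
#' @export
mds_project <- function(d, dims = 2, orient_by = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric")
  }
  if (n < dims + 1) stop("need at least dims + 1 points")
  A <- -0.5 * d^2
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  eg <- eigen(B, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(dims)], 0)
  coords <- eg$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(ev), dims)
  for (k in seq_len(dims)) {
    s <- if (!is.null(orient_by)) {
      if (stats::sd(coords[, k]) == 0 || stats::sd(orient_by) == 0) 1
      else sign(stats::cor(coords[, k], orient_by))
    } else {
      sign(coords[which.max(abs(coords[, k])), k])
    }
    if (!is.na(s) && s < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  coords
}
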