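# Shared fixtures and independent brute-force oracles.

tiny_config <- function(...) {
  args <- list(n_species = 8, images_per_species = c(1, 2), image_size = 64,
               seed = 7)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# --- brute-force oracles (deliberately naive, loop-based) ----------------

bf_cosine <- function(u, v) {
  dot <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    dot <- dot + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  1 - dot / (sqrt(nu) * sqrt(nv))
}

bf_mean_pairwise <- function(X) {
  n <- nrow(X)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + bf_cosine(X[i, ], X[j, ])
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

bf_var_n <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  s / length(x)
}

bf_t_ic_ir <- function(x_comm, x_region) bf_var_n(x_comm) / bf_var_n(x_region)

bf_t_ip_ic <- function(x, species) {
  s <- 0
  for (sp in unique(species)) {
    xs <- x[species == sp]
    m <- mean(xs)
    for (xi in xs) s <- s + (xi - m)^2
  }
  (s / length(x)) / bf_var_n(x)
}

# random nonnegative feature matrix
rand_features <- function(n, d) {
  matrix(stats::runif(n * d), n, d)
}

# uniform-colour image (unit scale)
uniform_image <- function(h, w, col) {
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- col[k]
  img
}

# mirror an image (and mask) left-right
mirror_image <- function(img) img[, ncol(img[, , 1]):1, , drop = FALSE]
mirror_mask <- function(m) m[, ncol(m):1, drop = FALSE]

# rotate the hue of every pixel by `deg`, preserving S and V
rotate_hue <- function(img, deg) {
  d <- dim(img)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- rgb_to_hsv(px, max_value = 1)
  hsv[, 1] <- (hsv[, 1] + deg) %% 360
  rgb <- hsv_to_rgb(hsv, max_value = 1)
  out <- array(0, dim = d)
  for (k in 1:3) out[, , k] <- matrix(rgb[, k], d[1], d[2])
  out
}
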