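# Internal helpers shared across modules.

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL leaves the
# stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated normal draws via inverse-CDF; vectorized over `mean`.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(clip01(rep_len(mean, n), lo, hi))
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, a, b)
  clip01(stats::qnorm(u, mean, sd), lo, hi)
}

# Soft (linearly interpolated) histogram over [lo, hi); mass sums to 1
# when `vals` is nonempty. `circular` wraps the first and last bin
# (used for hue).
soft_hist <- function(vals, nbins, lo = 0, hi = 1, circular = FALSE) {
  out <- numeric(nbins)
  if (length(vals) == 0L) return(out)
  t <- (vals - lo) / (hi - lo) * nbins - 0.5
  i0 <- floor(t)
  w1 <- t - i0
  i1 <- i0 + 1
  if (circular) {
    i0 <- i0 %% nbins
    i1 <- i1 %% nbins
  } else {
    i0 <- pmin(pmax(i0, 0), nbins - 1)
    i1 <- pmin(pmax(i1, 0), nbins - 1)
  }
  idx <- c(i0, i1) + 1L
  w <- c(1 - w1, w1)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out / length(vals)
}

# Accumulate weights `w` into `n` cells indexed by `idx` (1-based).
accum <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Soft joint histogram of two variables (a circular option for the first).
soft_hist2 <- function(x, y, nx, ny, xlo = 0, xhi = 1, ylo = 0, yhi = 1,
                       x_circular = FALSE) {
  npix <- length(x)
  if (npix == 0L) return(numeric(nx * ny))
  tx <- (x - xlo) / (xhi - xlo) * nx - 0.5
  ix0 <- floor(tx); wx1 <- tx - ix0; ix1 <- ix0 + 1
  if (x_circular) {
    ix0 <- ix0 %% nx; ix1 <- ix1 %% nx
  } else {
    ix0 <- pmin(pmax(ix0, 0), nx - 1); ix1 <- pmin(pmax(ix1, 0), nx - 1)
  }
  ty <- (y - ylo) / (yhi - ylo) * ny - 0.5
  iy0 <- floor(ty); wy1 <- ty - iy0; iy1 <- iy0 + 1
  iy0 <- pmin(pmax(iy0, 0), ny - 1); iy1 <- pmin(pmax(iy1, 0), ny - 1)
  idx <- c(ix0 * ny + iy0, ix0 * ny + iy1, ix1 * ny + iy0, ix1 * ny + iy1) + 1L
  w <- c((1 - wx1) * (1 - wy1), (1 - wx1) * wy1, wx1 * (1 - wy1), wx1 * wy1)
  accum(idx, w, nx * ny) / npix
}

# Points (px, py) inside the convex polygon with vertices (vx, vy).
# Orientation-agnostic: all edge cross-products must share a sign.
in_convex_polygon <- function(px, py, vx, vy) {
  k <- length(vx)
  pos <- rep(TRUE, length(px))
  neg <- rep(TRUE, length(px))
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    pos <- pos & (cr >= 0)
    neg <- neg & (cr <= 0)
  }
  pos | neg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
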