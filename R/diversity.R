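#' Bin species into elevational assemblages
#'
#' Half-open 100-m bins \code{[k*width, (k+1)*width)} on species mean
#' elevation; empty bins are omitted. Assemblages with fewer than two
#' species cannot contribute a diversity value and are flagged.
#'
#' @param mean_elev Species mean elevations (m, nonnegative).
#' @param width Bin width in metres (default 100).
#' @return Data.frame, one row per species: \code{bin_lo}, \code{label}
#'   (e.g. "0-100 m"), \code{midpoint}.
#' @export
bin_species <- function(mean_elev, width = 100) {
  if (any(mean_elev < 0)) stop("elevations must be nonnegative")
  lo <- floor(mean_elev / width) * width
  data.frame(bin_lo = lo,
             label = sprintf("%d-%d m", as.integer(lo), as.integer(lo + width)),
             midpoint = lo + width / 2,
             stringsAsFactors = FALSE)
}

#' Build assemblage objects from species-level data
#'
#' @param species_id Character vector of species ids.
#' @param mean_elev Species mean elevations (m).
#' @param vectors Matrix of representative feature vectors (rows follow
#'   \code{species_id}).
#' @param family_id Optional species family ids (needed for the family
#'   bootstrap).
#' @param width Bin width (m).
#' @return List of assemblages ordered by elevation; each has
#'   \code{label}, \code{bin_lo}, \code{midpoint}, \code{species},
#'   \code{families}, \code{vectors}, \code{n}.
#' @export
build_assemblages <- function(species_id, mean_elev, vectors,
                              family_id = NULL, width = 100) {
  bins <- bin_species(mean_elev, width)
  out <- list()
  for (lo in sort(unique(bins$bin_lo))) {
    idx <- which(bins$bin_lo == lo)
    out[[length(out) + 1L]] <- list(
      label = bins$label[idx[1]],
      bin_lo = lo,
      midpoint = bins$midpoint[idx[1]],
      species = species_id[idx],
      families = if (is.null(family_id)) NULL else family_id[idx],
      vectors = vectors[idx, , drop = FALSE],
      n = length(idx)
    )
  }
  out
}

#' Within-assemblage feature diversity
#'
#' Mean cosine distance over all n(n-1)/2 unordered species pairs.
#'
#' @param vectors Feature matrix of the assemblage's members (>= 2 rows),
#'   or a precomputed symmetric distance matrix (set
#'   \code{is_dist = TRUE}).
#' @param is_dist Interpret \code{vectors} as a distance matrix.
#' @return Mean pairwise distance.
#' @export
within_diversity <- function(vectors, is_dist = FALSE) {
  n <- nrow(vectors)
  if (is.null(n) || n < 2) stop("need at least 2 members")
  d <- if (is_dist) vectors else cosine_dist_matrix(vectors)
  mean(d[upper.tri(d)])
}

#' Diversity record per assemblage
#'
#' @param assemblages Output of \code{\link{build_assemblages}}.
#' @return Data.frame with one row per assemblage holding >= 2 species:
#'   label, midpoint, n_species, diversity.
#' @export
assemblage_diversity <- function(assemblages) {
  keep <- vapply(assemblages, function(a) a$n >= 2, logical(1))
  rows <- lapply(assemblages[keep], function(a) {
    data.frame(label = a$label, midpoint = a$midpoint, n_species = a$n,
               diversity = within_diversity(a$vectors),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares trend of a response along a gradient
#'
#' Gaussian OLS of y on x with the F statistic on (1, n-2) degrees of
#' freedom, two-sided p, plain and adjusted R-squared, and the t-based
#' 95\% confidence interval of the slope.
#'
#' @param y Response (e.g. assemblage diversity).
#' @param x Predictor (elevation, temperature or precipitation).
#' @return A \code{trend_fit} list: intercept, slope, r2, adj_r2, fstat,
#'   df1, df2, p, slope_ci, n.
#' @export
fit_trend <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 records")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- tryCatch(stats::confint(fit)[2, ], error = function(e) c(NA_real_, NA_real_))
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    fstat = unname(sm$fstatistic[1]),
    df1 = 1, df2 = n - 2,
    p = stats::pf(sm$fstatistic[1], 1, n - 2, lower.tail = FALSE),
    slope_ci = unname(ci),
    n = n
  ), class = "trend_fit")
}

# Vectorized OLS of many bootstrap responses on one predictor.
# Y: reps x k matrix; x: length k. Returns a data.frame of per-rep stats.
ols_stats_many <- function(Y, x) {
  k <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- drop(Y %*% xc) / sxx
  ybar <- rowMeans(Y)
  intercept <- ybar - slope * mean(x)
  ssy <- rowSums((Y - ybar)^2)
  sse <- ssy - slope^2 * sxx
  r2 <- ifelse(ssy > 0, 1 - sse / ssy, NaN)
  fstat <- ifelse(sse > 0, (r2 / 1) / ((1 - r2) / (k - 2)), Inf)
  data.frame(intercept = intercept, slope = slope, r2 = r2, fstat = fstat)
}

boot_ci_table <- function(stats_df, reps, m, seed) {
  params <- names(stats_df)
  ci <- t(vapply(params, function(p) {
    v <- stats_df[[p]]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(0.025, 0.975), names = FALSE)
  }, numeric(2)))
  out <- data.frame(param = params, lower = ci[, 1], upper = ci[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "reps") <- reps
  attr(out, "m") <- m
  attr(out, "seed") <- seed
  rownames(out) <- NULL
  out
}

#' Pairwise-resampling bootstrap of the diversity trend
#'
#' In each repeat, every assemblage's diversity is recomputed as the mean
#' of \code{m} pairwise cosine distances drawn with replacement from that
#' assemblage's observed pairwise distances (equalizing effective sample
#' size across assemblages — \code{m} defaults to choose(n_min, 2), the
#' pair count of the smallest assemblage); the trend on the bin-midpoint
#' elevation is then refit. 2.5/97.5 percentile bounds over repeats give
#' 95\% intervals for intercept, slope, R-squared and F.
#'
#' @param assemblages Output of \code{\link{build_assemblages}};
#'   assemblages with < 2 species are excluded.
#' @param m Resample size per assemblage (pair draws); NULL = pair count
#'   of the smallest included assemblage.
#' @param reps Bootstrap repeats (default 5000; < 100 triggers a warning).
#' @param seed Seed for the resampling stream (restored afterwards).
#' @return Data.frame of percentile CIs with attributes \code{reps},
#'   \code{m}, \code{seed}.
#' @export
bootstrap_pairwise <- function(assemblages, m = NULL, reps = 5000, seed = 1) {
  keep <- Filter(function(a) a$n >= 2, assemblages)
  if (length(keep) < 3) stop("need at least 3 assemblages with 2+ species")
  if (!is.null(m) && m <= 0) stop("m must be positive")
  if (reps < 100) warning("fewer than 100 bootstrap repeats")
  pair_dists <- lapply(keep, function(a) {
    d <- cosine_dist_matrix(a$vectors)
    d[upper.tri(d)]
  })
  if (is.null(m)) m <- min(vapply(keep, function(a) choose(a$n, 2), numeric(1)))
  x <- vapply(keep, function(a) a$midpoint, numeric(1))
  Y <- with_seed(seed, {
    vapply(pair_dists, function(d) {
      rowMeans(matrix(sample(d, reps * m, replace = TRUE), nrow = reps))
    }, numeric(reps))
  })
  if (reps == 1) Y <- matrix(Y, nrow = 1)
  boot_ci_table(ols_stats_many(Y, x), reps, m, seed)
}

#' Family-grouped bootstrap of the diversity trend
#'
#' In each repeat, four families are drawn with replacement from those
#' present in each assemblage, the member species of the drawn families
#' are pooled, the assemblage diversity is recomputed on the pooled
#' species (assemblages yielding < 2 species are skipped that repeat)
#' and the trend refit. Controls for family composition (a grouped
#' stand-in for phylogenetic structure).
#'
#' @param assemblages Output of \code{\link{build_assemblages}} (built
#'   with \code{family_id}).
#' @param n_fam Families drawn per assemblage per repeat (default 4).
#' @param reps Repeats (default 1000).
#' @param seed Seed (restored afterwards).
#' @return Percentile CI table as in \code{\link{bootstrap_pairwise}}.
#' @export
bootstrap_family <- function(assemblages, n_fam = 4, reps = 1000, seed = 1) {
  keep <- Filter(function(a) a$n >= 2, assemblages)
  if (length(keep) < 3) stop("need at least 3 assemblages with 2+ species")
  if (any(vapply(keep, function(a) is.null(a$families), logical(1)))) {
    stop("assemblages lack family ids")
  }
  if (reps < 100) warning("fewer than 100 bootstrap repeats")
  dmats <- lapply(keep, function(a) cosine_dist_matrix(a$vectors))
  fams <- lapply(keep, function(a) a$families)
  ufams <- lapply(fams, unique)
  x_all <- vapply(keep, function(a) a$midpoint, numeric(1))
  res <- with_seed(seed, {
    out <- vector("list", reps)
    for (r in seq_len(reps)) {
      yv <- rep(NA_real_, length(keep))
      for (i in seq_along(keep)) {
        pick <- sample(ufams[[i]], n_fam, replace = TRUE)
        sp <- which(fams[[i]] %in% pick)
        if (length(sp) >= 2) {
          d <- dmats[[i]][sp, sp]
          yv[i] <- mean(d[upper.tri(d)])
        }
      }
      ok <- is.finite(yv)
      out[[r]] <- if (sum(ok) >= 3 && stats::sd(x_all[ok]) > 0) {
        ols_stats_many(matrix(yv[ok], nrow = 1), x_all[ok])
      } else {
        data.frame(intercept = NA_real_, slope = NA_real_, r2 = NA_real_,
                   fstat = NA_real_)
      }
    }
    do.call(rbind, out)
  })
  boot_ci_table(res, reps, n_fam, seed)
}

#' Species turnover between adjacent assemblages
#'
#' Sorensen dissimilarity between consecutive occupied bins, with bin
#' membership defined by each species' full sampled elevational range
#' overlapping the bin (so wide-ranging species appear in several bins).
#'
#' @param min_elev,max_elev Species elevational range limits (m).
#' @param width Bin width (m).
#' @return Data.frame: from_label, to_label, turnover in [0, 1]
#'   (0 = identical membership, 1 = disjoint).
#' @export
beta_diversity_profile <- function(min_elev, max_elev, width = 100) {
  if (length(min_elev) != length(max_elev)) stop("range vectors differ in length")
  lo_bin <- floor(min_elev / width)
  hi_bin <- floor(pmax(min_elev, max_elev - 1e-9) / width)
  bins <- sort(unique(unlist(mapply(seq, lo_bin, hi_bin, SIMPLIFY = FALSE))))
  members <- lapply(bins, function(b) which(lo_bin <= b & hi_bin >= b))
  members <- members[vapply(members, length, integer(1)) > 0]
  bins <- bins[vapply(lapply(bins, function(b) which(lo_bin <= b & hi_bin >= b)),
                      length, integer(1)) > 0]
  if (length(bins) < 2) stop("need at least 2 occupied bins")
  out <- data.frame()
  for (i in seq_len(length(bins) - 1)) {
    a <- members[[i]]; b <- members[[i + 1]]
    turn <- 1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
    out <- rbind(out, data.frame(
      from_label = sprintf("%d-%d m", as.integer(bins[i] * width),
                           as.integer((bins[i] + 1) * width)),
      to_label = sprintf("%d-%d m", as.integer(bins[i + 1] * width),
                         as.integer((bins[i + 1] + 1) * width)),
      turnover = turn, stringsAsFactors = FALSE))
  }
  out
}
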