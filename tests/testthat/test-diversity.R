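test_that("species binning uses half-open 100-m intervals", {
  b <- bin_species(c(50, 99, 100))
  expect_equal(b$bin_lo, c(0, 0, 100))
  expect_equal(b$label[1], "0-100 m")
  expect_equal(b$midpoint, c(50, 50, 150))
  expect_error(bin_species(c(-5, 10)), "nonnegative")

  # alternative widths partition the same species set
  e <- runif(200, 0, 2500)
  for (w in c(50, 100, 250)) {
    expect_equal(nrow(bin_species(e, w)), 200)
  }
})

test_that("within-assemblage diversity equals the brute-force pair mean", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    X <- rand_features(n, 5)
    expect_equal(within_diversity(X), bf_mean_pairwise(X), tolerance = 1e-12)
  }
  # identical members: zero diversity
  same <- matrix(rep(runif(4), each = 3), 3, 4)
  expect_equal(within_diversity(same), 0, tolerance = 1e-12)
  two <- rand_features(2, 5)
  expect_equal(within_diversity(two), cosine_distance(two[1, ], two[2, ]))
  expect_error(within_diversity(rand_features(1, 5)), "2 members")
  # 11 members average choose(11, 2) = 55 pairwise distances
  X11 <- rand_features(11, 5)
  D <- cosine_dist_matrix(X11)
  expect_equal(length(D[upper.tri(D)]), 55)
  expect_equal(within_diversity(X11), mean(D[upper.tri(D)]))
})

test_that("trend fitting matches exact lines and the null R-squared law", {
  x <- seq(100, 1900, by = 100)
  y <- 0.5 - 1e-4 * x
  tr <- suppressWarnings(fit_trend(y, x))  # exact fit warns
  expect_equal(tr$slope, -1e-4)
  expect_equal(tr$r2, 1)
  expect_equal(tr$df1, 1); expect_equal(tr$df2, 17)   # 19 records -> (1, 17)

  set.seed(14)
  r2s <- replicate(1000, fit_trend(rnorm(19), seq_len(19))$r2)
  expect_lt(abs(mean(r2s) - 1 / 18), 0.02)

  expect_error(fit_trend(c(1, 2), c(1, 2)), "3 records")
  expect_error(fit_trend(rnorm(5), rep(1, 5)), "constant")
})

make_assemblages <- function(n_asm = 6, n_sp = 8, seed = 1, slope = 0) {
  set.seed(seed)
  sp <- sprintf("sp%03d", seq_len(n_asm * n_sp))
  elev <- rep(seq(50, by = 100, length.out = n_asm), each = n_sp)
  spread <- 1 + slope * rep(seq_len(n_asm), each = n_sp)
  X <- rand_features(n_asm * n_sp, 6) * spread
  fam <- rep_len(sprintf("f%d", 1:5), n_asm * n_sp)
  build_assemblages(sp, elev, X, family_id = fam)
}

test_that("pairwise bootstrap is seeded, degenerate-safe and consistent", {
  asm <- make_assemblages(seed = 2)
  b1 <- bootstrap_pairwise(asm, reps = 300, seed = 5)
  b2 <- bootstrap_pairwise(asm, reps = 300, seed = 5)
  expect_identical(b1, b2)
  expect_warning(bootstrap_pairwise(asm, reps = 50, seed = 1), "100")
  expect_error(bootstrap_pairwise(asm, m = 0, reps = 300, seed = 1), "positive")

  # all pairwise distances equal 1 (orthogonal members): CIs collapse onto
  # the point values slope = 0, intercept = 1
  Xc <- do.call(rbind, replicate(3, diag(4)[1:3, ], simplify = FALSE))
  asm_c <- build_assemblages(sprintf("s%d", 1:9), rep(c(50, 150, 250), each = 3), Xc)
  bc <- bootstrap_pairwise(asm_c, reps = 200, seed = 3)
  sl <- bc[bc$param == "slope", ]
  expect_equal(sl$lower, 0, tolerance = 1e-12)
  expect_equal(sl$upper, 0, tolerance = 1e-12)
  ic <- bc[bc$param == "intercept", ]
  expect_equal(ic$lower, 1, tolerance = 1e-12)
  expect_equal(ic$upper, 1, tolerance = 1e-12)
})

test_that("pairwise bootstrap converges to the point estimate as m grows", {
  asm <- make_assemblages(n_asm = 5, n_sp = 7, seed = 6, slope = 0.5)
  div <- assemblage_diversity(asm)
  point <- fit_trend(div$diversity, div$midpoint)$slope
  b <- bootstrap_pairwise(asm, m = 1e4, reps = 200, seed = 9)
  sl <- b[b$param == "slope", ]
  expect_lt(abs(sl$lower - point), 1e-3)
  expect_lt(abs(sl$upper - point), 1e-3)
})

test_that("family bootstrap degenerates to a point for a single family", {
  asm <- make_assemblages(seed = 4)
  for (i in seq_along(asm)) asm[[i]]$families <- rep("only", asm[[i]]$n)
  b <- bootstrap_family(asm, reps = 150, seed = 2)
  div <- assemblage_diversity(asm)
  point <- fit_trend(div$diversity, div$midpoint)$slope
  sl <- b[b$param == "slope", ]
  expect_equal(sl$lower, point, tolerance = 1e-12)
  expect_equal(sl$upper, point, tolerance = 1e-12)

  b1 <- bootstrap_family(asm, reps = 150, seed = 8)
  b2 <- bootstrap_family(asm, reps = 150, seed = 8)
  expect_identical(b1, b2)
})

test_that("adjacent-bin turnover follows the Sorensen arithmetic", {
  # two species spanning both bins: identical membership, turnover 0
  t0 <- beta_diversity_profile(c(10, 20), c(190, 180))
  expect_equal(t0$turnover, 0)
  # disjoint memberships: turnover 1
  t1 <- beta_diversity_profile(c(10, 110), c(90, 190))
  expect_equal(t1$turnover, 1)
  # equal sizes, half shared
  t2 <- beta_diversity_profile(c(10, 20, 110, 120), c(90, 190, 190, 190))
  # bin1 = {1,2}, bin2 = {2,3,4}: sorensen = 1 - 2*1/5
  expect_equal(t2$turnover, 1 - 2 / 5)
})
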