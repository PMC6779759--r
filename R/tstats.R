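# Variance partitioning of a one-dimensional trait across organizational
# levels: individuals within populations (species), within communities
# (assemblages) and within the regional pool. Variances use denominator
# n by default, under which the law of total variance holds exactly and
# is asserted on every computation.

pop_var <- function(x, denom = c("n", "n1")) {
  denom <- match.arg(denom)
  n <- length(x)
  if (n < 2) return(0)
  s <- sum((x - mean(x))^2)
  if (denom == "n") s / n else s / (n - 1)
}

#' Ratio of within-assemblage to regional trait variance (T_IC/IR)
#'
#' Variance of individual trait values within one assemblage divided by
#' the variance over all individuals in the regional pool; each variance
#' is taken around its own mean. Low values indicate external
#' (environmental) filtering of the assemblage's trait distribution.
#'
#' @param x_comm Trait values of the assemblage's individuals (>= 2).
#' @param x_region Trait values of all individuals in the region (>= 2).
#' @param denom Variance denominator: "n" (default; trait-statistics
#'   convention) or "n1".
#' @return The variance ratio (>= 0).
#' @export
t_ic_ir <- function(x_comm, x_region, denom = "n") {
  if (length(x_comm) < 2 || length(x_region) < 2) stop("need >= 2 individuals")
  vr <- pop_var(x_region, denom)
  if (vr == 0) stop("zero regional variance")
  pop_var(x_comm, denom) / vr
}

#' Ratio of pooled within-species to within-assemblage variance (T_IP/IC)
#'
#' Pooled within-population variance — the mean squared deviation of
#' individuals from their own species mean, pooled over the assemblage's
#' species — divided by the total within-assemblage variance of
#' individuals. Low values indicate internal filtering (interspecific
#' competition spacing species out in trait space).
#'
#' @param x Trait values of the assemblage's individuals (>= 2).
#' @param species Species id of each individual.
#' @param denom Variance denominator, see \code{\link{t_ic_ir}}.
#' @return The variance ratio in [0, 1] under \code{denom = "n"}.
#' @export
t_ip_ic <- function(x, species, denom = "n") {
  if (length(x) < 2) stop("need >= 2 individuals")
  if (length(x) != length(species)) stop("x and species differ in length")
  vc <- pop_var(x, denom)
  if (vc == 0) stop("zero community variance")
  pooled_within(x, species, denom) / vc
}

pooled_within <- function(x, species, denom = "n") {
  sp <- split(x, species)
  dev2 <- sum(vapply(sp, function(v) sum((v - mean(v))^2), numeric(1)))
  if (denom == "n") dev2 / length(x)
  else {
    df <- length(x) - length(sp)
    if (df <= 0) 0 else dev2 / df
  }
}

#' T-statistic table over all assemblages
#'
#' Computes the variance components and both ratios for every assemblage
#' from individual-level trait observations (one scalar per specimen
#' image, typically the 1-D MDS coordinate of its feature vector over
#' the full regional pool). Population = species within one assemblage;
#' individual = one specimen image. Under the denominator-n convention
#' the law of total variance (within-assemblage variance = pooled
#' within-species variance + weighted variance of species means) is
#' asserted on every assemblage.
#'
#' @param trait Individual trait values.
#' @param species Species id per individual.
#' @param assemblage Assemblage label per individual.
#' @param denom Variance denominator ("n" default; the law-of-total-
#'   variance assertion applies only to "n").
#' @return Data.frame per assemblage: label, n_ind, n_species, var_ip
#'   (pooled within-species), var_ic (within-assemblage), t_ip_ic,
#'   t_ic_ir; the regional variance is attached as attribute
#'   \code{var_ir}. Assemblages with < 2 individuals or zero variance
#'   yield NA ratios.
#' @export
t_stats <- function(trait, species, assemblage, denom = "n") {
  if (length(trait) != length(species) || length(trait) != length(assemblage)) {
    stop("trait, species and assemblage must have equal length")
  }
  var_ir <- pop_var(trait, denom)
  if (var_ir == 0) stop("zero regional variance")
  labs <- unique(assemblage)
  rows <- lapply(labs, function(l) {
    idx <- assemblage == l
    x <- trait[idx]
    sp <- species[idx]
    n <- length(x)
    if (n < 2) {
      return(data.frame(label = l, n_ind = n, n_species = length(unique(sp)),
                        var_ip = NA_real_, var_ic = NA_real_,
                        t_ip_ic = NA_real_, t_ic_ir = NA_real_,
                        stringsAsFactors = FALSE))
    }
    vic <- pop_var(x, denom)
    vip <- pooled_within(x, sp, denom)
    if (denom == "n") {
      mu <- vapply(split(x, sp), mean, numeric(1))
      w <- vapply(split(x, sp), length, numeric(1)) / n
      between <- sum(w * (mu - mean(x))^2)
      if (abs(vic - (vip + between)) > 1e-9 * max(1, vic)) {
        stop("law of total variance violated (internal error)")
      }
    }
    data.frame(label = l, n_ind = n, n_species = length(unique(sp)),
               var_ip = vip, var_ic = vic,
               t_ip_ic = if (vic > 0) vip / vic else NA_real_,
               t_ic_ir = vic / var_ir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "var_ir") <- var_ir
  out
}
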