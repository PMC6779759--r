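#' Path analysis: temperature -> relative brightness -> trait variation
#'
#' Fits the recursive causal chain as sequential standardized OLS
#' regressions: assemblage mean brightness index on temperature, and
#' log-transformed within-assemblage variance ratio (T_IC/IR) on the
#' brightness index. All variables are z-scored, so each single-predictor
#' path coefficient equals the Pearson correlation of the pair and lies
#' in [-1, 1]; the indirect effect of temperature on trait variation is
#' the product of the two coefficients. For a recursive chain with
#' single predecessors these coincide with the structural-equation
#' estimates (no global fit statistic is produced).
#'
#' @param temperature Assemblage temperature (degrees C).
#' @param b_index Assemblage mean brightness index B = Bf/Bw.
#' @param t_ic_ir Assemblage T_IC/IR (> 0; log-transformed internally).
#' @return A \code{path_fit}: \code{edges} data.frame (edge, coef, r2,
#'   fstat, p, ci_lo, ci_hi), \code{indirect} effect, \code{n}.
#' @export
fit_path <- function(temperature, b_index, t_ic_ir) {
  n <- length(temperature)
  if (n < 4) stop("need at least 4 assemblages")
  if (length(b_index) != n || length(t_ic_ir) != n) stop("inputs differ in length")
  if (any(!is.finite(t_ic_ir)) || any(t_ic_ir <= 0)) {
    stop("T_IC/IR must be positive for the log transform")
  }
  zt <- as.vector(scale(temperature))
  zb <- as.vector(scale(b_index))
  zl <- as.vector(scale(log(t_ic_ir)))
  e1 <- path_edge("temperature -> brightness", zt, zb)
  e2 <- path_edge("brightness -> log T_IC/IR", zb, zl)
  edges <- rbind(e1, e2)
  structure(list(edges = edges, indirect = e1$coef * e2$coef, n = n),
            class = "path_fit")
}

path_edge <- function(name, zx, zy) {
  fit <- stats::lm(zy ~ zx)
  sm <- summary(fit)
  ci <- stats::confint(fit)[2, ]
  data.frame(edge = name,
             coef = unname(stats::coef(fit)[2]),
             r2 = sm$r.squared,
             fstat = unname(sm$fstatistic[1]),
             p = stats::pf(sm$fstatistic[1], 1, length(zx) - 2, lower.tail = FALSE),
             ci_lo = unname(ci[1]), ci_hi = unname(ci[2]),
             stringsAsFactors = FALSE)
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Standardized path model (n =", x$n, "assemblages)\n")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %-28s coef = %6.3f  R2 = %5.3f  p = %.3g\n",
                e$edge, e$coef, e$r2, e$p))
  }
  cat(sprintf("  indirect effect (product)    = %6.3f\n", x$indirect))
  invisible(x)
}

#' Saturation side-check of the constraint model
#'
#' OLS of log T_IC/IR on the assemblage mean saturation index; under the
#' colour-space constraint, more saturated (darker) assemblages should
#' show lower within-assemblage trait variation (negative slope).
#'
#' @param s_index Assemblage mean saturation index S = Sf/Sw.
#' @param t_ic_ir Assemblage T_IC/IR (> 0).
#' @return A \code{\link{fit_trend}} object.
#' @export
fit_saturation_check <- function(s_index, t_ic_ir) {
  if (any(!is.finite(t_ic_ir)) || any(t_ic_ir <= 0)) {
    stop("T_IC/IR must be positive for the log transform")
  }
  fit_trend(log(t_ic_ir), s_index)
}
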