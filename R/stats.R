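#' One-tailed Pearson correlation
#'
#' Product-moment correlation with a one-tailed p-value from the t
#' transform, in the hypothesised direction. Correlations opposite to the
#' hypothesis give p > 0.5 (e.g. a negative r tested under a positive
#' directional hypothesis).
#'
#' @param x,y numeric vectors (length >= 4, finite, nonzero variance).
#' @param direction `"positive"` (more damage, larger measure) or
#'   `"negative"`.
#' @return list of class `correlation_result`: `r`, `n`, `t`, `df`,
#'   `p_one_tailed`, `direction`.
#' @examples
#' set.seed(1)
#' x <- rnorm(18); y <- x + rnorm(18)
#' pearson_one_tailed(x, y, "positive")
#' @export
pearson_one_tailed <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  df <- n - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- if (direction == "positive") {
    stats::pt(tval, df, lower.tail = FALSE)
  } else {
    stats::pt(tval, df, lower.tail = TRUE)
  }
  structure(list(r = r, n = n, t = tval, df = df, p_one_tailed = p,
                 direction = direction),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, n = %d, one-tailed p = %.3f (%s)\n",
              x$r, x$n, x$p_one_tailed, x$direction))
  invisible(x)
}

#' Fisher's z transform
#'
#' `artanh(r) = log((1 + r) / (1 - r)) / 2`; odd in r, defined for |r| < 1.
#'
#' @param r correlation with `abs(r) < 1`.
#' @return transformed value.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}

#' Meng's z test for two dependent, overlapping correlations
#'
#' Compares `r1 = cor(x1, y)` against `r2 = cor(x2, y)` when both share the
#' variable `y` (here: two lesion-volume predictors against one behavioural
#' measure), given `r12 = cor(x1, x2)`, using the Fisher-transform statistic
#' of Meng, Rosenthal and Rubin (1992):
#'
#' `z = (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))`
#'
#' with `rbar2 = (r1^2 + r2^2) / 2`,
#' `f = min(1, (1 - r12) / (2 * (1 - rbar2)))` and
#' `h = (1 - f * rbar2) / (1 - rbar2)`. The p-value is two-tailed normal.
#'
#' @param r1,r2 the two correlations sharing a variable (|r| < 1).
#' @param r12 correlation between the two non-shared variables.
#' @param n sample size (>= 4).
#' @return list of class `comparison_result`: `r1`, `r2`, `r12`, `n`, `z`,
#'   `p_two_tailed`.
#' @examples
#' meng_z(0.6, 0.3, 0.2, n = 18)
#' @export
meng_z <- function(r1, r2, r12, n) {
  for (v in list(r1 = r1, r2 = r2, r12 = r12)) {
    if (!is.finite(v) || abs(v) >= 1) {
      stop("correlations must be finite with |r| < 1", call. = FALSE)
    }
  }
  if (n < 4) stop("need n >= 4", call. = FALSE)
  R <- matrix(c(1, r1, r2,
                r1, 1, r12,
                r2, r12, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("infeasible correlation triple (r1, r2, r12)", call. = FALSE)
  }
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (fisher_z(r1) - fisher_z(r2)) *
    sqrt((n - 3) / (2 * (1 - r12) * h))
  structure(list(r1 = r1, r2 = r2, r12 = r12, n = n, z = z,
                 p_two_tailed = 2 * stats::pnorm(-abs(z))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Meng's z = %.3f, two-tailed p = %.3f (r1 = %.3f, r2 = %.3f, r12 = %.3f, n = %d)\n",
              x$z, x$p_two_tailed, x$r1, x$r2, x$r12, as.integer(x$n)))
  invisible(x)
}
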