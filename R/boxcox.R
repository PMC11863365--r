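# Box-Cox power transform of the (strictly positive) relative-sensitivity
# target, with maximum-likelihood estimation of lambda and an exact inverse.

#' Box-Cox transform
#'
#' `(y^lambda - 1)/lambda` for `lambda != 0`, `log(y)` at `lambda = 0`.
#'
#' @param y Strictly positive values.
#' @param lambda Power parameter.
#' @return Transformed values.
#' @export
boxcox_transform <- function(y, lambda) {
  abort_if(any(y <= 0), "Box-Cox requires strictly positive values")
  if (abs(lambda) < 1e-10) log(y) else (y^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#'
#' Exact algebraic inverse of [boxcox_transform()]. Out-of-domain inputs
#' (where `lambda * z + 1 <= 0`, which can arise when a regressor
#' extrapolates) are clamped to a tiny positive value so predictions remain
#' finite and strictly positive.
#'
#' @param z Transformed values.
#' @param lambda Power parameter used in the forward transform.
#' @return Values on the original (positive) scale.
#' @export
boxcox_inverse <- function(z, lambda) {
  if (abs(lambda) < 1e-10) return(exp(z))
  base <- pmax(lambda * z + 1, 1e-12)
  base^(1 / lambda)
}

#' Estimate the Box-Cox lambda by maximum likelihood
#'
#' Maximizes the profile log-likelihood of the normal model for the
#' transformed values over `interval` (golden-section search refined to
#' `tol`).
#'
#' @param y Strictly positive values (at least 3).
#' @param interval Search interval for lambda. Default `c(-2, 2)`.
#' @return List with `lambda` and the forward-`transformed` values.
#' @export
boxcox_fit <- function(y, interval = c(-2, 2)) {
  abort_if(any(y <= 0), "Box-Cox requires strictly positive values")
  abort_if(length(y) < 3, "need at least 3 values to estimate lambda")
  n <- length(y)
  slog <- sum(log(y))
  ll <- function(lambda) {
    z <- boxcox_transform(y, lambda)
    s2 <- mean((z - mean(z))^2)
    if (s2 <= 0) return(Inf)                  # degenerate (constant) sample
    -n / 2 * log(s2) + (lambda - 1) * slog
  }
  if (sd(y) == 0) return(list(lambda = 1, transformed = boxcox_transform(y, 1)))
  opt <- optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  list(lambda = lambda, transformed = boxcox_transform(y, lambda))
}
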