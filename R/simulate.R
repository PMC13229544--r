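#' doseresp: nonparametric inference on the causal dose-response function
#'
#' Tools for testing whether the mean-centered causal dose-response
#' function of a bounded continuous exposure equals a candidate curve, and
#' for building simultaneous confidence bands for the centered curve by
#' test inversion. The test estimates inner products between the curve
#' contrast and a truncated Sobolev eigenbasis with one-step or targeted
#' minimum loss (TML) estimators, maximizes the estimated inner product
#' over a roughness-bounded, unit-variance function class via the KKT
#' closed form, and calibrates the supremum with a multiplier bootstrap of
#' the estimated efficient influence functions.
#'
#' @keywords internal
#' @importFrom stats approx coef dnorm integrate median optim optimize
#'   plogis predict quantile rnorm runif sd uniroot var
"_PACKAGE"

#' Confounding function for the simulated designs
#'
#' The scalar summary of the bivariate covariate that drives both the
#' exposure density tilt and the outcome-level confounding in the
#' synthetic designs: `zeta(w) = 3 * (expit(w1 + w2) - 1/2)`. It is odd
#' under `(w1, w2) -> (-w1, -w2)`, bounded in (-3/2, 3/2), and has mean
#' zero over any W distribution that is symmetric about the origin.
#'
#' @param w1,w2 Numeric vectors (recycled) of covariate values.
#' @return Numeric vector of the same length as the longer input.
#' @export
#' @examples
#' zeta(0, 0)       # 0
#' zeta(10, 10)     # ~ 1.5
zeta <- function(w1, w2) {
  3 * (plogis(w1 + w2) - 0.5)
}

# Normalizing constant int_{-1}^{1} expit(z * u) du. The antiderivative of
# u -> expit(z u) is log(1 + exp(z u)) / z, so the constant is
# [log1pexp(z) - log1pexp(-z)] / z, with limit 1 as z -> 0.
.expit_norm_const <- function(z) {
  out <- rep(1, length(z))
  big <- abs(z) >= 1e-8
  zb <- z[big]
  out[big] <- (.log1pexp(zb) - .log1pexp(-zb)) / zb
  out
}

.log1pexp <- function(x) {
  # log(1 + exp(x)) without overflow
  ifelse(x > 35, x, log1p(exp(pmin(x, 35))))
}

#' Conditional exposure density of the simulated designs
#'
#' Density of the exposure A given covariates, proportional to
#' `expit(zeta(w) * a)` on `[-1, 1]`:
#' `g0(a | w) = expit(zeta(w) a) / int_{-1}^{1} expit(zeta(w) u) du`.
#'
#' @param a Numeric vector of exposure values in `[-1, 1]`.
#' @param w1,w2 Covariate values (scalars or vectors recycled against `a`).
#' @return Nonnegative density values; integrates to one over `[-1, 1]`
#'   for every `w`.
#' @export
conditional_exposure_density <- function(a, w1, w2) {
  if (any(a < -1 - 1e-12 | a > 1 + 1e-12)) {
    stop("exposure values must lie in [-1, 1]")
  }
  z <- zeta(w1, w2)
  plogis(z * a) / .expit_norm_const(z)
}

#' True dose-response curves of the simulated designs
#'
#' Under the null design (`"flat_null"`) the dose-response function is
#' identically zero; under the alternative design (`"cubic_alt"`) it is
#' the cubic `theta0(a) = (2 a + a^2 - 3 a^3) / 2` on `[-1, 1]`.
#'
#' @param a Numeric vector of exposures in `[-1, 1]`.
#' @param setting `"flat_null"` or `"cubic_alt"`.
#' @return Numeric vector `theta0(a)`.
#' @export
true_theta <- function(a, setting = c("flat_null", "cubic_alt")) {
  setting <- match.arg(setting)
  if (setting == "flat_null") {
    rep(0, length(a))
  } else {
    (2 * a + a^2 - 3 * a^3) / 2
  }
}

# Inverse-CDF sampler for the conditional exposure law. The conditional
# CDF given zeta(w) = z has closed antiderivative
#   G(a) = [L(z a) - L(-z)] / (z * C(z)),  L = log1pexp,
# but we invert on a fine grid with linear interpolation, which is exact
# enough (grid error << Monte Carlo noise) and robust near z = 0.
.icdf_grid <- 1000L

#' Draw exposures from the confounded conditional density
#'
#' Samples each `A_i` from [conditional_exposure_density()] at the i-th
#' covariate row by numeric inversion of the conditional CDF on a
#' 1000-point grid over `[-1, 1]`.
#'
#' @param W Two-column numeric matrix of covariates.
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of exposures in `[-1, 1]`, one per row of `W`.
#' @export
sample_exposures <- function(W, seed = NULL) {
  W <- as.matrix(W)
  stopifnot(ncol(W) == 2)
  n <- nrow(W)
  G <- .icdf_grid
  grid <- seq(-1, 1, length.out = G)
  dg <- grid[2] - grid[1]
  draw <- function() {
    u <- runif(n)
    z <- zeta(W[, 1], W[, 2])
    out <- numeric(n)
    # chunked, fully vectorized inverse-CDF on the grid (trapezoid CDF,
    # linear interpolation between bracketing grid points)
    for (start in seq(1, n, by = 4000L)) {
      ii <- start:min(start + 3999L, n)
      dens <- plogis(outer(z[ii], grid))           # m x G
      mids <- (dens[, -1, drop = FALSE] +
                 dens[, -G, drop = FALSE]) / 2 * dg
      cdf <- cbind(0, t(apply(mids, 1, cumsum)))
      cdf <- cdf / cdf[, G]
      j <- pmin(pmax(rowSums(cdf < u[ii]), 1L), G - 1L)
      m <- length(ii)
      c0 <- cdf[cbind(seq_len(m), j)]
      c1 <- cdf[cbind(seq_len(m), j + 1L)]
      out[ii] <- grid[j] + (u[ii] - c0) / pmax(c1 - c0, 1e-300) * dg
    }
    pmin(pmax(out, -1), 1)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic dose-response dataset
#'
#' Generates an i.i.d. sample from one of two confounded
#' continuous-exposure designs. Covariates `W = (W1, W2)` are bivariate
#' normal with mean zero, unit variances and correlation `correlation`;
#' the exposure `A` is drawn from the tilted density
#' [conditional_exposure_density()] on `[-1, 1]`; the outcome is
#' `Y = theta0(A) - zeta(W) (1 - A^2) + e` with `e ~ Uniform(-h, h)`
#' (noise half-width `h = 2` by default) and `theta0` given by
#' [true_theta()]. Under `"flat_null"` the centered dose-response curve is
#' exactly zero because `zeta(W)` has mean zero.
#'
#' @param setting `"flat_null"` or `"cubic_alt"`.
#' @param n Sample size.
#' @param seed Optional integer seed (applied locally).
#' @param correlation Correlation of the two covariates, in (-1, 1).
#' @param noise_halfwidth Half-width of the uniform outcome noise.
#' @return A `dr_sample`: a data frame with columns `w1, w2, a, y` and an
#'   `exposure_bounds` attribute `c(-1, 1)`.
#' @export
#' @examples
#' d <- generate_dataset("cubic_alt", n = 100, seed = 1)
#' head(d)
generate_dataset <- function(setting = c("flat_null", "cubic_alt"), n,
                             seed = NULL, correlation = 0.5,
                             noise_halfwidth = 2) {
  setting <- match.arg(setting)
  stopifnot(n >= 1, abs(correlation) < 1, noise_halfwidth > 0)
  gen <- function() {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    w1 <- z1
    w2 <- correlation * z1 + sqrt(1 - correlation^2) * z2
    a <- sample_exposures(cbind(w1, w2))
    eps <- runif(n, -noise_halfwidth, noise_halfwidth)
    y <- true_theta(a, setting) - zeta(w1, w2) * (1 - a^2) + eps
    dr_sample(data.frame(w1 = w1, w2 = w2, a = a, y = y),
              exposure_bounds = c(-1, 1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Construct an observed-sample object
#'
#' Tags a data frame of observations with the exposure support. Columns:
#' covariates (every column except `a` and `y`), exposure `a`, outcome
#' `y`. The exposure bounds are carried on the object and used to rescale
#' the exposure onto `[0, 1]` for the Sobolev basis.
#'
#' @param data Data frame with columns `a`, `y`, and covariate columns.
#' @param exposure_bounds Length-2 numeric `c(a_min, a_max)`; defaults to
#'   the observed exposure range.
#' @return The data frame with class `dr_sample`.
#' @export
dr_sample <- function(data, exposure_bounds = NULL) {
  stopifnot(is.data.frame(data), all(c("a", "y") %in% names(data)))
  if (!all(vapply(data, function(x) all(is.finite(x)), logical(1)))) {
    stop("all observations must be finite")
  }
  if (is.null(exposure_bounds)) exposure_bounds <- range(data$a)
  stopifnot(length(exposure_bounds) == 2,
            exposure_bounds[1] < exposure_bounds[2],
            all(data$a >= exposure_bounds[1] - 1e-9),
            all(data$a <= exposure_bounds[2] + 1e-9))
  attr(data, "exposure_bounds") <- as.numeric(exposure_bounds)
  class(data) <- unique(c("dr_sample", class(data)))
  data
}

#' Accessors for observed-sample objects
#'
#' @param s A [dr_sample()].
#' @return `sample_W()` the covariate matrix, `sample_A()` / `sample_Y()`
#'   the exposure and outcome vectors, `exposure_bounds()` the exposure
#'   support carried on the object.
#' @export
sample_W <- function(s) {
  as.matrix(s[, setdiff(names(s), c("a", "y")), drop = FALSE])
}

#' @rdname sample_W
#' @export
sample_A <- function(s) s$a

#' @rdname sample_W
#' @export
sample_Y <- function(s) s$y

#' @rdname sample_W
#' @export
exposure_bounds <- function(s) attr(s, "exposure_bounds")
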