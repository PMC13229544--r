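# Quadrature oracles for the synthetic designs: the true nuisance
# functions, the marginal exposure density, moments of the true curve, and
# the population roughness constants used as "oracle" tuning values in the
# simulation experiments. These provide the testing seam for injecting
# exact nuisances into the estimators.

#' Gauss-Hermite nodes and weights for a standard normal expectation
#'
#' Computed by the Golub-Welsch eigenvalue method for the probabilists'
#' Hermite polynomials, with weights normalized to sum to one, so that
#' `sum(w * f(x))` approximates `E[f(Z)]`, `Z ~ N(0,1)`.
#'
#' @param n Number of nodes.
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n = 40) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

#' True dose-response integrand of the null design, by 2-D quadrature
#'
#' Computes `E_W[Q0(W, a)]` for the flat-null design, where
#' `Q0(w, a) = -zeta(w) (1 - a^2)`, by two-dimensional Gauss-Hermite
#' quadrature over the bivariate normal covariate law. The mean-zero
#' symmetry of `zeta(W)` makes this identically zero, hence every inner
#' product with a bounded test function is zero under the null design.
#'
#' @param a Exposure values in `[-1, 1]`.
#' @param correlation Covariate correlation.
#' @param gh_n Quadrature nodes per dimension.
#' @return `E_W[Q0(W, a)]` at each `a` (numerically ~ 1e-16).
#' @export
theta_null_quadrature <- function(a, correlation = 0.5, gh_n = 40) {
  gh <- gauss_hermite(gh_n)
  L <- chol(matrix(c(1, correlation, correlation, 1), 2))  # upper tri
  z1 <- rep(gh$nodes, times = gh_n)
  z2 <- rep(gh$nodes, each = gh_n)
  wgt <- rep(gh$weights, times = gh_n) * rep(gh$weights, each = gh_n)
  W <- cbind(z1, z2) %*% L
  ez <- sum(wgt * zeta(W[, 1], W[, 2]))
  -ez * (1 - a^2)
}

#' Marginal exposure density of the synthetic designs
#'
#' `f_A(a) = E_W[g0(a | W)]` by Gauss-Hermite quadrature. Since
#' `zeta(w)` depends on `w` only through `s = w1 + w2 ~ N(0, 2 + 2 rho)`,
#' a one-dimensional quadrature over `s` is exact up to node error.
#'
#' @param a Exposure values in `[-1, 1]`.
#' @param correlation Covariate correlation.
#' @param gh_n Number of quadrature nodes.
#' @return Density values `f_A(a)`.
#' @export
marginal_exposure_density <- function(a, correlation = 0.5, gh_n = 60) {
  gh <- gauss_hermite(gh_n)
  s <- gh$nodes * sqrt(2 + 2 * correlation)
  z <- 3 * (plogis(s) - 0.5)
  dens <- plogis(outer(z, a)) / .expit_norm_const(z)   # nodes x length(a)
  drop(crossprod(gh$weights, dens))
}

#' Population moments of the true dose-response curve
#'
#' Mean and variance of `theta0(A)` under the marginal exposure law of the
#' synthetic designs, by Simpson quadrature of [true_theta()] against
#' [marginal_exposure_density()].
#'
#' @param setting Design name.
#' @param correlation Covariate correlation.
#' @param n_grid Simpson grid size (odd).
#' @return List with `mean` and `var`.
#' @export
oracle_theta_moments <- function(setting = "cubic_alt", correlation = 0.5,
                                 n_grid = 601) {
  a <- seq(-1, 1, length.out = n_grid)
  fa <- marginal_exposure_density(a, correlation)
  th <- true_theta(a, setting)
  simp <- .simpson_weights(n_grid, a[2] - a[1])
  m <- sum(simp * fa * th)
  v <- sum(simp * fa * (th - m)^2)
  list(mean = m, var = v)
}

.simpson_weights <- function(n, h) {
  stopifnot(n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

#' Oracle roughness constants for the cubic design
#'
#' The population tuning values used by the "oracle" variants of the test
#' and the bands, computed by quadrature from the known curve.
#'
#' `kappa0 = J(theta0) / Var(theta0(A))` is the roughness of the
#' least-orthogonal direction `h0 = (theta0 - E theta0) / SD(theta0(A))`,
#' with `J(theta0)` the integrated squared second derivative of the true
#' curve on the embedded basis axis (`J = (da/du)^3 int theta0''(a)^2 da`)
#' and the variance obtained by quadrature against the marginal exposure
#' law.
#'
#' `nu0`, the candidate-class bound for band inversion, accounts for basis
#' truncation: the true cubic is not in the span of the D = 20 truncated
#' (periodic) eigenbasis, so the differential norm understates the
#' roughness its class representative needs. `nu0` is defined as the
#' smallest roughness bound whose J-constrained weighted-L2 projection of
#' the true centered curve achieves accuracy of 1 percent of the curve's
#' standard deviation -- the operative meaning of "the candidate class
#' contains the truth" in a truncated basis.
#'
#' @param setting Design name (the flat-null design has no nonzero curve;
#'   requesting its oracle constants is an error).
#' @param correlation Covariate correlation.
#' @param D Basis size used for the `nu0` truncation correction.
#' @return List with `nu`, `kappa`, `J` (differential roughness), and the
#'   curve moments.
#' @export
oracle_class_bounds <- function(setting = "cubic_alt", correlation = 0.5,
                                D = 20) {
  if (setting != "cubic_alt") {
    stop("oracle roughness constants are defined for the cubic design only")
  }
  # theta0''(a) = 1 - 9 a; da/du follows from the embedding of [-1, 1]
  # into the basis period
  dadu <- 2 / (.embed_hi - .embed_lo)
  J <- dadu^3 * integrate(function(a) (1 - 9 * a)^2, -1, 1,
                          rel.tol = 1e-10)$value
  mom <- oracle_theta_moments(setting, correlation)
  # truncation-corrected nu0 by quadrature
  basis <- sobolev_basis(D)
  aq <- seq(-1, 1, length.out = 801)
  fa <- marginal_exposure_density(aq, correlation)
  wq <- fa / sum(fa)
  truth <- true_theta(aq, setting) - mom$mean
  E <- evaluate_basis(basis, scale_exposure(aq, c(-1, 1)))
  Ec <- sweep(E, 2, colSums(E * wq))
  WV <- crossprod(Ec * wq, Ec)
  bv <- drop(crossprod(Ec * wq, truth))
  Pen <- diag(1 / basis$gamma)
  err_at <- function(loglam) {
    cc <- solve(WV + 10^loglam * Pen, bv)
    sqrt(sum(wq * (truth - drop(Ec %*% cc))^2))
  }
  target <- 0.01 * sqrt(mom$var)
  ll <- uniroot(function(l) err_at(l) - target, c(-16, 0), tol = 1e-10)$root
  cc <- solve(WV + 10^ll * Pen, bv)
  nu <- sum(cc^2 / basis$gamma)
  list(nu = nu, kappa = J / mom$var, J = J, mean = mom$mean,
       var = mom$var)
}

#' Oracle nuisance fits for the synthetic designs
#'
#' Returns exact `Q0` and `g0` wrapped in the same predict interface as
#' the fitted nuisances, for injecting true nuisance values into the
#' estimators (the dependency-inversion seam used throughout the tests).
#'
#' @param setting Design name.
#' @return List with elements `qfit` (class `dr_oracle_qfit`) and `gfit`
#'   (class `dr_oracle_gfit`).
#' @export
oracle_nuisances <- function(setting = c("flat_null", "cubic_alt")) {
  setting <- match.arg(setting)
  list(qfit = structure(list(setting = setting), class = "dr_oracle_qfit"),
       gfit = structure(list(floor = 0), class = "dr_oracle_gfit"))
}

#' @export
predict_q.dr_oracle_qfit <- function(qfit, W, a) {
  W <- as.matrix(W)
  true_theta(a, qfit$setting) - zeta(W[, 1], W[, 2]) * (1 - a^2)
}

#' @export
predict_q_grid.dr_oracle_qfit <- function(qfit, W, avec) {
  W <- as.matrix(W)
  th <- true_theta(avec, qfit$setting)
  outer(-zeta(W[, 1], W[, 2]), 1 - avec^2) +
    matrix(th, nrow(W), length(avec), byrow = TRUE)
}

#' @export
predict_g_grid.dr_oracle_gfit <- function(gfit, avec, W) {
  W <- as.matrix(W)
  z <- zeta(W[, 1], W[, 2])
  t(plogis(outer(z, avec)) / .expit_norm_const(z))
}

#' Wrap arbitrary functions as nuisance fits
#'
#' Adapts user-supplied functions to the prediction interface of the
#' fitted nuisances, for injecting known conditional means and densities
#' (e.g. exact components of a discrete toy distribution) into the
#' estimators.
#'
#' @param q Function `(W, a) -> numeric` giving the conditional outcome
#'   mean for paired rows of `W` and elements of `a`.
#' @param g Function `(a, W) -> numeric` giving the conditional exposure
#'   density (or mass) for one exposure value against rows of `W`.
#' @return List with `qfit` and `gfit` in the standard interface.
#' @export
function_nuisances <- function(q, g) {
  list(qfit = structure(list(fun = q), class = "dr_fun_qfit"),
       gfit = structure(list(fun = g, floor = 0), class = "dr_fun_gfit"))
}

#' @export
predict_q.dr_fun_qfit <- function(qfit, W, a) {
  qfit$fun(as.matrix(W), a)
}

#' @export
predict_q_grid.dr_fun_qfit <- function(qfit, W, avec) {
  W <- as.matrix(W)
  vapply(avec, function(a) qfit$fun(W, rep(a, nrow(W))), numeric(nrow(W)))
}

#' @export
predict_g_grid.dr_fun_gfit <- function(gfit, avec, W) {
  W <- as.matrix(W)
  t(vapply(avec, function(a) gfit$fun(a, W), numeric(nrow(W))))
}
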