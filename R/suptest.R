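# The supremum statistic over the roughness-bounded unit-variance class,
# solved through the KKT closed form; a dual-bound brute-force oracle; the
# multiplier bootstrap; and the end-to-end flat-null test.

#' Precompute the eigenstructure for repeated supremum solves
#'
#' Whitens by the diagonal penalty `Gamma` and eigendecomposes the
#' whitened variance matrix once, so that each subsequent supremum solve
#' (for the observed statistic, every bootstrap draw, and every TML step)
#' costs only a one-dimensional root-find over scalar sums.
#'
#' @param V Empirical basis covariance (D x D, PSD).
#' @param Gamma Diagonal roughness penalty matrix (D x D, positive).
#' @return A context list for [solve_sup_ctx()].
#' @export
sup_context <- function(V, Gamma) {
  g <- diag(Gamma)
  stopifnot(all(g > 0))
  s <- 1 / sqrt(g)                       # Gamma^{-1/2}
  Vt <- t(V * s) * s                     # Gamma^{-1/2} V Gamma^{-1/2}
  e <- eigen((Vt + t(Vt)) / 2, symmetric = TRUE)
  list(s = s, P = e$vectors, lam = pmax(e$values, 0), D = length(g))
}

#' Supremum of the estimated inner product over the function class
#'
#' Computes `max U'c` subject to `c'Vc = 1` (unit empirical variance) and
#' `c'Gamma c <= kappa` (bounded roughness) via the KKT conditions: the
#' maximizer is `c = (V + lambda2 Gamma)^{-1} U / lambda1` where `lambda2`
#' solves the roughness-ratio equation by monotone root-finding on
#' `log(lambda2)` and `lambda1` normalizes the empirical variance. When
#' the unconstrained-roughness solution already satisfies the bound, the
#' boundary-inactive solution (`lambda2 = 0`) is returned.
#'
#' @param U Length-D vector of estimated inner products.
#' @param V,Gamma As in [sup_context()].
#' @param kappa Positive roughness bound.
#' @return A list: `statistic` (nonnegative), coefficient vector `c`,
#'   multipliers `lambda1`, `lambda2`.
#' @export
solve_sup <- function(U, V, Gamma, kappa) {
  solve_sup_ctx(sup_context(V, Gamma), U, kappa)
}

#' @rdname solve_sup
#' @param ctx A [sup_context()].
#' @param hard_case What to do when the positive-multiplier KKT system
#'   has no root because `U` points into directions rougher than `kappa`
#'   allows at unit variance: `"error"` (default) stops with diagnostics;
#'   `"relax"` returns the closed-form maximum over the convex hull
#'   (variance at most one) used as a conservative bootstrap fallback;
#'   `"member"` returns the smoothest unit-variance class member aligned
#'   with `U` (a valid, if suboptimal, fluctuation direction for TML).
#' @export
solve_sup_ctx <- function(ctx, U, kappa,
                          hard_case = c("error", "relax", "member")) {
  stopifnot(kappa > 0)
  hard_case <- match.arg(hard_case)
  D <- ctx$D
  if (sqrt(sum(U^2)) < 1e-14) {
    return(list(statistic = 0, c = numeric(D), lambda1 = NA_real_,
                lambda2 = NA_real_))
  }
  u <- drop(crossprod(ctx$P, ctx$s * U))   # U in the whitened eigenbasis
  lam <- ctx$lam
  ratio <- function(l2) {
    d <- (lam + l2)^2
    sum(u^2 / d) / sum(lam * u^2 / d)
  }
  lo <- 1e-12; hi <- 1e12
  l2 <- if (lam[D] > 1e-10 && ratio(lo) <= kappa) {
    0                                  # roughness bound inactive
  } else if (ratio(hi) > kappa) {
    if (hard_case == "relax") {
      # variance constraint slack: maximize over the J-ball alone
      y <- sqrt(kappa) * u / sqrt(sum(u^2))
      return(list(statistic = sqrt(kappa * sum(u^2)),
                  c = ctx$s * drop(ctx$P %*% y),
                  lambda1 = NA_real_, lambda2 = Inf))
    }
    if (hard_case == "member") {
      # smoothest unit-variance member, signed along U
      if (1 / lam[1] > kappa) {
        stop("function class {Var_n = 1, J <= kappa} is empty: kappa = ",
             signif(kappa, 4), " < ", signif(1 / lam[1], 4))
      }
      y <- numeric(D); y[1] <- sign(u[1] + (u[1] == 0)) / sqrt(lam[1])
      return(list(statistic = abs(u[1]) / sqrt(lam[1]),
                  c = ctx$s * drop(ctx$P %*% y),
                  lambda1 = NA_real_, lambda2 = Inf))
    }
    stop("supremum KKT root not bracketed: roughness-ratio at ",
         "lambda2 = 1e12 is ", signif(ratio(hi), 4), " > kappa = ",
         signif(kappa, 4),
         "; kappa is too small for the direction of U at unit variance")
  } else {
    10^uniroot(function(t) log(ratio(10^t)) - log(kappa),
               c(log10(lo), log10(hi)), tol = 1e-12)$root
  }
  d <- lam + l2
  lambda1 <- sqrt(sum(lam * u^2 / d^2))
  y <- u / d / lambda1
  c_vec <- ctx$s * drop(ctx$P %*% y)
  list(statistic = sum(u^2 / d) / lambda1, c = c_vec,
       lambda1 = lambda1, lambda2 = l2)
}

#' Brute-force oracle for the supremum statistic
#'
#' Independent verification route for [solve_sup()]: by Lagrangian duality
#' the constrained maximum equals `min_t sqrt(U' Q(t)^{-1} U)` over the
#' active-constraint mixtures `Q(t) = (1 - t) V + t Gamma / kappa`,
#' `t` in `[0, 1]`. The dual curve is evaluated on a fine deterministic
#' sweep and the minimum refined by golden-section search.
#'
#' @inheritParams solve_sup
#' @param budget Number of sweep points.
#' @return The supremum value (nonnegative scalar).
#' @export
sup_bruteforce <- function(U, V, Gamma, kappa, budget = 400) {
  if (sqrt(sum(U^2)) < 1e-14) return(0)
  ub <- function(t) {
    Q <- (1 - t) * V + t * Gamma / kappa
    qr_Q <- tryCatch(chol(Q), error = function(e) NULL)
    if (is.null(qr_Q)) return(Inf)
    z <- backsolve(qr_Q, forwardsolve(t(qr_Q), U))
    sqrt(sum(U * z))
  }
  ts <- seq(1e-9, 1, length.out = budget)
  vals <- vapply(ts, ub, numeric(1))
  i <- which.min(vals)
  lo <- ts[max(1, i - 1)]; hi <- ts[min(budget, i + 1)]
  opt <- optimize(ub, c(lo, hi), tol = 1e-12)
  min(opt$objective, vals[i])
}

#' Multiplier bootstrap of the supremum null distribution
#'
#' For each of `M` replicates, draws i.i.d. standard normal multipliers,
#' perturbs the influence-function contributions,
#' `U_d = n^-1 sum_i (xi_i - mean xi) Phi[i, d]`, and recomputes the
#' supremum statistic, yielding draws from the estimated null limiting
#' distribution of the test statistic.
#'
#' @param Phi n x D influence matrix (from [estimate_eif()] or a
#'   `dr_psi` object).
#' @param V,Gamma,kappa Class matrices and roughness bound.
#' @param M Number of bootstrap replicates (at least 100).
#' @param seed Optional integer seed (local).
#' @return Length-M vector of nonnegative bootstrap statistics, on the
#'   same (unscaled) footing as the observed statistic.
#' @export
multiplier_bootstrap <- function(Phi, V, Gamma, kappa, M = 1000,
                                 seed = NULL) {
  stopifnot(M >= 100)
  ctx <- sup_context(V, Gamma)
  .multiplier_bootstrap_ctx(Phi, ctx, kappa, M, seed)
}

.multiplier_bootstrap_ctx <- function(Phi, ctx, kappa, M, seed = NULL,
                                      indicator = FALSE) {
  n <- nrow(Phi)
  draw <- function() {
    Xi <- matrix(rnorm(n * M), n, M)
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Umat <- crossprod(Phi, Xi) / n       # D x M
    if (indicator) {
      apply(abs(Umat), 2, max)
    } else {
      vapply(seq_len(M), function(m) {
        solve_sup_ctx(ctx, Umat[, m], kappa, hard_case = "relax")$statistic
      }, numeric(1))
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
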