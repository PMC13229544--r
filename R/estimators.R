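# Plug-in, one-step, and TML estimators of the inner products
# psi(eta_d) = E[(theta_bar - theta_bar*)(A) eta_d(A)] for the truncated
# Sobolev basis, together with the estimated efficient influence function.
#
# All three estimators are linear in the basis coefficients, so each is
# summarized by the D-vector U with psi_hat(sum c_d eta_d) = U' c; the
# n x D matrix Phi of per-observation influence values drives both the
# one-step correction and the multiplier bootstrap.

# Shared per-sample quantities. QM[i, j] = Q(W_i, A_j); thetaA is the
# plug-in curve at the observed exposures; wts the density-ratio weights;
# Z the TML fluctuation covariate Z[i, d] = wts_i * eta_c[i, d].
.psi_ingredients <- function(sample, qfit, gfit, basis,
                             theta_star = NULL, gram = NULL) {
  W <- sample_W(sample); A <- sample_A(sample); Y <- sample_Y(sample)
  n <- length(Y)
  bounds <- exposure_bounds(sample)
  a01 <- scale_exposure(A, bounds)
  if (is.null(gram)) gram <- gram_matrices(basis, a01)
  G <- predict_g_grid(gfit, A, W)              # G[j, i] = g(A_j | W_i)
  fbar <- rowMeans(G)
  wts <- fbar / diag(G)
  QM <- predict_q_grid(qfit, W, A)
  thetaA <- colMeans(QM)
  Qdiag <- diag(QM)
  res <- Y - Qdiag
  tstarA <- if (is.null(theta_star)) rep(0, n) else theta_star(A)
  Z <- wts * gram$eta_c
  list(W = W, A = A, Y = Y, n = n, bounds = bounds, a01 = a01,
       gram = gram, G = G, fbar = fbar, wts = wts, QM = QM,
       thetaA = thetaA, res = res, tstarA = tstarA, Z = Z,
       qfit = qfit, gfit = gfit, basis = basis, theta_star = theta_star)
}

# core psi / EIF algebra given (possibly TML-updated) fit values
.psi_core <- function(ing, QM, thetaA, res, use_theta_hat) {
  n <- ing$n
  eta <- ing$gram$eta
  eta_c <- ing$gram$eta_c
  contrast <- thetaA - ing$tstarA
  ctr <- contrast - mean(contrast)
  U_plug <- drop(crossprod(eta, ctr)) / n
  correction <- drop(crossprod(eta_c, ing$wts * res)) / n
  # EIF rows: curve-contrast term, weighted-residual term, the
  # E[Q(w, A) eta_c(A)] term, and the centering constants
  # -E_hat[theta_n(A) eta_c(A)] - psi_plug (derived form of the printed
  # influence function; constants drop out of the bootstrap).
  T3 <- QM %*% eta_c / n
  const <- -drop(crossprod(eta_c, thetaA)) / n
  if (use_theta_hat) {
    Phi <- (ing$wts * res) * eta_c + T3 +
      matrix(const, n, ncol(eta), byrow = TRUE)
  } else {
    Phi <- ctr * eta_c + (ing$wts * res) * eta_c + T3 +
      matrix(const - U_plug, n, ncol(eta), byrow = TRUE)
  }
  list(U_plug = U_plug, correction = correction, Phi = Phi)
}

#' Plug-in estimator of the dose-response curve
#'
#' `theta_n(a) = n^-1 sum_i Q_hat(W_i, a)`.
#'
#' @param qfit Fitted (or oracle) outcome regression.
#' @param sample A [dr_sample()].
#' @return A function mapping an exposure vector to curve values.
#' @export
plugin_theta <- function(qfit, sample) {
  W <- sample_W(sample)
  function(avec) colMeans(predict_q_grid(qfit, W, avec))
}

#' Naive plug-in estimator of the basis inner products
#'
#' `U_d = n^-1 sum_i [contrast(A_i) - mean contrast] eta_d(A_i)` with
#' `contrast = theta_n - theta*`.
#'
#' @param theta_n Curve estimate as a function (e.g. [plugin_theta()]).
#' @param theta_star Candidate null curve function, or `NULL` for zero.
#' @param eta Basis evaluation matrix at the (rescaled) observed exposures.
#' @param A Observed exposures.
#' @return Length-`D` vector of plug-in inner products.
#' @export
plugin_psi <- function(theta_n, theta_star, eta, A) {
  contrast <- theta_n(A) - (if (is.null(theta_star)) 0 else theta_star(A))
  ctr <- contrast - mean(contrast)
  drop(crossprod(eta, ctr)) / length(A)
}

#' TML fluctuation covariate
#'
#' `Z[i, d] = w_i (eta_d(A_i) - mean_j eta_d(A_j))` with `w_i` the
#' density-ratio weights: the direction along which the outcome
#' regression is fluctuated, and the weight pattern of the efficient
#' influence function estimating equations.
#'
#' @param sample A [dr_sample()].
#' @param gfit Fitted (or oracle) conditional density.
#' @param eta Basis evaluation matrix at the rescaled observed exposures.
#' @return An n x D matrix.
#' @export
Zn_weights <- function(sample, gfit, eta) {
  wts <- density_ratio_weights(gfit, sample)
  eta_c <- sweep(eta, 2, colMeans(eta))
  wts * eta_c
}

#' One-step estimator of the basis inner products
#'
#' Adds the empirical mean of the estimated efficient influence function
#' to the naive plug-in:
#' `U_d = U_plug_d + n^-1 sum_i w_i (Y_i - Q_hat_i) eta_c_d(A_i)`.
#'
#' @param sample A [dr_sample()].
#' @param qfit,gfit Fitted (or oracle) nuisances.
#' @param theta_star Candidate null curve function, or `NULL` for zero.
#' @param basis A [sobolev_basis()].
#' @param use_theta_hat_eif If `TRUE` (default), the influence-function
#'   estimate replaces `theta*` with the plug-in curve, so the same
#'   bootstrap serves every candidate null (used by the band inversion).
#' @return A `dr_psi` object: `U`, `Phi` (n x D influence matrix),
#'   `kind = "one_step"`, and the plug-in curve `theta_hat`.
#' @export
one_step_psi <- function(sample, qfit, gfit, theta_star = NULL,
                         basis = sobolev_basis(), use_theta_hat_eif = TRUE) {
  ing <- .psi_ingredients(sample, qfit, gfit, basis, theta_star)
  core <- .psi_core(ing, ing$QM, ing$thetaA, ing$res, use_theta_hat_eif)
  structure(list(U = core$U_plug + core$correction, kind = "one_step",
                 Phi = core$Phi, U_plug = core$U_plug,
                 theta_hat = plugin_theta(qfit, sample),
                 ingredients = ing),
            class = "dr_psi")
}

#' Estimated efficient influence function matrix
#'
#' Evaluates the plug-in estimate of the efficient influence function of
#' `psi(eta_d)` at every observation: the centered curve-contrast term,
#' the density-ratio-weighted residual term, the
#' `E[Q(w, A)(eta_d(A) - mean)]` term, and centering constants. With
#' `use_theta_hat = TRUE` the candidate null is replaced by the plug-in
#' curve and the contrast term vanishes.
#'
#' @inheritParams one_step_psi
#' @param use_theta_hat Replace `theta*` by the plug-in curve.
#' @return An n x D matrix `Phi`.
#' @export
estimate_eif <- function(sample, qfit, gfit, theta_star = NULL,
                         basis = sobolev_basis(), use_theta_hat = TRUE) {
  ing <- .psi_ingredients(sample, qfit, gfit, basis, theta_star)
  .psi_core(ing, ing$QM, ing$thetaA, ing$res, use_theta_hat)$Phi
}

#' Targeted minimum-loss update of the outcome regression
#'
#' Fluctuates the fitted outcome regression along the universal least
#' favorable submodel: at each step the direction `h*` maximizing the
#' empirical influence equation `n^-1 sum_i r_i Z_i(h)` over the
#' roughness-bounded unit-variance class is found by the KKT closed form,
#' and the fit moves a small step `eps` along `Z(., .; h*)`. Iteration
#' stops once the loss derivative `|D_n|` falls below the threshold
#' `(n log n)^{-1/2} sd_n((Y - Q_hat) Z(h_n))`. The squared-error loss is
#' non-increasing by construction; if a step increases it, the step size
#' is divided by 10 and the step retried.
#'
#' @param sample A [dr_sample()].
#' @param qfit,gfit Fitted (or oracle) nuisances.
#' @param basis A [sobolev_basis()].
#' @param kappa Roughness bound of the fluctuation class.
#' @param h_n Standardized coefficient vector of the estimated
#'   least-orthogonal direction, used in the stopping threshold; defaults
#'   to the first-step maximizer.
#' @param eps_frac Step size as a fraction of `sd(Y)`.
#' @param max_steps Step budget.
#' @return A `dr_tmle` state: cumulative fluctuation coefficients `cumC`,
#'   steps taken `B`, `final_derivative`, `threshold`, `loss` trace, and
#'   the ingredients needed to evaluate the updated fit.
#' @export
tmle_update <- function(sample, qfit, gfit, basis = sobolev_basis(),
                        kappa, h_n = NULL, eps_frac = 1e-3,
                        max_steps = 5000) {
  ing <- .psi_ingredients(sample, qfit, gfit, basis)
  .tmle_update_core(ing, kappa, h_n, eps_frac, max_steps)
}

.tmle_update_core <- function(ing, kappa, h_n = NULL, eps_frac = 1e-3,
                              max_steps = 5000) {
  n <- ing$n
  Z <- ing$Z
  ctx <- sup_context(ing$gram$V, ing$gram$Gamma)
  r <- ing$res
  eps <- eps_frac * sd(ing$Y)
  cumC <- numeric(ncol(Z))
  loss <- mean(r^2)
  loss_trace <- loss
  # stopping threshold: (n log n)^{-1/2} * sd_n of (initial residual) x
  # Z(h_n), with h_n the adaptive least-orthogonal direction when
  # available, else the first-step maximizer
  first <- solve_sup_ctx(ctx, drop(crossprod(Z, r)) / n, kappa,
                         hard_case = "member")
  if (is.null(h_n)) h_n <- first$c
  Zh <- drop(Z %*% h_n)
  threshold <- sd(ing$res * Zh) / sqrt(n * log(n))
  B <- 0L
  Dmag <- first$statistic
  while (Dmag > threshold && B < max_steps) {
    sol <- if (B == 0L) first else {
      solve_sup_ctx(ctx, drop(crossprod(Z, r)) / n, kappa,
                    hard_case = "member")
    }
    Dmag <- sol$statistic
    if (Dmag <= threshold) break
    step_ok <- FALSE
    while (!step_ok) {
      r_new <- r - eps * drop(Z %*% sol$c)
      if (mean(r_new^2) <= loss + 1e-12) {
        step_ok <- TRUE
      } else {
        eps <- eps / 10
        if (eps < 1e-12 * sd(ing$Y)) break
      }
    }
    if (!step_ok) {
      warning("TML step size underflow; stopping before threshold")
      break
    }
    r <- r_new
    cumC <- cumC + eps * sol$c
    loss <- mean(r^2)
    loss_trace <- c(loss_trace, loss)
    B <- B + 1L
  }
  if (B >= max_steps && Dmag > threshold) {
    warning("TML update did not reach the stopping threshold within ",
            max_steps, " steps")
  }
  structure(list(cumC = cumC, B = B, eps = eps, final_derivative = Dmag,
                 threshold = threshold, loss = loss_trace, kappa = kappa,
                 residual = r, ingredients = ing),
            class = "dr_tmle")
}

# updated fit values on the sample implied by a TML state
.tmle_updated_values <- function(state) {
  ing <- state$ingredients
  etaC <- drop(ing$gram$eta_c %*% state$cumC)   # fluctuation at each A_j
  # Q_tilde(W_i, A_j) = QM[i,j] + (fbar_j / G[j,i]) * etaC_j
  QM_t <- ing$QM + t(ing$fbar * etaC / ing$G)
  thetaA_t <- ing$thetaA + etaC * ing$fbar * rowMeans(1 / ing$G)
  res_t <- ing$res - drop(ing$Z %*% state$cumC)
  list(QM = QM_t, thetaA = thetaA_t, res = res_t)
}

#' Curve estimate implied by a TML update
#'
#' @param state A `dr_tmle` from [tmle_update()].
#' @return A function evaluating the TML-updated plug-in curve
#'   `a -> n^-1 sum_i Q_tilde(W_i, a)`.
#' @export
tmle_theta <- function(state) {
  ing <- state$ingredients
  eta_means <- colMeans(ing$gram$eta)
  function(avec) {
    base <- colMeans(predict_q_grid(ing$qfit, ing$W, avec))
    Gg <- predict_g_grid(ing$gfit, avec, ing$W)   # m x n
    mult <- rowMeans(Gg) * rowMeans(1 / Gg)
    eta_a <- evaluate_basis(ing$basis, scale_exposure(avec, ing$bounds))
    etaC <- drop(sweep(eta_a, 2, eta_means) %*% state$cumC)
    base + etaC * mult
  }
}

#' TML estimator of the basis inner products
#'
#' Applies the plug-in inner-product formula at the TML-updated outcome
#' regression and evaluates the influence matrix at the updated fit.
#'
#' @param state A `dr_tmle` from [tmle_update()].
#' @param theta_star Candidate null curve function, or `NULL` for zero.
#' @param use_theta_hat_eif As in [one_step_psi()].
#' @return A `dr_psi` object with `kind = "tmle"`.
#' @export
tmle_psi <- function(state, theta_star = NULL, use_theta_hat_eif = TRUE) {
  ing <- state$ingredients
  if (!is.null(theta_star)) ing$tstarA <- theta_star(ing$A)
  upd <- .tmle_updated_values(state)
  core <- .psi_core(ing, upd$QM, upd$thetaA, upd$res, use_theta_hat_eif)
  structure(list(U = core$U_plug, kind = "tmle", Phi = core$Phi,
                 U_plug = core$U_plug, theta_hat = tmle_theta(state),
                 tmle_state = state, ingredients = ing),
            class = "dr_psi")
}
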