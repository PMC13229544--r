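# End-to-end hypothesis test that the mean-centered dose-response curve
# equals a candidate null curve (by default the zero function: the flat
# null). Pipeline: rescale the exposure, fit nuisances, build the Sobolev
# class and its roughness bound, estimate the basis inner products by
# one-step or TML estimation, and calibrate the supremum statistic by
# multiplier bootstrap.

#' Control parameters for the dose-response pipeline
#'
#' @param knots Quantile knots per variable in the outcome-regression
#'   basis.
#' @param lambda_rule Penalty rule for the outcome regression (`"min"` or
#'   `"1se"`).
#' @param density_knots Quantile knots per covariate in the
#'   conditional-density basis.
#' @param cv_folds Cross-validation folds for the learners.
#' @param density_grid Exposure grid size for the conditional density.
#' @param bandwidth Kernel bandwidth for the conditional density; `NULL`
#'   selects it by marginal cross-validation.
#' @param floor_frac Conditional-density floor fraction.
#' @param eps_frac TML step size as a fraction of `sd(Y)`.
#' @param max_steps TML step budget.
#' @param proj_folds Folds for the penalized-projection cross-validation.
#' @return A named list of control values.
#' @export
dr_control <- function(knots = 8, lambda_rule = "min",
                       density_knots = 5, cv_folds = 5,
                       density_grid = 50, bandwidth = NULL,
                       floor_frac = 1e-3, eps_frac = 1e-3,
                       max_steps = 5000, proj_folds = 10) {
  list(knots = knots, lambda_rule = lambda_rule,
       density_knots = density_knots, cv_folds = cv_folds,
       density_grid = density_grid, bandwidth = bandwidth,
       floor_frac = floor_frac, eps_frac = eps_frac,
       max_steps = max_steps, proj_folds = proj_folds)
}

# Fit nuisances (unless injected) and assemble shared pipeline state.
.dr_prepare <- function(sample, theta_star, D, control, nuisances) {
  if (is.null(nuisances$qfit)) {
    qfit <- fit_outcome_regression(sample, knots = control$knots,
                                   cv_folds = control$cv_folds,
                                   lambda_rule = control$lambda_rule)
  } else qfit <- nuisances$qfit
  if (is.null(nuisances$gfit)) {
    gfit <- fit_conditional_density(sample, r = control$bandwidth,
                                    grid_size = control$density_grid,
                                    floor_frac = control$floor_frac,
                                    knots = control$density_knots,
                                    cv_folds = control$cv_folds)
  } else gfit <- nuisances$gfit
  basis <- sobolev_basis(D)
  ing <- .psi_ingredients(sample, qfit, gfit, basis, theta_star)
  list(sample = sample, qfit = qfit, gfit = gfit, basis = basis,
       ing = ing)
}

# Adaptive roughness bound from the penalized projection of the
# pseudo-outcome; falls back to (2 pi)^4 on a flat projection.
.dr_kappa <- function(prep, control) {
  ing <- prep$ing
  f <- ing$thetaA + ing$wts * ing$res - ing$tstarA
  proj <- fit_penalized_projection(f, prep$basis, ing$a01,
                                   folds = control$proj_folds)
  out <- tryCatch(estimate_kappa(proj$c, prep$basis, ing$gram$V),
                  error = function(e) NULL)
  if (is.null(out)) {
    list(kappa = .default_kappa(ing$gram$V, ing$gram$Gamma), h = NULL,
         proj = proj, fallback = TRUE)
  } else {
    c(out, list(proj = proj, fallback = FALSE))
  }
}

#' Test that the centered dose-response curve equals a candidate null
#'
#' Runs the full inference pipeline on an observed sample and returns the
#' supremum statistic, bootstrap draws, and p-value for the null
#' hypothesis that the mean-centered dose-response function equals the
#' centered candidate `theta_star` (the flat null when `theta_star` is
#' `NULL`). The p-value is the fraction of multiplier-bootstrap draws
#' exceeding the observed statistic.
#'
#' @param data A [dr_sample()] or a data frame with columns `a`, `y` and
#'   covariate columns.
#' @param theta_star Candidate null curve as a function of the raw
#'   exposure; `NULL` for the flat (zero) null.
#' @param alpha Nominal level (recorded; rejection is `p_value <= alpha`).
#' @param estimator `"one_step"` or `"tmle"`.
#' @param kappa `"adaptive"` for the data-driven roughness bound, or a
#'   positive number (e.g. an oracle value).
#' @param M Number of bootstrap replicates.
#' @param D Number of Sobolev basis functions (even).
#' @param seed Integer seed for the bootstrap multipliers (local).
#' @param exposure_bounds Optional known exposure support.
#' @param nuisances Optional list with `qfit` and/or `gfit` to inject
#'   (e.g. oracle nuisances); missing components are fitted.
#' @param hclass `"sobolev"` for the roughness-bounded unit-variance
#'   class (default), or `"indicator"` for the comparator class of
#'   threshold indicators `1(a <= a0)` with the supremum over a cutoff
#'   grid (one-step estimation only).
#' @param control A [dr_control()] list.
#' @return A `dr_test` object: `statistic` (unscaled), `sqrt_n_statistic`,
#'   `p_value`, `draws`, `M`, `seed`, `kappa_used`, `estimator_kind`,
#'   `reject`, plus internal state reused by [confidence_band()].
#' @export
flat_null_test <- function(data, theta_star = NULL, alpha = 0.05,
                           estimator = c("one_step", "tmle"),
                           kappa = "adaptive", M = 1000, D = 20,
                           seed = 1, exposure_bounds = NULL,
                           nuisances = list(),
                           hclass = c("sobolev", "indicator"),
                           control = dr_control()) {
  estimator <- match.arg(estimator)
  hclass <- match.arg(hclass)
  sample <- if (inherits(data, "dr_sample")) data else {
    dr_sample(data, exposure_bounds)
  }
  if (hclass == "indicator") {
    return(.flat_null_test_indicator(sample, theta_star, alpha, M, seed,
                                     nuisances, control))
  }
  prep <- .dr_prepare(sample, theta_star, D, control, nuisances)
  ing <- prep$ing
  h_n <- NULL
  if (identical(kappa, "adaptive")) {
    ka <- .dr_kappa(prep, control)
    kappa_used <- ka$kappa
    h_n <- ka$h
  } else {
    stopifnot(is.numeric(kappa), kappa > 0)
    kappa_used <- kappa
  }
  if (estimator == "one_step") {
    core <- .psi_core(ing, ing$QM, ing$thetaA, ing$res, TRUE)
    U <- core$U_plug + core$correction
    Phi <- core$Phi
    theta_hat <- plugin_theta(prep$qfit, sample)
    tmle_state <- NULL
  } else {
    tmle_state <- .tmle_update_core(ing, kappa_used, h_n,
                                    control$eps_frac, control$max_steps)
    psi <- tmle_psi(tmle_state, theta_star, use_theta_hat_eif = TRUE)
    U <- psi$U
    Phi <- psi$Phi
    theta_hat <- psi$theta_hat
  }
  ctx <- sup_context(ing$gram$V, ing$gram$Gamma)
  sol <- solve_sup_ctx(ctx, U, kappa_used, hard_case = "relax")
  draws <- .multiplier_bootstrap_ctx(Phi, ctx, kappa_used, M, seed)
  p <- mean(draws > sol$statistic)
  structure(list(statistic = sol$statistic,
                 sqrt_n_statistic = sqrt(ing$n) * sol$statistic,
                 p_value = p, reject = (p <= alpha), alpha = alpha,
                 M = M, draws = draws, seed = seed,
                 kappa_used = kappa_used, estimator_kind = estimator,
                 hclass = hclass, U = U, Phi = Phi, solution = sol,
                 theta_hat = theta_hat, n = ing$n,
                 tmle_state = tmle_state,
                 prep = prep),
            class = "dr_test")
}

# Comparator test over the indicator class {1(a <= a0)}: the supremum is
# the maximum absolute estimated inner product over a cutoff grid, with
# the same one-step estimator and multiplier bootstrap.
.flat_null_test_indicator <- function(sample, theta_star, alpha, M, seed,
                                      nuisances, control,
                                      n_cutoffs = 50) {
  A <- sample_A(sample)
  cuts <- unique(quantile(A, probs = seq(0.02, 0.98,
                                         length.out = n_cutoffs),
                          names = FALSE))
  H <- outer(A, cuts, "<=") + 0
  prep <- .dr_prepare(sample, theta_star, 2, control, nuisances)
  ing <- prep$ing
  ing$gram$eta <- H
  ing$gram$eta_c <- sweep(H, 2, colMeans(H))
  core <- .psi_core(ing, ing$QM, ing$thetaA, ing$res, TRUE)
  U <- core$U_plug + core$correction
  stat <- max(abs(U))
  draws <- .multiplier_bootstrap_ctx(core$Phi, NULL, NULL, M, seed,
                                     indicator = TRUE)
  p <- mean(draws > stat)
  structure(list(statistic = stat, sqrt_n_statistic = sqrt(ing$n) * stat,
                 p_value = p, reject = (p <= alpha), alpha = alpha,
                 M = M, draws = draws, seed = seed, kappa_used = NA_real_,
                 estimator_kind = "one_step", hclass = "indicator",
                 U = U, Phi = core$Phi, solution = NULL,
                 theta_hat = plugin_theta(prep$qfit, sample),
                 n = ing$n, tmle_state = NULL, prep = prep),
            class = "dr_test")
}

#' @exportS3Method base::print
print.dr_test <- function(x, ...) {
  cat("Nonparametric dose-response curve test\n")
  cat(sprintf("  class: %s   estimator: %s\n", x$hclass, x$estimator_kind))
  if (is.finite(x$kappa_used)) {
    cat(sprintf("  roughness bound kappa: %.4g\n", x$kappa_used))
  }
  cat(sprintf("  sqrt(n) x statistic: %.4f   bootstrap M: %d\n",
              x$sqrt_n_statistic, x$M))
  cat(sprintf("  p-value: %.4g  (%s at level %.3g)\n", x$p_value,
              if (x$reject) "reject" else "fail to reject", x$alpha))
  invisible(x)
}
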