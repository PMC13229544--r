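# Plug-in, one-step, and TML estimators of the basis inner products, the
# estimated efficient influence function (including the finite-difference
# pathwise-derivative oracle), and the targeted update contract.

test_that("plug-in curve and inner products: constants, centering,
          determinism", {
  d <- fixture_data("flat_null", 100, 41)
  const_q <- function_nuisances(q = function(W, a) rep(2.5, length(a)),
                                g = function(a, W) rep(0.5, nrow(W)))
  th <- plugin_theta(const_q$qfit, d)
  expect_equal(th(c(-0.5, 0, 0.5)), rep(2.5, 3))
  b <- sobolev_basis(6)
  eta <- evaluate_basis(b, scale_exposure(d$a, exposure_bounds(d)))
  # theta_n = theta*  =>  all inner products vanish
  expect_equal(plugin_psi(th, function(a) rep(2.5, length(a)), eta, d$a),
               rep(0, 6))
  # a constant test-function column gets exactly zero by centering
  expect_equal(plugin_psi(th, NULL, matrix(1, 100, 1), d$a), 0)
  expect_identical(plugin_psi(th, NULL, eta, d$a),
                   plugin_psi(th, NULL, eta, d$a))
})

test_that("Zn weights: unity for covariate-free densities, hand
          computation on a 5-row sample", {
  df <- dr_sample(data.frame(w1 = c(-1, 0, 1, 2, -2), a = seq(0.1, 0.9, 0.2),
                             y = rnorm(5)), exposure_bounds = c(0, 1))
  flatg <- function_nuisances(q = function(W, a) rep(0, length(a)),
                              g = function(a, W) rep(1, nrow(W)))$gfit
  expect_equal(density_ratio_weights(flatg, df), rep(1, 5))
  b <- sobolev_basis(4)
  eta <- evaluate_basis(b, scale_exposure(df$a, c(0, 1)))
  Z <- Zn_weights(df, flatg, eta)
  expect_equal(Z, sweep(eta, 2, colMeans(eta)))
  expect_equal(colMeans(sweep(eta, 2, colMeans(eta))), rep(0, 4))
  # hand computation with a w-dependent density g(a | w) = exp(w a)-tilted
  gman <- function_nuisances(q = function(W, a) rep(0, length(a)),
                             g = function(a, W) {
                               exp(W[, 1] * a) / (exp(W[, 1]) - 1) * W[, 1]
                             })
  # guard the degenerate w = 0 rows out of this toy
  df2 <- dr_sample(data.frame(w1 = c(1, 2, 0.5), a = c(0.2, 0.5, 0.8),
                              y = c(0, 0, 0)), exposure_bounds = c(0, 1))
  G <- predict_g_grid(gman$gfit, df2$a, as.matrix(df2$w1))
  w_hand <- rowMeans(G) / diag(G)
  eta2 <- evaluate_basis(b, scale_exposure(df2$a, c(0, 1)))
  Z2 <- Zn_weights(df2, gman$gfit, eta2)
  expect_equal(Z2, w_hand * sweep(eta2, 2, colMeans(eta2)))
})

test_that("one-step estimator: reduces to plug-in at zero residuals,
          linearity in the test function, and centered null sampling
          behavior with oracle nuisances", {
  d <- fixture_data("flat_null", 150, 43)
  on <- oracle_nuisances("flat_null")
  # Y generated exactly at Q0 => correction vanishes
  d0 <- d
  W <- sample_W(d)
  d0$y <- predict_q(on$qfit, W, d$a)
  d0 <- dr_sample(as.data.frame(d0), c(-1, 1))
  ps0 <- one_step_psi(d0, on$qfit, on$gfit, basis = sobolev_basis(6))
  th <- plugin_theta(on$qfit, d0)
  eta <- evaluate_basis(sobolev_basis(6),
                        scale_exposure(d0$a, c(-1, 1)))
  expect_equal(ps0$U, plugin_psi(th, NULL, eta, d0$a), tolerance = 1e-12)
  # psi(sum c_d eta_d) = U'c: linearity carried by the U vector
  ps <- one_step_psi(d, on$qfit, on$gfit, basis = sobolev_basis(6))
  expect_equal(length(ps$U), 6)
  expect_equal(dim(ps$Phi), c(150, 6))
  # under the null with oracle nuisances, sqrt(n) U_d is centered:
  # across replicates the mean is within Monte Carlo error of zero
  Us <- sapply(1:40, function(s) {
    di <- generate_dataset("flat_null", 150, seed = 4000 + s)
    one_step_psi(di, on$qfit, on$gfit, basis = sobolev_basis(4))$U
  })
  zstat <- sqrt(150) * rowMeans(Us) / (apply(sqrt(150) * Us, 1, sd) /
                                         sqrt(40))
  expect_true(all(abs(zstat) < 4))
})

test_that("estimated EIF satisfies the empirical-mean identity and the
          theta-replacement flag removes the null dependence", {
  nf <- fixture_nuisances("cubic_alt", 200, 44)
  d <- nf$data
  b <- sobolev_basis(8)
  ps <- one_step_psi(d, nf$qfit, nf$gfit, basis = b,
                     use_theta_hat_eif = FALSE)
  # algebraic identity: column means of Phi equal the one-step correction
  expect_equal(colMeans(ps$Phi), ps$U - ps$U_plug, tolerance = 1e-10)
  # flag on: Phi is invariant to the candidate null
  p1 <- estimate_eif(d, nf$qfit, nf$gfit, theta_star = NULL, basis = b,
                     use_theta_hat = TRUE)
  p2 <- estimate_eif(d, nf$qfit, nf$gfit,
                     theta_star = function(a) 3 * a - 1, basis = b,
                     use_theta_hat = TRUE)
  expect_equal(p1, p2)
  p3 <- estimate_eif(d, nf$qfit, nf$gfit,
                     theta_star = function(a) 3 * a - 1, basis = b,
                     use_theta_hat = FALSE)
  expect_gt(max(abs(p1 - p3)), 1e-8)
})

test_that("finite-difference Gateaux derivative matches the analytic
          influence function on a discrete toy distribution", {
  dist <- toy_distribution()
  cm <- toy_components(dist)
  # empirical replica: 16 rows reproducing the exact probabilities
  reps <- round(dist$p * 16)
  idx <- rep(seq_len(nrow(dist$support)), reps)
  df <- dr_sample(data.frame(w1 = dist$support$w[idx],
                             a = dist$support$a[idx],
                             y = dist$support$y[idx]),
                  exposure_bounds = c(0.1, 0.9))
  nf <- function_nuisances(
    q = function(W, a) {
      vapply(seq_along(a), function(i) {
        cm$Q[match(W[i, 1], cm$w_lv), match(a[i], cm$a_lv)]
      }, numeric(1))
    },
    g = function(a, W) {
      cm$G[match(a, cm$a_lv), match(W[, 1], cm$w_lv)]
    })
  b <- sobolev_basis(4)
  tstar <- function(a) 0.5 * a
  Phi <- estimate_eif(df, nf$qfit, nf$gfit, theta_star = tstar,
                      basis = b, use_theta_hat = FALSE)
  h_fun <- function(d0) {
    function(a) evaluate_basis(b, scale_exposure(a, c(0.1, 0.9)))[, d0]
  }
  perturb <- function(dist, k, t) {
    p <- (1 - t) * dist$p
    p[k] <- p[k] + t
    list(support = dist$support, p = p)
  }
  t_eps <- 1e-5
  for (d0 in 1:4) {
    h <- h_fun(d0)
    for (k in c(1, 5, 9, 12)) {
      deriv <- (toy_psi(perturb(dist, k, t_eps), h, tstar) -
                  toy_psi(perturb(dist, k, -t_eps), h, tstar)) /
        (2 * t_eps)
      row <- which(idx == k)[1]
      expect_equal(Phi[row, d0], deriv, tolerance = 1e-4)
    }
  }
})

test_that("TML update: zero steps when residuals are orthogonal, loss
          monotone, final estimating equation below threshold", {
  nf <- fixture_nuisances("cubic_alt", 200, 45)
  d <- nf$data
  ob <- oracle_class_bounds()
  st <- tmle_update(d, nf$qfit, nf$gfit, basis = sobolev_basis(10),
                    kappa = ob$kappa)
  expect_true(all(diff(st$loss) <= 1e-12))
  expect_lte(st$final_derivative, st$threshold)
  # re-solve the program at the converged state: residual equation holds
  ing <- st$ingredients
  Ufin <- drop(crossprod(ing$Z, st$residual)) / ing$n
  re <- solve_sup_ctx(sup_context(ing$gram$V, ing$gram$Gamma), Ufin,
                      ob$kappa, hard_case = "member")
  expect_lte(re$statistic, st$threshold * (1 + 1e-8))
  # orthogonal start: replace Y by fitted values, no update needed
  d0 <- d
  d0$y <- predict_q(nf$qfit, sample_W(d), d$a)
  d0 <- dr_sample(as.data.frame(d0), c(-1, 1))
  st0 <- tmle_update(d0, nf$qfit, nf$gfit, basis = sobolev_basis(10),
                     kappa = ob$kappa)
  expect_equal(st0$B, 0L)
  ps0 <- tmle_psi(st0)
  th <- plugin_theta(nf$qfit, d0)
  eta <- evaluate_basis(sobolev_basis(10), scale_exposure(d0$a, c(-1, 1)))
  expect_equal(ps0$U, plugin_psi(th, NULL, eta, d0$a), tolerance = 1e-10)
})

test_that("TML curve stays within padded outcome range and one-step/TML
          agree to first order on simulated data", {
  nf <- fixture_nuisances("cubic_alt", 300, 46)
  d <- nf$data
  ob <- oracle_class_bounds()
  st <- tmle_update(d, nf$qfit, nf$gfit, kappa = ob$kappa)
  tht <- tmle_theta(st)
  vals <- tht(seq(-1, 1, length.out = 21))
  pad <- 0.3 * diff(range(d$y))
  expect_true(all(vals > min(d$y) - pad - 2 & vals < max(d$y) + pad + 2))
  ps2 <- tmle_psi(st)
  ps1 <- one_step_psi(d, nf$qfit, nf$gfit)
  # coarse first-order sanity here; the n-scaling of the agreement is
  # exercised in the acceptance suite
  expect_lt(max(abs(ps1$U - ps2$U)), 0.15)
})
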