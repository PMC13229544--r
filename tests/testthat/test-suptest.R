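# KKT supremum solver vs brute-force dual oracle, multiplier bootstrap
# mechanics, and the end-to-end flat-null test object.

random_instance <- function(D, n = 60) {
  X <- matrix(rnorm(n * D), n, D)
  V <- crossprod(scale(X, scale = FALSE)) / n
  gam <- sort(exp(runif(D, -6, 0)), decreasing = TRUE)
  list(V = V, Gamma = diag(1 / gam), U = rnorm(D), gam = gam)
}

test_that("solve_sup: trivial single-direction case and sign symmetry", {
  # V = I, huge kappa: statistic is the Euclidean norm (variance bound
  # alone), attained at c proportional to U
  V <- diag(2); Gamma <- diag(c(5, 9)); U <- c(0.8, -0.6)
  s <- solve_sup(U, V, Gamma, 1e6)
  expect_equal(s$statistic, 1)
  expect_equal(drop(crossprod(s$c, V %*% s$c)), 1, tolerance = 1e-8)
  expect_equal(solve_sup(-U, V, Gamma, 1e6)$statistic, s$statistic)
  # U = 0 degenerates to zero
  z <- solve_sup(c(0, 0), V, Gamma, 10)
  expect_equal(z$statistic, 0)
  expect_equal(z$c, c(0, 0))
})

test_that("solve_sup agrees with the dual-bound brute force on random
          instances and satisfies its own KKT constraints", {
  set.seed(11)
  for (i in 1:100) {
    inst <- random_instance(sample(2:6, 1))
    # keep kappa above the minimum feasible roughness at unit variance
    kmin <- 1 / sup_context(inst$V, inst$Gamma)$lam[1]
    kap <- kmin * exp(runif(1, 0.3, 5))
    s <- tryCatch(solve_sup(inst$U, inst$V, inst$Gamma, kap),
                  error = function(e) NULL)
    if (is.null(s)) next   # hard-case instances are excluded by design
    bf <- sup_bruteforce(inst$U, inst$V, inst$Gamma, kap)
    expect_equal(s$statistic, bf, tolerance = 1e-5)
    expect_equal(drop(crossprod(s$c, inst$V %*% s$c)), 1,
                 tolerance = 1e-6)
    expect_lte(drop(crossprod(s$c, inst$Gamma %*% s$c)), kap * (1 + 1e-6))
    expect_equal(sum(inst$U * s$c), s$statistic, tolerance = 1e-8)
  }
})

test_that("brute force oracle: zero input and hard-case error path", {
  inst <- random_instance(4)
  expect_equal(sup_bruteforce(rep(0, 4), inst$V, inst$Gamma, 5), 0)
  # kappa below the minimum feasible roughness: KKT root not bracketed
  kmin <- 1 / sup_context(inst$V, inst$Gamma)$lam[1]
  expect_error(solve_sup(inst$U, inst$V, inst$Gamma, kmin / 10),
               "kappa")
})

test_that("multiplier bootstrap: degenerate influence, linear scaling,
          and seed reproducibility", {
  set.seed(3)
  inst <- random_instance(4, n = 50)
  kap <- 3 / sup_context(inst$V, inst$Gamma)$lam[1]
  Phi0 <- matrix(0, 50, 4)
  expect_equal(multiplier_bootstrap(Phi0, inst$V, inst$Gamma, kap,
                                    M = 100, seed = 1),
               rep(0, 100))
  Phi <- matrix(rnorm(200), 50, 4)
  d1 <- multiplier_bootstrap(Phi, inst$V, inst$Gamma, kap, M = 150,
                             seed = 7)
  d2 <- multiplier_bootstrap(3 * Phi, inst$V, inst$Gamma, kap, M = 150,
                             seed = 7)
  expect_equal(d2, 3 * d1, tolerance = 1e-9)
  expect_identical(d1, multiplier_bootstrap(Phi, inst$V, inst$Gamma, kap,
                                            M = 150, seed = 7))
  expect_true(all(d1 >= 0))
  expect_error(multiplier_bootstrap(Phi, inst$V, inst$Gamma, kap, M = 10),
               "M >= 100")
})

test_that("bootstrap quantiles are stable across seeds at moderate M", {
  nf <- fixture_nuisances("flat_null", 200, 47)
  ps <- one_step_psi(nf$data, nf$qfit, nf$gfit)
  gm <- ps$ingredients$gram
  ob <- oracle_class_bounds()
  q1 <- quantile(multiplier_bootstrap(ps$Phi, gm$V, gm$Gamma, ob$kappa,
                                      M = 1000, seed = 1), 0.95)
  q2 <- quantile(multiplier_bootstrap(ps$Phi, gm$V, gm$Gamma, ob$kappa,
                                      M = 1000, seed = 2), 0.95)
  expect_equal(unname(q1), unname(q2), tolerance = 0.08)
})

test_that("flat-null test object invariants and degenerate p-values", {
  nf <- fixture_nuisances("cubic_alt", 150, 48)
  ob <- oracle_class_bounds()
  tst <- flat_null_test(nf$data, kappa = ob$kappa, M = 150, seed = 5,
                        nuisances = nf[c("qfit", "gfit")],
                        control = ctl_fast)
  expect_s3_class(tst, "dr_test")
  expect_gte(tst$statistic, 0)
  expect_true(tst$p_value >= 0 && tst$p_value <= 1)
  expect_equal(tst$p_value, mean(tst$draws > tst$statistic))
  expect_length(tst$draws, 150)
  expect_output(print(tst), "p-value")
  # same seed, same data: identical result
  tst2 <- flat_null_test(nf$data, kappa = ob$kappa, M = 150, seed = 5,
                         nuisances = nf[c("qfit", "gfit")],
                         control = ctl_fast)
  expect_identical(tst$statistic, tst2$statistic)
  expect_identical(tst$p_value, tst2$p_value)
})

test_that("statistic is invariant to affine exposure rescaling", {
  nf <- fixture_nuisances("cubic_alt", 150, 49)
  d <- nf$data
  ob <- oracle_class_bounds()
  t1 <- flat_null_test(d, kappa = ob$kappa, M = 100, seed = 3,
                       nuisances = nf[c("qfit", "gfit")],
                       control = ctl_fast)
  # rescale exposures affinely; wrap nuisances to act on the raw scale
  d2 <- as.data.frame(d)
  d2$a <- 10 + 5 * d2$a
  d2 <- dr_sample(d2, exposure_bounds = c(5, 15))
  back <- function(a) (a - 10) / 5
  nf2 <- function_nuisances(
    q = function(W, a) predict_q(nf$qfit, W, back(a)),
    g = function(a, W) drop(predict_g_grid(nf$gfit, back(a), W)) / 5)
  t2 <- flat_null_test(d2, kappa = ob$kappa, M = 100, seed = 3,
                       nuisances = nf2, control = ctl_fast)
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-8)
})

test_that("indicator-class comparator runs and shares the bootstrap
          contract", {
  nf <- fixture_nuisances("cubic_alt", 150, 48)
  tst <- flat_null_test(nf$data, hclass = "indicator", M = 150, seed = 9,
                        nuisances = nf[c("qfit", "gfit")],
                        control = ctl_fast)
  expect_gte(tst$statistic, 0)
  expect_true(tst$p_value >= 0 && tst$p_value <= 1)
  expect_true(all(tst$draws >= 0))
})
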