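# Band inversion: nu estimation, fixed multipliers, the two-ellipsoid
# band-limit program (against closed forms and an independent penalized
# optimizer), and end-to-end band construction.

test_that("estimate_nu: roughness of the curve projection, scaling, and
          oracle-nuisance magnitude", {
  nf <- fixture_nuisances("cubic_alt", 500, 61)
  nu <- estimate_nu(nf$data, nf$qfit, nf$gfit)
  expect_gt(nu, 0)
  # quadratic scaling in the response: J(t f) = t^2 J(f) for fixed lambda
  b <- sobolev_basis(10)
  a01 <- scale_exposure(nf$data$a, c(-1, 1))
  f <- pseudo_outcome(nf$data, nf$qfit, nf$gfit)
  pr1 <- fit_penalized_projection(f, b, a01, lambda_grid = c(1, 2, 4))
  pr2 <- fit_penalized_projection(2 * f, b, a01,
                                  lambda_grid = c(1, 2, 4) * 4^0)
  expect_gt(roughness(pr2$c, b), roughness(pr1$c, b))
})

test_that("fixed multipliers expose the order-statistic critical value", {
  nf <- fixture_nuisances("cubic_alt", 150, 48)
  ob <- oracle_class_bounds()
  tst <- flat_null_test(nf$data, kappa = ob$kappa, M = 200, seed = 5,
                        nuisances = nf[c("qfit", "gfit")],
                        control = ctl_fast)
  fm <- fixed_multipliers(tst, alpha = 0.05)
  expect_equal(fm$t_star,
               sort(sqrt(tst$n) * tst$draws)[ceiling(0.95 * 200)])
  expect_gt(fm$lambda1, 0)
  expect_gte(fm$lambda2, 0)
})

test_that("band limits: closed-form Cauchy-Schwarz bound when the test
          constraint is inactive, and collapse as nu -> 0", {
  set.seed(21)
  D <- 8
  b20 <- sobolev_basis(D)
  X <- matrix(runif(400), 50)
  a01 <- seq(0.36, 0.64, length.out = 50)
  gm <- gram_matrices(b20, a01)
  U0 <- rnorm(D, sd = 0.05)
  sol <- solve_sup(U0, gm$V, gm$Gamma, 1e5)
  bvec <- gm$eta[7, ] - colMeans(gm$eta)
  nu <- 200
  # enormous critical value: only the roughness ball matters
  lim <- band_limits(bvec, U0, gm$V, gm$Gamma, sol$lambda1,
                     max(sol$lambda2, 1e-8), nu, t_star = 1e8, n = 50)
  cs <- sqrt(nu * sum(bvec^2 * b20$gamma))
  expect_equal(lim$upper, cs, tolerance = 1e-6)
  expect_equal(lim$lower, -cs, tolerance = 1e-6)
  # nu -> 0: both limits shrink to zero (only near-flat candidates) when
  # the flat candidate itself passes
  lim0 <- band_limits(bvec, U0 * 0, gm$V, gm$Gamma, sol$lambda1,
                      max(sol$lambda2, 1e-8), nu = 1e-10, t_star = 1e8,
                      n = 50)
  expect_lt(abs(lim0$upper), 1e-4)
  expect_lt(abs(lim0$lower), 1e-4)
})

test_that("band limits carry a primal-dual certificate and dominate an
          independent feasible search", {
  set.seed(31)
  D <- 6
  b6 <- sobolev_basis(D)
  for (rep in 1:8) {
    a01 <- scale_exposure(sort(runif(80, -1, 1)), c(-1, 1))
    gm <- gram_matrices(b6, a01)
    U0 <- rnorm(D, sd = 0.1)
    kap <- 3 / sup_context(gm$V, gm$Gamma)$lam[1]
    sol <- tryCatch(solve_sup(U0, gm$V, gm$Gamma, kap),
                    error = function(e) NULL)
    if (is.null(sol) || sol$lambda2 <= 0) next
    nu <- exp(runif(1, 2, 8))
    tst <- runif(1, 0.5, 3)
    bvec <- gm$eta[11, ] - colMeans(gm$eta)
    lim <- band_limits(bvec, U0, gm$V, gm$Gamma, sol$lambda1,
                       sol$lambda2, nu, t_star = tst, n = 80)
    if (is.null(lim)) next
    G <- solve(gm$V + sol$lambda2 * gm$Gamma)
    Mq <- gm$V %*% G %*% gm$V / sol$lambda1
    mv <- drop(gm$V %*% G %*% U0) / sol$lambda1
    q0 <- drop(crossprod(U0, G %*% U0)) / sol$lambda1
    tau <- tst / sqrt(80)
    gmv <- 1 / b6$gamma
    q1f <- function(cc) sum(gmv * cc^2)
    q2f <- function(cc) {
      drop(crossprod(cc, Mq %*% cc)) - 2 * sum(mv * cc) + q0
    }
    # attainment: the reported limit is achieved by a feasible vector
    cu <- lim$c_upper
    expect_lte(q1f(cu), nu * (1 + 1e-5))
    expect_lte(q2f(cu), tau + 1e-5 * max(1, tau))
    expect_gte(sum(bvec * cu), lim$upper - 1e-3 * max(1, abs(lim$upper)))
    # dominance: no feasible point from an independent penalized search
    # exceeds the reported limit
    obj <- function(cc) {
      viol <- max(0, q1f(cc) / nu - 1) +
        max(0, (q2f(cc) - tau) / max(tau, 0.1))
      -sum(bvec * cc) + 1e4 * viol^2
    }
    for (k in 1:12) {
      st <- rnorm(D, 0, 0.2 / sqrt(gmv))
      o <- optim(st, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-12))
      cc <- o$par
      if (q1f(cc) <= nu && q2f(cc) <= tau) {
        expect_lte(sum(bvec * cc), lim$upper + 1e-4 * max(1, abs(lim$upper)))
      }
    }
  }
})

test_that("feasible-set monotonicity: larger nu or t* never narrows the
          band", {
  nf <- fixture_nuisances("cubic_alt", 150, 48)
  ob <- oracle_class_bounds()
  tst <- flat_null_test(nf$data, kappa = ob$kappa, M = 200, seed = 5,
                        nuisances = nf[c("qfit", "gfit")],
                        control = ctl_fast)
  ing <- tst$prep$ing
  fm <- fixed_multipliers(tst, 0.05)
  bvec <- ing$gram$eta[5, ] - colMeans(ing$gram$eta)
  l1 <- band_limits(bvec, tst$U, ing$gram$V, ing$gram$Gamma, fm$lambda1,
                    fm$lambda2, nu = ob$nu, fm$t_star, ing$n)
  l2 <- band_limits(bvec, tst$U, ing$gram$V, ing$gram$Gamma, fm$lambda1,
                    fm$lambda2, nu = 2 * ob$nu, fm$t_star, ing$n)
  l3 <- band_limits(bvec, tst$U, ing$gram$V, ing$gram$Gamma, fm$lambda1,
                    fm$lambda2, nu = ob$nu, 2 * fm$t_star, ing$n)
  expect_gte(l2$upper + 1e-7, l1$upper)
  expect_lte(l2$lower - 1e-7, l1$lower)
  expect_gte(l3$upper + 1e-7, l1$upper)
  expect_lte(l3$lower - 1e-7, l1$lower)
})

test_that("end-to-end band: runs on a 50-point grid, ordered limits, and
          self-consistency with the accepted flat null", {
  d <- fixture_data("flat_null", 200, 62)
  ob <- oracle_class_bounds()
  bd <- suppressWarnings(
    confidence_band(d, nu = ob$nu, kappa = ob$kappa, M = 300, seed = 8,
                    control = ctl_fast))
  expect_length(bd$grid, 50)
  ok <- !bd$infeasible
  expect_true(all(bd$lower[ok] <= bd$upper[ok] + 1e-9))
  expect_output(print(bd), "band")
  # flat null accepted => the zero function lies inside the band
  if (bd$test$p_value > bd$alpha) {
    expect_true(all(bd$lower[ok] <= 1e-7 & bd$upper[ok] >= -1e-7))
  }
  # plug-in centered curve at grid points stays within its own band
  th <- bd$test$theta_hat(bd$grid)
  thc <- th - mean(bd$test$theta_hat(d$a))
  inside <- mean(bd$lower[ok] - 0.05 <= thc[ok] &
                   thc[ok] <= bd$upper[ok] + 0.05)
  expect_gt(inside, 0.9)
})
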