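# Shared fixtures: cached datasets, light pipeline controls, and the
# discrete toy distribution used for the influence-function derivative
# oracle.

# light learner settings so the suite stays fast
ctl_fast <- dr_control(knots = 5, cv_folds = 4, proj_folds = 5)

# memoized datasets (generation is cheap but repeated in many tests)
.fixture_env <- new.env()
fixture_data <- function(setting, n, seed) {
  key <- paste(setting, n, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_dataset(setting, n = n, seed = seed)
  }
  .fixture_env[[key]]
}

fixture_nuisances <- function(setting, n, seed, control = ctl_fast) {
  key <- paste("nuis", setting, n, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    d <- fixture_data(setting, n, seed)
    qf <- fit_outcome_regression(d, knots = control$knots,
                                 cv_folds = control$cv_folds)
    gf <- fit_conditional_density(d, knots = control$density_knots,
                                  cv_folds = control$cv_folds)
    .fixture_env[[key]] <- list(qfit = qf, gfit = gf, data = d)
  }
  .fixture_env[[key]]
}

# Discrete toy distribution on a small support, used to compute exact
# population functionals and finite-difference pathwise derivatives.
# Probabilities are multiples of 1/16 so an exact empirical replica
# exists as a 16-row sample.
toy_distribution <- function() {
  support <- expand.grid(w = c(-1, 1), a = c(0.1, 0.5, 0.9),
                         y = c(-1, 2))
  p <- c(2, 1, 1, 2, 1, 1, 1, 2, 2, 1, 1, 1) / 16
  list(support = support, p = p)
}

# exact population pieces of a discrete (w, a, y) distribution
toy_components <- function(dist) {
  s <- dist$support; p <- dist$p
  a_lv <- sort(unique(s$a)); w_lv <- sort(unique(s$w))
  f_a <- vapply(a_lv, function(a) sum(p[s$a == a]), numeric(1))
  f_w <- vapply(w_lv, function(w) sum(p[s$w == w]), numeric(1))
  Q <- outer(w_lv, a_lv, Vectorize(function(w, a) {
    i <- s$w == w & s$a == a
    sum(p[i] * s$y[i]) / sum(p[i])
  }))
  G <- outer(a_lv, w_lv, Vectorize(function(a, w) {
    sum(p[s$w == w & s$a == a]) / sum(p[s$w == w])   # pmf of A given W
  }))
  list(a_lv = a_lv, w_lv = w_lv, f_a = f_a, f_w = f_w, Q = Q, G = G)
}

# exact psi(h) for a discrete distribution and test function h(a)
toy_psi <- function(dist, h, theta_star = function(a) 0) {
  cm <- toy_components(dist)
  theta <- drop(cm$f_w %*% cm$Q)                  # E_W Q(W, a) on a_lv
  tbar <- theta - sum(cm$f_a * theta)
  tsbar <- theta_star(cm$a_lv) - sum(cm$f_a * theta_star(cm$a_lv))
  sum(cm$f_a * (tbar - tsbar) * h(cm$a_lv))
}
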