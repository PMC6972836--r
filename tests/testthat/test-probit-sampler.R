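rtnorm <- latentord:::rtnorm

test_that("truncated normal draws respect bounds, moments and far tails", {
  set.seed(1)
  x <- rtnorm(1e5, mean = 0, lower = 0)
  expect_true(all(x > 0))
  expect_equal(mean(x), sqrt(2 / pi), tolerance = 0.01)

  y <- rtnorm(1e4, mean = 0, lower = -1, upper = 1)
  expect_true(all(y >= -1 & y <= 1))

  # deep-tail truncation stays finite and inside the region
  z <- rtnorm(1e3, mean = 0, lower = 12)
  expect_true(all(is.finite(z)) && all(z >= 12) && all(z < 14))
  z2 <- rtnorm(1e3, mean = 0, upper = -12)
  expect_true(all(is.finite(z2)) && all(z2 <= -12))
  expect_error(rtnorm(1, lower = 1, upper = 0), "empty")
})

test_that("probit augmentation truncates to the observed class region", {
  set.seed(2)
  eta <- matrix(0, 100, 10)
  y1 <- matrix(1, 100, 10)
  zs <- latentord:::.draw_zstar(y1, eta, "binary")
  expect_true(all(zs > 0))
  expect_equal(mean(zs), sqrt(2 / pi), tolerance = 0.02)
  y0 <- matrix(0, 100, 10)
  expect_true(all(latentord:::.draw_zstar(y0, eta, "binary") <= 0))

  yo <- matrix(2, 50, 10)
  zso <- latentord:::.draw_zstar(yo, eta[1:50, ], "ordinal",
                                 cutoffs = c(-1, 1))
  expect_true(all(zso > -1 & zso <= 1))
})

test_that("gaussian full conditionals match conjugate/brute-force oracles", {
  # single observation, V = 1, mu0 = 0: posterior N(r/2, 1/2); verified
  # against a brute-force grid posterior before asserting the sampler
  r <- 0.8
  grid <- seq(-6, 6, length.out = 4001)
  gp <- grid_posterior(grid, dnorm(grid, 0, 1, log = TRUE) +
                               dnorm(r, grid, 1, log = TRUE))
  expect_equal(gp$mean, r / 2, tolerance = 1e-6)
  expect_equal(gp$var, 1 / 2, tolerance = 1e-4)
  set.seed(3)
  draws <- replicate(5e4, latentord:::.draw_unit_effects(r, 1, 0, 1))
  expect_equal(mean(draws), gp$mean, tolerance = 0.05)
  expect_equal(var(draws), gp$var, tolerance = 0.05)

  # prior-only conditional of the latent factors is standard normal
  set.seed(4)
  Z <- latentord:::.draw_factors(matrix(0, 500, 4), matrix(0, 4, 2))
  expect_gt(ks.test(as.vector(Z), pnorm)$p.value, 0.01)

  # constrained loading rows: zero pattern kept, diagonals positive
  set.seed(5)
  R1 <- matrix(rnorm(30 * 5), 30, 5)
  Z5 <- matrix(rnorm(60), 30, 2)
  for (i in 1:50) {
    Th <- latentord:::.draw_loadings(R1, Z5, matrix(0.5, 5, 2), diag(2))
    expect_identical(Th[1, 2], 0)
    expect_gt(Th[1, 1], 0)
    expect_gt(Th[2, 2], 0)
  }
})

test_that("probit Gibbs matches an importance-sampling posterior on a 2x2 toy", {
  # q = 1, y with one presence per row; oracle = self-normalised
  # importance sampling from the prior (exact as M -> infinity)
  y <- community_matrix(matrix(c(1, 0, 0, 1), 2, 2), "binary")
  set.seed(6)
  M <- 2e6
  a1 <- rnorm(M); a2 <- rnorm(M); b1 <- rnorm(M); b2 <- rnorm(M)
  z1 <- rnorm(M); z2 <- rnorm(M)
  t1 <- abs(rnorm(M)); t2 <- rnorm(M)
  ll <- pnorm(a1 + b1 + z1 * t1, log.p = TRUE) +
    pnorm(-(a1 + b2 + z1 * t2), log.p = TRUE) +
    pnorm(-(a2 + b1 + z2 * t1), log.p = TRUE) +
    pnorm(a2 + b2 + z2 * t2, log.p = TRUE)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  neff <- 1 / sum(w^2)
  is_mean <- function(x) sum(w * x)
  is_se <- function(x) sqrt(sum(w * (x - is_mean(x))^2) / neff)

  fit <- latentord(y, q = 1, control = mcmc_control(20000, 5000, 5,
                                                    seed = 7))
  for (par in list(list(a1, fit$draws$alpha[, 1]),
                   list(a2, fit$draws$alpha[, 2]),
                   list(b1, fit$draws$beta[, 1]),
                   list(b2, fit$draws$beta[, 2]))) {
    se_chain <- sd(par[[2]]) / sqrt(latentord:::.ess_imse(par[[2]]))
    tol <- 3 * sqrt(is_se(par[[1]])^2 + se_chain^2)
    expect_lt(abs(is_mean(par[[1]]) - mean(par[[2]])), max(tol, 0.05))
  }
})

test_that("the sampler recovers a known latent configuration", {
  d <- ord_design("binary", n = 50, p = 50, seed = 8)
  sim <- sim_community(d, 1)
  fit <- latentord(sim$y, control = mcmc_control(3000, 1500, 3, seed = 8))
  Zhat <- apply(align_factors(fit), c(2, 3), mean)
  expect_gt(procrustes_cor(Zhat, sim$truth$Z), 0.7)
})

test_that("one-dimensional fits are calibrated on the raw posterior", {
  # q = 1: the positivity constraint pins the reflection completely, so
  # chains converge on the raw scale and Bayesian calibration must hold
  # without any alignment
  d <- ord_design("binary", n = 8, p = 8, q = 1, seed = 55)
  covered <- 0L; tot <- 0L
  for (r in 1:40) {
    sim <- sim_community(d, r)
    f <- latentord(sim$y, q = 1,
                   control = mcmc_control(6000, 2000, 25, seed = 7000 + r))
    for (i in 1:8) {
      int <- hpd_interval(f$draws$Z[, i, 1], 0.95)
      covered <- covered + (sim$truth$Z[i, 1] >= int[1] &&
                              sim$truth$Z[i, 1] <= int[2])
      tot <- tot + 1L
    }
  }
  expect_gt(covered / tot, 0.88)
  expect_lte(covered / tot, 1)
})

test_that("chains are reproducible and always satisfy the constraints", {
  sim <- sim_community(ord_design("binary", n = 10, p = 8, seed = 9))
  ctl <- mcmc_control(600, 200, 2, seed = 10)
  f1 <- latentord(sim$y, control = ctl)
  f2 <- latentord(sim$y, control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws$Theta[, 1, 2] == 0))
  expect_true(all(f1$draws$Theta[, 1, 1] > 0))
  expect_true(all(f1$draws$Theta[, 2, 2] > 0))
})

test_that("ordinal cutoffs stay ordered and class-1-only data push c1 up", {
  d <- ord_design("ordinal", n = 12, p = 10, K = 4, seed = 11)
  sim <- sim_community(d, 1)
  fit <- latentord(sim$y, control = mcmc_control(1000, 400, 2, seed = 11))
  co <- fit$draws$cutoffs
  expect_true(all(co[, 2] > co[, 1] & co[, 3] > co[, 2]))

  # every observation in the lowest class: c1 sits above the latent mass
  y1 <- community_matrix(matrix(1, 6, 6), "ordinal", K = 2)
  f1 <- latentord(y1, control = mcmc_control(400, 100, 1, seed = 12))
  eta_hat <- linear_predictor(latentord:::.posterior_mean_state(f1))
  expect_gt(mean(f1$draws$cutoffs), mean(eta_hat))
})
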