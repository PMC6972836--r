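test_that("community generation is reproducible with independent replicates", {
  d <- ord_design("binary", n = 15, p = 12, seed = 1)
  s1 <- sim_community(d, 1)
  s1b <- sim_community(d, 1)
  expect_identical(s1$y, s1b$y)
  expect_identical(s1$truth, s1b$truth)
  s2 <- sim_community(d, 2)
  expect_false(identical(unclass(s1$y), unclass(s2$y)))

  # generated loadings satisfy the identifiability constraints
  expect_identical(s1$truth$Theta[1, 2], 0)
  expect_gt(s1$truth$Theta[1, 1], 0)
  expect_gt(s1$truth$Theta[2, 2], 0)
})

test_that("binary generation is symmetric around one half", {
  # all effect means zero: marginal presence probability is exactly 1/2
  # by symmetry of the latent terms
  # cells within a row/column are correlated (shared effects), so the
  # tolerance reflects the effective rather than nominal sample size
  d <- ord_design("binary", n = 100, p = 100, seed = 2)
  pres <- mean(vapply(1:4, function(r)
    mean(unclass(sim_community(d, r)$y)), numeric(1)))
  expect_equal(pres, 0.5, tolerance = 0.03)
})

test_that("count generation matches a direct Monte Carlo oracle", {
  # with zero effects the zero-probability of a cell is
  # E[exp(-exp(z'theta))]; oracle by direct Monte Carlo of the latent term
  set.seed(3)
  M <- 5e5
  th <- matrix(rnorm(2 * M), M, 2)
  z <- matrix(rnorm(2 * M), M, 2)
  p0_oracle <- mean(exp(-exp(rowSums(th * z))))
  d <- ord_design("poisson", n = 100, p = 100, sigma_alpha = 0,
                  sigma_beta = 0, seed = 3)
  p0 <- mean(vapply(1:4, function(r)
    mean(unclass(sim_community(d, r)$y) == 0), numeric(1)))
  expect_equal(p0, p0_oracle, tolerance = 0.02 * p0_oracle)

  # negative binomial designs generate overdispersed counts
  dn <- ord_design("negbinomial", n = 60, p = 60, omega = 1, seed = 4)
  sn <- sim_community(dn, 1)
  dp <- ord_design("poisson", n = 60, p = 60, seed = 4)
  sp <- sim_community(dp, 1)
  expect_gt(mean(unclass(sn$y) == 0), mean(unclass(sp$y) == 0))
})

test_that("rare-species occurrence analytics behave as designed", {
  d <- ord_design("binary", n = 20, p = 10, sigma_beta = 0.5,
                  p_rare = 10, seed = 5)
  os <- occurrence_summaries(d, mc_draws = 4e4, seed = 5)
  expect_lt(os$occurrence$estimate, 0.06)   # rare indeed
  expect_gt(os$zero_fraction$estimate, 0.5)

  # standard errors shrink like 1/sqrt(draws)
  os_small <- occurrence_summaries(d, mc_draws = 1e4, seed = 6)
  ratio <- os_small$occurrence$se / os$occurrence$se
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.7)

  # degenerate symmetric spec: occurrence is one half
  d0 <- ord_design("binary", n = 10, p = 2, sigma_alpha = 0,
                   p_rare = 2, mu_rare = 0, sigma_rare = 0, seed = 7)
  o0 <- occurrence_summaries(d0, mc_draws = 4e4, seed = 7)
  expect_lt(abs(o0$occurrence$estimate - 0.5),
            4 * o0$occurrence$se + 1e-3)
})

test_that("population parameters are the mean and SD of unit effect estimates", {
  fake <- structure(list(draws = list(
    alpha = matrix(rep(c(-1, 1), each = 120), 120, 2),
    beta = matrix(0, 120, 2))), class = "latentord")
  est <- estimate_population_params(fake)
  expect_equal(unname(est), c(0, sqrt(2), 0, 0))

  fake2 <- structure(list(draws = list(
    alpha = matrix(2.5, 120, 3), beta = matrix(1, 120, 2))),
    class = "latentord")
  expect_equal(unname(estimate_population_params(fake2)[1:2]), c(2.5, 0))
})

test_that("the design tool returns one finite row per grid cell", {
  d <- ord_design("binary", n = 10, p = 10, reps = 2, seed = 8)
  res <- hpd_width_design(d, settings = mcmc_control(400, 150, 1, seed = 8))
  expect_equal(nrow(res), 1L)
  expect_true(is.finite(res$mean_width) && res$mean_width > 0)
  expect_equal(res$reps, 2L)
  expect_equal(res$failed, 0L)

  res2 <- hpd_width_design(d, p_grid = c(8, 12),
                           settings = mcmc_control(400, 150, 1, seed = 8))
  expect_equal(nrow(res2), 2L)
  expect_equal(res2$p, c(8L, 12L))
})

test_that("abundance beats presence on matched simulations", {
  # same underlying Poisson communities analysed as counts vs as
  # presence/absence: counts give narrower intervals
  d <- ord_design("poisson", n = 20, p = 25, seed = 9, reps = 3)
  wc <- wb <- numeric(3)
  for (r in 1:3) {
    sim <- sim_community(d, r)
    fc <- latentord(sim$y, family = "poisson",
                    control = mcmc_control(6000, 3000, 5, seed = r))
    fb <- latentord(degrade_to_presence(sim$y),
                    control = mcmc_control(3000, 1500, 3, seed = r))
    wc[r] <- hpd_widths(fc)$mean_width
    wb[r] <- hpd_widths(fb)$mean_width
  }
  expect_lt(mean(wc), mean(wb))
})
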