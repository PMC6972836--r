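test_that("1-D HPD interval equals the exhaustive window-scan oracle", {
  expect_equal(unname(hpd_interval(0:99, 0.95)), c(0, 94))

  set.seed(1)
  gens <- list(function(m) rnorm(m), function(m) rexp(m),
               function(m) rlnorm(m),
               function(m) c(rnorm(m %/% 2), rnorm(m - m %/% 2, 4)))
  for (i in 1:1000) {
    m <- sample(100:500, 1)
    x <- gens[[(i %% 4) + 1]](m)
    lev <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(unname(hpd_interval(x, lev)), hpd_oracle(x, lev))
  }
  expect_error(hpd_interval(rnorm(50)), "at least 100")
})

test_that("HPD width matches analytic values for known distributions", {
  set.seed(2)
  x <- rnorm(1e6)
  expect_equal(diff(hpd_interval(x, 0.95)), 2 * qnorm(0.975),
               tolerance = 0.02, ignore_attr = TRUE)
  e <- rexp(1e6)
  int <- hpd_interval(e, 0.95)
  expect_lt(int[1], 0.001)                  # monotone density: starts at 0
  expect_equal(int[[2]], -log(0.05), tolerance = 0.02)
})

test_that("latent factor width summaries average all site x dimension widths", {
  set.seed(3)
  m <- 1e4; n <- 6; q <- 2
  Z <- array(rnorm(m * n * q), c(m, n, q))
  hw <- hpd_widths(Z, align = FALSE)
  expect_equal(dim(hw$widths), c(n, q))
  expect_equal(hw$mean_width, mean(hw$intervals$width))
  expect_equal(hw$mean_width, 2 * qnorm(0.975), tolerance = 0.05)

  # degenerate draws give zero widths
  Z0 <- array(1.5, c(200, 3, 2))
  expect_equal(hpd_widths(Z0, align = FALSE)$mean_width, 0)

  # widths are invariant under a constant shift of one coordinate
  Z2 <- Z
  Z2[, 4, 1] <- Z2[, 4, 1] + 50
  expect_equal(hpd_widths(Z2, align = FALSE)$widths,
               hpd_widths(Z, align = FALSE)$widths, tolerance = 1e-12)

  # ...but not under anchoring, which measures relative uncertainty
  hw_anch <- hpd_widths(Z, align = FALSE, anchor_site = 1)
  expect_false(isTRUE(all.equal(hw_anch$mean_width, hw$mean_width,
                                tolerance = 0.01)))
  expect_equal(hw_anch$widths[1, ], c(LF1 = 0, LF2 = 0))
})

test_that("anchoring recentres every draw on the reference site", {
  set.seed(4)
  Z <- array(rnorm(200 * 4 * 2), c(200, 4, 2))
  A <- anchor_factors(Z, 2)
  expect_true(all(A[, 2, ] == 0))
  expect_equal(anchor_factors(A, 2), A)    # idempotent

  # a common random shift of all sites cancels exactly
  shift <- array(rep(rnorm(200 * 2), each = 1), c(200, 1, 2))
  Zs <- Z + shift[, rep(1, 4), , drop = FALSE]
  expect_equal(anchor_factors(Zs, 2), A, tolerance = 1e-12)

  # two-site constant toy: anchored position is the difference
  Zt <- array(0, c(150, 2, 2))
  Zt[, 1, ] <- rep(c(1, 1), each = 150)
  Zt[, 2, ] <- rep(c(3, 2), each = 150)
  At <- anchor_factors(Zt, 1)
  expect_true(all(At[, 2, 1] == 2) && all(At[, 2, 2] == 1))
  expect_error(anchor_factors(Z, 9), "out of range")
})

test_that("rotation alignment is stable and harmless for pinned configurations", {
  set.seed(5)
  # draws tightly concentrated around a fixed configuration: alignment
  # must be essentially a no-op
  conf <- matrix(rnorm(12), 6, 2)
  Z <- array(0, c(500, 6, 2))
  for (t in 1:500) Z[t, , ] <- conf + 0.01 * matrix(rnorm(12), 6, 2)
  expect_equal(align_factors(Z), Z, tolerance = 0.05)

  # spinning the same configuration by random angles: alignment removes
  # the rotational smear entirely
  Zr <- Z
  for (t in 1:500) {
    a <- runif(1, -pi, pi)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    Zr[t, , ] <- Z[t, , ] %*% R
  }
  w_raw <- hpd_widths(Zr, align = FALSE)$mean_width
  w_al <- hpd_widths(Zr, align = TRUE)$mean_width
  expect_gt(w_raw, 10 * w_al)
  expect_equal(w_al, hpd_widths(Z, align = FALSE)$mean_width,
               tolerance = 0.2)
})

test_that("2-D HPD regions have the right area and content", {
  set.seed(6)
  X <- matrix(rnorm(2e5), ncol = 2)
  ell <- hpd_region_2d(X, method = "normal_ellipse")
  expect_equal(ell$area, pi * qchisq(0.95, 2), tolerance = 0.03)
  expect_equal(ell$fraction, 0.95, tolerance = 0.02)
  # isotropic draws: near-circular boundary
  ev <- eigen(ell$cov)$values
  expect_lt(abs(sqrt(ev[1] / ev[2]) - 1), 0.05)

  kde <- hpd_region_2d(X, method = "kde")
  expect_equal(kde$fraction, 0.95, tolerance = 0.02)
  area_poly <- function(p) abs(sum(p[-nrow(p), 1] * p[-1, 2] -
                                   p[-1, 1] * p[-nrow(p), 2])) / 2
  a_kde <- sum(vapply(kde$boundary, area_poly, numeric(1)))
  expect_equal(a_kde, ell$area, tolerance = 0.1 * ell$area,
               ignore_attr = TRUE)

  expect_warning(hpd_region_2d(cbind(rnorm(200), 0), method = "kde"),
                 "rank-deficient")
})

test_that("convergence diagnostics flag broken chains and pass clean ones", {
  fit <- small_binary_fit()
  set.seed(7)
  # white-noise chain: Rhat near 1, ESS near the number of draws
  clean <- fit
  m <- length(fit$loglik)
  expect_lt(latentord:::.split_rhat(rnorm(1e4)), 1.01)
  expect_equal(latentord:::.ess_imse(rnorm(1e4)), 1e4, tolerance = 0.1)

  # two halves with distinct means: split-Rhat far above 1.1
  broken <- c(rnorm(500), rnorm(500, 8))
  expect_gt(latentord:::.split_rhat(broken), 2)

  di <- suppressWarnings(mcmc_diagnostics(fit))
  expect_true(all(is.finite(di$rhat)))
  expect_true(all(di$ess >= 1))
})

test_that("HPD tables export as delimited text", {
  set.seed(8)
  Z <- array(rnorm(150 * 3 * 2), c(150, 3, 2))
  hw <- hpd_widths(Z, align = FALSE)
  f <- tempfile(fileext = ".csv")
  write_hpd(hw, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 6)
  expect_equal(back$width, hw$intervals$width, tolerance = 1e-9)
})
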