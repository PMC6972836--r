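# Shared helpers: independent oracles and small cached fits.

# Exhaustive window-scan HPD oracle: checks every window of ceil(level*m)
# consecutive order statistics with an explicit loop.
hpd_oracle <- function(x, level = 0.95) {
  x <- sort(x)
  m <- length(x)
  k <- ceiling(level * m)
  best <- c(x[1L], x[k])
  for (i in seq_len(m - k + 1L)) {
    if (x[i + k - 1L] - x[i] < best[2L] - best[1L])
      best <- c(x[i], x[i + k - 1L])
  }
  best
}

# correlation between two site configurations after optimal orthogonal
# rotation of A onto B (Procrustes)
procrustes_cor <- function(A, B) {
  s <- svd(crossprod(A, B))
  stats::cor(as.vector(A %*% tcrossprod(s$u, s$v)), as.vector(B))
}

# small cached binary fit shared within a test file
local_fit_cache <- new.env(parent = emptyenv())
small_binary_fit <- function() {
  if (is.null(local_fit_cache$fit)) {
    sim <- sim_community(ord_design("binary", n = 12, p = 10, seed = 42))
    local_fit_cache$fit <- latentord(
      sim$y, control = mcmc_control(800L, 300L, 1L, seed = 42))
  }
  local_fit_cache$fit
}

# posterior mean/variance of a scalar by 1-D grid integration:
# target densities supplied as log(prior)+log(lik) over a grid
grid_posterior <- function(grid, logpost) {
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  m <- sum(w * grid)
  list(mean = m, var = sum(w * (grid - m)^2))
}
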