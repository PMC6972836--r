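# Gibbs sampler for the probit (binary) and cumulative-probit (ordinal)
# latent factor models via the classic latent-normal data augmentation:
# z*_ij ~ N(eta_ij, 1) truncated to the region the observed class implies,
# after which every other full conditional is Gaussian (conjugate).

# Draw the augmented latents z* given observations and linear predictor.
# binary: y=1 -> z* > 0, y=0 -> z* <= 0.
# ordinal: class l -> c_{l-1} <= z* < c_l (c_0 = -Inf, c_K = +Inf).
.draw_zstar <- function(y, eta, family, cutoffs = NULL) {
  if (family == "binary") {
    lower <- ifelse(y == 1, 0, -Inf)
    upper <- ifelse(y == 1, Inf, 0)
  } else {
    lower <- c(-Inf, cutoffs)[y]
    upper <- c(cutoffs, Inf)[y]
  }
  zs <- rtnorm(length(eta), mean = eta, sd = 1, lower = lower,
               upper = upper)
  dim(zs) <- dim(eta)
  zs
}

# Conjugate normal draw for n unit effects each observed m times with unit
# residual variance: prior N(mu0, V0), summed residuals `s`.
.draw_unit_effects <- function(s, m, mu0, V0) {
  prec <- 1 / V0 + m
  stats::rnorm(length(s), (mu0 / V0 + s) / prec, sqrt(1 / prec))
}

# Joint Gaussian draw of all latent factor rows.  R1 = z* - alpha - beta,
# conditional z_i ~ N(A^-1 Theta' r_i, A^-1) with A = I_q + Theta'Theta
# (standard normal prior, unit augmented variance) shared across sites.
.draw_factors <- function(R1, Theta) {
  q <- ncol(Theta); n <- nrow(R1)
  A <- diag(q) + crossprod(Theta)
  S <- chol2inv(chol(A))
  M <- R1 %*% Theta %*% S
  M + matrix(stats::rnorm(n * q), n, q) %*% chol(S)
}

# Draw loadings Theta.  Unconstrained species rows are joint Gaussian
# draws; the first q species rows carry the identifiability constraints
# (theta_jk = 0 for k > j, theta_jj > 0) and are updated by exact scalar
# Gibbs with the diagonal element drawn from its positive-truncated
# conditional.
.draw_loadings <- function(R1, Z, Theta, Pprior) {
  p <- nrow(Theta); q <- ncol(Theta)
  A <- Pprior + crossprod(Z)
  S <- chol2inv(chol(A))
  B <- crossprod(R1, Z)              # p x q, row j = Z' r_j
  free <- if (p > q) (q + 1L):p else integer(0)
  if (length(free)) {
    M <- B[free, , drop = FALSE] %*% S
    Theta[free, ] <- M +
      matrix(stats::rnorm(length(free) * q), length(free), q) %*% chol(S)
  }
  for (j in seq_len(min(q, p))) {
    th <- Theta[j, ]
    th[seq_len(q) > j] <- 0          # structural zeros above the diagonal
    for (k in seq_len(j)) {
      m_k <- (B[j, k] - sum(A[k, -k] * th[-k])) / A[k, k]
      s_k <- sqrt(1 / A[k, k])
      th[k] <- if (k == j) rtnorm(1L, m_k, s_k, lower = 0)
               else stats::rnorm(1L, m_k, s_k)
    }
    Theta[j, ] <- th
  }
  Theta
}

# Cutoff update for the cumulative probit: standard normal prior truncated
# to the interval bounded by the augmented latents of the two adjacent
# classes and the neighbouring cutoffs, preserving the ordering.
.draw_cutoffs <- function(zs, y, cutoffs) {
  Km1 <- length(cutoffs)
  for (l in seq_len(Km1)) {
    lo <- max(c(-Inf, if (l > 1L) cutoffs[l - 1L], zs[y == l]))
    hi <- min(c(Inf, if (l < Km1) cutoffs[l + 1L], zs[y == l + 1L]))
    cutoffs[l] <- rtnorm(1L, 0, 1, lower = lo, upper = hi)
  }
  cutoffs
}

# initial cutoffs: standard-normal quantiles of empirical cumulative class
# frequencies, clamped and forced strictly increasing
.init_cutoffs <- function(y, K) {
  cf <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / length(y)
  co <- stats::qnorm(pmin(pmax(cf, 0.001), 0.999))
  for (l in seq_along(co)[-1L])
    if (co[l] <= co[l - 1L]) co[l] <- co[l - 1L] + 1e-3
  co
}

.init_loadings <- function(p, q) {
  Theta <- matrix(0, p, q)
  diag(Theta)[seq_len(min(p, q))] <- 1
  Theta
}

# Full Gibbs sampler for binary/ordinal families.
.fit_probit <- function(Y, q, prior, control) {
  y <- unclass(Y)
  family <- attr(Y, "family")
  K <- attr(Y, "K")
  n <- nrow(y); p <- ncol(y)
  Vt <- .vtheta_matrix(prior$V_theta, q)
  Pprior <- chol2inv(chol(Vt))

  alpha <- numeric(n); beta <- numeric(p)
  Z <- matrix(0, n, q)
  Theta <- .init_loadings(p, q)
  cutoffs <- if (family == "ordinal") .init_cutoffs(y, K)

  m <- .n_retained(control)
  out <- list(alpha = matrix(NA_real_, m, n), beta = matrix(NA_real_, m, p),
              Z = array(NA_real_, c(m, n, q)),
              Theta = array(NA_real_, c(m, p, q)),
              cutoffs = if (family == "ordinal")
                matrix(NA_real_, m, K - 1L))
  loglik <- numeric(m)
  keep <- 0L

  for (t in seq_len(control$n_iter)) {
    ZT <- tcrossprod(Z, Theta)
    eta <- outer(alpha, beta, `+`) + ZT
    zs <- .draw_zstar(y, eta, family, cutoffs)
    if (family == "ordinal") cutoffs <- .draw_cutoffs(zs, y, cutoffs)

    alpha <- .draw_unit_effects(
      rowSums(zs - ZT) - sum(beta), p, prior$mu_alpha, prior$V_alpha)
    beta <- .draw_unit_effects(
      colSums(zs - ZT) - sum(alpha), n, prior$mu_beta, prior$V_beta)
    R1 <- zs - outer(alpha, beta, `+`)
    Z <- .draw_factors(R1, Theta)
    Theta <- .draw_loadings(R1, Z, Theta, Pprior)

    if (t > control$burnin && (t - control$burnin) %% control$thin == 0L) {
      keep <- keep + 1L
      out$alpha[keep, ] <- alpha
      out$beta[keep, ] <- beta
      out$Z[keep, , ] <- Z
      out$Theta[keep, , ] <- Theta
      if (family == "ordinal") out$cutoffs[keep, ] <- cutoffs
      st <- list(alpha = alpha, beta = beta, Z = Z, Theta = Theta,
                 cutoffs = cutoffs)
      loglik[keep] <- sum(.loglik_matrix(Y, st, family))
    }
  }
  list(draws = out, loglik = loglik, accept = NULL,
       model_family = family)
}
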