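#' Prior hyperparameters for the latent factor model
#'
#' The model places normal priors on the site effects
#' \eqn{\alpha_i \sim N(\mu_\alpha, V_\alpha)} and species effects
#' \eqn{\beta_j \sim N(\mu_\beta, V_\beta)}, a (constrained) normal prior
#' \eqn{\theta_j \sim N(0, V_\theta)} on each species' factor loadings, a
#' standard normal prior on the latent factors \eqn{z_i \sim N(0, I)}, a
#' half-Cauchy prior on the negative binomial overdispersion \eqn{\omega},
#' and independent standard normal priors on the ordinal cutoffs subject to
#' the ordering constraint.
#'
#' @param mu_alpha,V_alpha prior mean and variance of the site effects.
#' @param mu_beta,V_beta prior mean and variance of the species effects.
#' @param V_theta prior covariance of each loading vector: a scalar
#'   (isotropic), a length-`q` vector (diagonal), or a `q x q`
#'   positive-definite matrix.  Default identity.
#' @param omega_scale scale of the half-Cauchy prior on the overdispersion
#'   parameter; default `sqrt(20)`.
#' @return a list of class `"latentord_prior"`.
#' @export
prior_control <- function(mu_alpha = 0, V_alpha = 1, mu_beta = 0,
                          V_beta = 1, V_theta = NULL,
                          omega_scale = sqrt(20)) {
  stopifnot(V_alpha > 0, V_beta > 0, omega_scale > 0)
  structure(list(mu_alpha = mu_alpha, V_alpha = V_alpha,
                 mu_beta = mu_beta, V_beta = V_beta, V_theta = V_theta,
                 omega_scale = omega_scale),
            class = "latentord_prior")
}

# resolve V_theta to a q x q PD matrix and its inverse
.vtheta_matrix <- function(V_theta, q) {
  V <- if (is.null(V_theta)) diag(q)
       else if (is.matrix(V_theta)) V_theta
       else if (length(V_theta) == 1L) diag(q) * V_theta
       else diag(V_theta, q)
  if (!isTRUE(all.equal(V, t(V))) || any(eigen(V, TRUE, TRUE)$values <= 0))
    stop("V_theta must be symmetric positive definite")
  V
}

#' MCMC sampler settings
#'
#' @param n_iter total iterations (default 20000).
#' @param burnin burn-in iterations discarded (default 10000); proposal
#'   scales for the count-family Metropolis updates adapt only during
#'   burn-in and are frozen afterwards.
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed RNG seed; identical settings give bit-identical chains.
#' @param proposal_scale initial random-walk proposal scale for the
#'   count-family Metropolis updates.
#' @param adapt enable Robbins-Monro scale adaptation during burn-in.
#' @param target_accept length-2 vector of target acceptance rates, for
#'   scalar blocks and multivariate (row) blocks respectively.
#' @return a list of class `"latentord_mcmc"`.
#' @export
mcmc_control <- function(n_iter = 20000L, burnin = 10000L, thin = 10L,
                         seed = 1L, proposal_scale = 0.5, adapt = TRUE,
                         target_accept = c(scalar = 0.44, block = 0.234)) {
  n_iter <- as.integer(n_iter); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  stopifnot(n_iter >= 1L, burnin >= 0L, burnin < n_iter, thin >= 1L,
            proposal_scale > 0, all(target_accept > 0 & target_accept < 1))
  if (length(target_accept) == 1L)
    target_accept <- c(scalar = target_accept, block = target_accept)
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 seed = as.integer(seed), proposal_scale = proposal_scale,
                 adapt = isTRUE(adapt), target_accept = target_accept),
            class = "latentord_mcmc")
}

.n_retained <- function(control)
  (control$n_iter - control$burnin) %/% control$thin
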