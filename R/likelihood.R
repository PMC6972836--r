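#' Linear predictor of the latent factor model
#'
#' The model links the mean response for site \eqn{i} and species \eqn{j}
#' through \eqn{g(\mu_{ij}) = \alpha_i + \beta_j + z_i' \theta_j}, where
#' \eqn{\alpha_i} is the site effect, \eqn{\beta_j} the species effect,
#' \eqn{z_i} the q-dimensional latent factors (ordination coordinates of
#' the site) and \eqn{\theta_j} the species' factor loadings.
#'
#' @param state a parameter state: a list with elements `alpha` (length n),
#'   `beta` (length p), `Z` (n x q) and `Theta` (p x q).
#' @param i,j optional site/species indices (1-based).  If omitted the full
#'   n x p matrix of linear predictors is returned.
#' @return scalar \eqn{\eta_{ij}}, or the n x p matrix \eqn{\eta}.
#' @examples
#' st <- list(alpha = 1, beta = -1, Z = matrix(c(1, 2), 1),
#'            Theta = matrix(c(0.5, 0.25), 1))
#' linear_predictor(st, 1, 1)  # 1 - 1 + 1*0.5 + 2*0.25 = 1
#' @export
linear_predictor <- function(state, i = NULL, j = NULL) {
  n <- length(state$alpha); p <- length(state$beta)
  Z <- as.matrix(state$Z); Theta <- as.matrix(state$Theta)
  stopifnot(nrow(Z) == n, nrow(Theta) == p, ncol(Z) == ncol(Theta))
  if (is.null(i) && is.null(j))
    return(outer(state$alpha, state$beta, `+`) + tcrossprod(Z, Theta))
  if (i < 1L || i > n || j < 1L || j > p)
    stop("site or species index out of range")
  state$alpha[i] + state$beta[j] + sum(Z[i, ] * Theta[j, ])
}

#' Mean response (inverse link) for each family
#'
#' Binary: \eqn{\mu = \Phi(\eta)} (probit).  Count (Poisson or negative
#' binomial): \eqn{\mu = \exp(\eta)} (log link).  Ordinal: the K class
#' probabilities of the cumulative probit model,
#' \eqn{P(y = l) = \Phi(c_l - \eta) - \Phi(c_{l-1} - \eta)} with
#' \eqn{c_0 = -\infty}, \eqn{c_K = +\infty}.
#'
#' @param eta linear predictor (vectorised for binary/count; scalar for
#'   ordinal).
#' @param family `"binary"`, `"count"` or `"ordinal"`.
#' @param cutoffs strictly increasing cutoffs `c_1 < ... < c_{K-1}`
#'   (ordinal only).
#' @return mean(s), or for ordinal a vector of K probabilities summing to 1.
#' @examples
#' mean_response(0, "binary")                      # 0.5
#' mean_response(0, "ordinal", cutoffs = c(-1, 1)) # three probabilities
#' @export
mean_response <- function(eta, family = c("binary", "count", "ordinal"),
                          cutoffs = NULL) {
  family <- match.arg(family)
  stopifnot(all(is.finite(eta)))
  switch(family,
    binary = stats::pnorm(eta),
    count = exp(eta),
    ordinal = {
      if (is.null(cutoffs) || any(diff(cutoffs) <= 0))
        stop("ordinal cutoffs must be strictly increasing")
      cum <- stats::pnorm(c(cutoffs - eta, Inf))
      diff(c(0, cum))
    })
}

#' Negative binomial variance
#'
#' Under the mean/overdispersion parameterisation used throughout the
#' package, a count with mean \eqn{\mu} and overdispersion \eqn{\omega} has
#' variance \eqn{\mu + \omega \mu^2}; \eqn{\omega = 0} recovers the Poisson
#' mean-variance equality.
#'
#' @param mu mean(s), non-negative.
#' @param omega overdispersion, non-negative.
#' @return the variance \eqn{\mu + \omega \mu^2}.
#' @export
nb_variance <- function(mu, omega) {
  if (any(mu < 0) || any(omega < 0))
    stop("mu and omega must be non-negative")
  mu + omega * mu^2
}

# log-density matrix of Y under a state; Y a community_matrix,
# state as in linear_predictor plus omega/cutoffs where relevant.
.loglik_matrix <- function(Y, state, family = attr(Y, "family")) {
  eta <- linear_predictor(state)
  y <- unclass(Y)
  switch(family,
    binary = stats::dbinom(y, 1L, stats::pnorm(eta), log = TRUE),
    poisson = stats::dpois(y, exp(eta), log = TRUE),
    negbinomial = stats::dnbinom(y, size = 1 / state$omega, mu = exp(eta),
                                 log = TRUE),
    ordinal = {
      co <- state$cutoffs
      if (any(diff(co) <= 0)) stop("cutoffs must be strictly increasing")
      lo <- c(-Inf, co)[y]; hi <- c(co, Inf)[y]
      log(stats::pnorm(hi - eta) - stats::pnorm(lo - eta))
    },
    stop("unknown family '", family, "'"))
}

#' Log-likelihood of a community matrix under a parameter state
#'
#' Sums the log probability mass of every cell \eqn{y_{ij}} under the
#' family's observation distribution evaluated at the model mean.
#'
#' @param Y a [community_matrix()].
#' @param state parameter state (see [linear_predictor()]); count states
#'   need `omega` for the negative binomial, ordinal states need `cutoffs`.
#' @param family observation model: `"binary"`, `"poisson"`,
#'   `"negbinomial"` or `"ordinal"`.  Must be compatible with the data
#'   family of `Y`.
#' @return scalar log-likelihood.
#' @export
community_loglik <- function(Y, state, family = NULL) {
  dfam <- attr(Y, "family")
  if (is.null(family))
    family <- switch(dfam, binary = "binary", count = "poisson",
                     ordinal = "ordinal")
  ok <- switch(family, binary = "binary", poisson = , negbinomial = "count",
               ordinal = "ordinal")
  if (!identical(dfam, ok))
    stop(sprintf("family mismatch: '%s' model for '%s' data", family, dfam))
  sum(.loglik_matrix(Y, state, family))
}

#' Deviance information criterion of a fitted model
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - D(\bar\theta)}, where
#' \eqn{D = -2 \log L} is the deviance, \eqn{\bar D} its posterior mean
#' over the retained draws and \eqn{D(\bar\theta)} the deviance at the
#' posterior mean of the parameters.  Used to compare Poisson and negative
#' binomial fits to the same counts.
#'
#' @param fit a fitted [latentord()] model.
#' @return scalar DIC.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "latentord"))
  m <- length(fit$loglik)
  if (m < 1L) stop("empty chains")
  dbar <- mean(-2 * fit$loglik)
  st <- .posterior_mean_state(fit)
  dhat <- -2 * sum(.loglik_matrix(fit$y, st, fit$family))
  dbar + (dbar - dhat)
}

# posterior means of all parameters as a single state
.posterior_mean_state <- function(fit) {
  d <- fit$draws
  st <- list(alpha = colMeans(d$alpha), beta = colMeans(d$beta),
             Z = apply(d$Z, c(2, 3), mean),
             Theta = apply(d$Theta, c(2, 3), mean))
  if (!is.null(d$omega)) st$omega <- mean(d$omega)
  if (!is.null(d$cutoffs))
    st$cutoffs <- if (is.matrix(d$cutoffs)) colMeans(d$cutoffs)
                  else mean(d$cutoffs)
  st
}
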