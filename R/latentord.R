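#' Bayesian latent factor model for unconstrained ordination
#'
#' Fits the latent factor model
#' \eqn{g(\mu_{ij}) = \alpha_i + \beta_j + z_i' \theta_j}
#' to a site-by-species community matrix by MCMC, where the
#' \eqn{q}-dimensional latent factors \eqn{z_i} are the ordination
#' coordinates of the sites.  Four observation models are available:
#' probit for presence/absence, Poisson and negative binomial (log link)
#' for counts, and cumulative probit for ordinal cover classes.  For
#' identifiability the loading matrix is constrained to have zero
#' upper triangle and positive diagonal in its first \eqn{q} rows
#' (\eqn{\theta_{11} > 0}, \eqn{\theta_{12} = 0}, \eqn{\theta_{22} > 0}
#' for \eqn{q = 2}), enforced inside the sampler via truncated-normal
#' priors on the diagonal elements.
#'
#' Binary and ordinal families are sampled by an exact Gibbs scheme using
#' the latent-normal data augmentation; count families use adaptive
#' random-walk Metropolis-within-Gibbs (see the package vignette for
#' details).  Chains are bit-reproducible given the seed in `control`.
#'
#' @param y a [community_matrix()], or a plain matrix (then `family` and
#'   `K` describe it).
#' @param family observation model: `"binary"`, `"poisson"`,
#'   `"negbinomial"` or `"ordinal"`.  Defaults to `"binary"`,
#'   `"poisson"` or `"ordinal"` according to the data family of `y`.
#' @param q latent dimension (default 2, the usual choice for ordination).
#' @param K number of ordinal classes (ordinal data in plain-matrix form).
#' @param prior a [prior_control()] list.
#' @param control an [mcmc_control()] list.
#' @return An object of class `"latentord"` with components `draws` (lists
#'   of retained draws: `alpha` m x n, `beta` m x p, `Z` m x n x q,
#'   `Theta` m x p x q, plus `omega` / `cutoffs` where applicable),
#'   `loglik` (log-likelihood at each retained draw), `accept`
#'   (Metropolis acceptance rates, count families), and the inputs.
#' @examples
#' sim <- sim_community(ord_design("binary", n = 12, p = 8, seed = 1))
#' fit <- latentord(sim$y, control = mcmc_control(500, 250, 2, seed = 1))
#' fit
#' @seealso [hpd_widths()], [anchor_factors()], [plot_ordination()], [dic()]
#' @export
latentord <- function(y, family = NULL, q = 2L, K = NULL,
                      prior = prior_control(), control = mcmc_control()) {
  cl <- match.call()
  if (!inherits(y, "community_matrix")) {
    dfam <- switch(family %||% "binary", binary = "binary",
                   poisson = , negbinomial = "count", ordinal = "ordinal")
    y <- community_matrix(y, family = dfam, K = K)
  }
  dfam <- attr(y, "family")
  if (is.null(family))
    family <- switch(dfam, binary = "binary", count = "poisson",
                     ordinal = "ordinal")
  family <- match.arg(family,
                      c("binary", "poisson", "negbinomial", "ordinal"))
  need <- switch(family, binary = "binary", poisson = , negbinomial =
                 "count", ordinal = "ordinal")
  if (!identical(need, dfam))
    stop(sprintf("'%s' model cannot be fit to '%s' data", family, dfam))
  q <- as.integer(q)
  stopifnot(q >= 1L)
  if (.n_retained(control) < 1L)
    stop("settings retain no draws; increase n_iter or reduce burnin/thin")

  set.seed(control$seed)
  res <- if (family %in% c("binary", "ordinal"))
    .fit_probit(y, q, prior, control)
  else
    .fit_count(y, q, family, prior, control)
  if (any(!is.finite(res$loglik)))
    warning("non-finite log-likelihood at some retained draws")

  structure(list(call = cl, y = y, family = family, n = nrow(y),
                 p = ncol(y), q = q, K = attr(y, "K"),
                 prior = prior, control = control, draws = res$draws,
                 loglik = res$loglik, accept = res$accept),
            class = "latentord")
}

#' @export
print.latentord <- function(x, ...) {
  cat(sprintf(
    "Bayesian latent factor ordination (%s family)\n%d sites x %d species, q = %d latent dimensions\n%d retained draws (n_iter = %d, burnin = %d, thin = %d, seed = %d)\n",
    x$family, x$n, x$p, x$q, length(x$loglik), x$control$n_iter,
    x$control$burnin, x$control$thin, x$control$seed))
  if (!is.null(x$accept))
    cat("Metropolis acceptance rates:",
        paste(sprintf("%s %.2f", names(x$accept), x$accept),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.latentord <- function(object, ...) {
  st <- .posterior_mean_state(object)
  names(st$alpha) <- rownames(object$y)
  names(st$beta) <- colnames(object$y)
  dimnames(st$Z) <- list(rownames(object$y),
                         paste0("LF", seq_len(object$q)))
  dimnames(st$Theta) <- list(colnames(object$y),
                             paste0("LF", seq_len(object$q)))
  st
}

#' @export
summary.latentord <- function(object, level = 0.95, ...) {
  hw <- hpd_widths(object, level = level)
  di <- mcmc_diagnostics(object)
  out <- list(fit = object, hpd = hw, diagnostics = di, level = level,
              dic = dic(object))
  class(out) <- "summary.latentord"
  out
}

#' @export
print.summary.latentord <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nMean %d%% HPD width of the latent factors: %.3f\n",
              round(100 * x$level), x$hpd$mean_width))
  cat(sprintf("DIC: %.1f\n", x$dic))
  rh <- x$diagnostics$rhat
  cat(sprintf("Split-Rhat: max %.3f (median %.3f); min ESS %.0f\n",
              max(rh, na.rm = TRUE), stats::median(rh, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' @export
predict.latentord <- function(object, type = c("response", "link"), ...) {
  type <- match.arg(type)
  st <- .posterior_mean_state(object)
  eta <- linear_predictor(st)
  dimnames(eta) <- dimnames(object$y)
  if (type == "link") return(eta)
  switch(object$family,
    binary = stats::pnorm(eta),
    poisson = , negbinomial = exp(eta),
    ordinal = {
      pr <- vapply(eta, function(e)
        sum(seq_len(object$K) *
              mean_response(e, "ordinal", cutoffs = st$cutoffs)),
        numeric(1))
      dim(pr) <- dim(eta); dimnames(pr) <- dimnames(eta)
      pr
    })
}

#' @export
residuals.latentord <- function(object,
                                type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- predict(object, type = "response")
  r <- unclass(object$y) - mu
  if (type == "pearson") {
    v <- switch(object$family,
      binary = mu * (1 - mu),
      poisson = mu,
      negbinomial = nb_variance(mu, mean(object$draws$omega)),
      ordinal = return(r))  # class-mean residuals left unscaled
    r <- r / sqrt(v)
  }
  r
}

#' Posterior predictive simulation from a fitted ordination model
#'
#' Draws `nsim` replicate community matrices, each generated from one
#' retained posterior draw of the parameters.
#'
#' @param object a fitted [latentord()] model.
#' @param nsim number of replicate matrices.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `nsim` matrices.
#' @export
simulate.latentord <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(object$loglik)
  idx <- sample.int(m, nsim, replace = nsim > m)
  lapply(idx, function(t) {
    st <- .state_at(object, t)
    eta <- linear_predictor(st)
    yr <- switch(object$family,
      binary = (matrix(stats::rnorm(length(eta)), nrow(eta)) + eta > 0) + 0,
      poisson = matrix(stats::rpois(length(eta), exp(eta)), nrow(eta)),
      negbinomial = matrix(stats::rnbinom(length(eta),
        size = 1 / st$omega, mu = exp(eta)), nrow(eta)),
      ordinal = {
        zs <- matrix(stats::rnorm(length(eta)), nrow(eta)) + eta
        matrix(findInterval(zs, st$cutoffs) + 1L, nrow(eta))
      })
    dimnames(yr) <- dimnames(object$y)
    yr
  })
}

# parameter state at one retained draw
.state_at <- function(fit, t) {
  d <- fit$draws
  st <- list(alpha = d$alpha[t, ], beta = d$beta[t, ],
             Z = d$Z[t, , , drop = FALSE][1, , , drop = TRUE],
             Theta = d$Theta[t, , , drop = FALSE][1, , , drop = TRUE])
  if (fit$q == 1L) {
    st$Z <- matrix(st$Z, ncol = 1L)
    st$Theta <- matrix(st$Theta, ncol = 1L)
  }
  if (!is.null(d$omega)) st$omega <- d$omega[t]
  if (!is.null(d$cutoffs)) st$cutoffs <- d$cutoffs[t, ]
  st
}

#' @export
plot.latentord <- function(x, mode = "points", ...) {
  plot_ordination(x, mode = mode, ...)
}
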