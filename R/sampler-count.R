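# Metropolis-within-Gibbs sampler for the count families (Poisson and
# negative binomial, log link).  The count conditionals are non-conjugate,
# so each parameter block is updated by an adaptive random-walk Metropolis
# step; blocks of the same kind (site effects, species effects, factor
# rows, loading rows) are conditionally independent given the rest of the
# state.  Proposal scales adapt by Robbins-Monro during burn-in only
# (targets 0.44 for scalar blocks, 0.234 for multivariate rows) and are
# frozen afterwards, preserving detailed balance for the retained draws.
# The sweep loop is compiled (src/count_sampler.cpp) and uses R's RNG, so
# chains are bit-reproducible under the control seed.
#
# `update` switches individual block types on/off and `init` overrides the
# default initial state; both exist so single conditionals can be
# validated in isolation against numerical oracles.
.fit_count <- function(Y, q, family, prior, control,
                       update = c(alpha = TRUE, beta = TRUE, Z = TRUE,
                                  Theta = TRUE, omega = TRUE),
                       init = NULL) {
  y <- unclass(Y)
  Vt <- .vtheta_matrix(prior$V_theta, q)
  pr <- list(mu_alpha = prior$mu_alpha, V_alpha = prior$V_alpha,
             mu_beta = prior$mu_beta, V_beta = prior$V_beta,
             P_theta = chol2inv(chol(Vt)),
             omega_scale = prior$omega_scale)
  opts <- as.list(update)
  if (!is.null(init)) opts$init <- init
  res <- .fit_count_cpp(y, q, family == "negbinomial", pr,
                        control$n_iter, control$burnin, control$thin,
                        control$proposal_scale, control$adapt,
                        control$target_accept[[1L]],
                        control$target_accept[[2L]], opts)
  m <- nrow(res$alpha); n <- nrow(y); p <- ncol(y)
  draws <- list(alpha = res$alpha, beta = res$beta,
                Z = array(as.vector(res$Z), c(m, n, q)),
                Theta = array(as.vector(res$Theta), c(m, p, q)),
                omega = if (family == "negbinomial") res$omega)
  rates <- res$accept
  if (family != "negbinomial") rates <- rates[names(rates) != "omega"]
  rates <- rates[unlist(update[names(rates)])]
  out <- rates < 0.1 | rates > 0.7
  if (length(rates) && any(out))
    warning("post-burn-in acceptance rate outside [0.1, 0.7] for block(s): ",
            paste(names(rates)[out], collapse = ", "))
  list(draws = draws, loglik = res$loglik, accept = rates,
       model_family = family)
}
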