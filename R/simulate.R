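#' Simulation design for a planned ordination study
#'
#' Describes the generative model used by [sim_community()] and the
#' study-design tool [hpd_width_design()]: site effects
#' \eqn{\alpha_i \sim N(\mu_\alpha, \sigma_\alpha^2)}, species effects
#' \eqn{\beta_j \sim N(\mu_\beta, \sigma_\beta^2)}, latent factors and
#' loadings elementwise standard normal (loadings with the identifiability
#' constraints applied: zero upper triangle, positive diagonal), and
#' family-specific response generation from the linear predictor
#' \eqn{\eta_{ij} = \alpha_i + \beta_j + z_i'\theta_j}.  Optionally the
#' species pool is augmented with `p_rare` rare species whose effects are
#' drawn from \eqn{N(\mu_{rare}, \sigma_{rare}^2)} (default mean -4, SD
#' 0.5): strongly negative effects that make occurrences sparse.
#'
#' @param family the sampling distribution of the planned study:
#'   `"binary"`, `"poisson"`, `"negbinomial"` or `"ordinal"`.  Responses
#'   are generated from this distribution and [hpd_width_design()] fits
#'   the matching model.
#' @param n,p numbers of sites and of common species.
#' @param mu_alpha,sigma_alpha site-effect mean and SD (defaults 0, 1).
#' @param mu_beta,sigma_beta species-effect mean and SD (defaults 0, 1).
#' @param q latent dimension (default 2).
#' @param p_rare,mu_rare,sigma_rare optional rare-species block appended
#'   after the `p` common species.
#' @param omega generative overdispersion for `"negbinomial"` designs
#'   (default 1, unit overdispersion).
#' @param K ordinal classes; generation cuts a unit-variance latent normal
#'   at `cutoffs` (default the standard-normal `K`-tiles).
#' @param cutoffs generation cutoffs for ordinal designs.
#' @param reps replicate count for design summaries (default 50).
#' @param seed base RNG seed; replicate r uses a stream derived from
#'   `(seed, r)`.
#' @return a list of class `"ord_design"`.
#' @export
ord_design <- function(family = c("binary", "poisson", "negbinomial",
                                  "ordinal"),
                       n, p, mu_alpha = 0, sigma_alpha = 1, mu_beta = 0,
                       sigma_beta = 1, q = 2L, p_rare = 0L, mu_rare = -4,
                       sigma_rare = 0.5, omega = 1, K = NULL,
                       cutoffs = NULL, reps = 50L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(n >= 2, p >= 1, p + p_rare >= 2, sigma_alpha >= 0,
            sigma_beta >= 0, sigma_rare >= 0, q >= 1, reps >= 1,
            omega > 0)
  if (family == "ordinal") {
    if (is.null(K) && is.null(cutoffs))
      stop("ordinal designs need K or cutoffs")
    if (is.null(cutoffs))
      cutoffs <- stats::qnorm(seq_len(K - 1L) / K)
    if (is.null(K)) K <- length(cutoffs) + 1L
    stopifnot(all(diff(cutoffs) > 0), K >= 2L)
  }
  structure(list(family = family, n = as.integer(n), p = as.integer(p),
                 mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 mu_beta = mu_beta, sigma_beta = sigma_beta,
                 q = as.integer(q), p_rare = as.integer(p_rare),
                 mu_rare = mu_rare, sigma_rare = sigma_rare,
                 omega = omega, K = K,
                 cutoffs = cutoffs, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "ord_design")
}

# independent, reproducible seed for one (seed, replicate) pair
.replicate_seed <- function(seed, replicate)
  (as.numeric(seed) * 48271 + replicate * 69621) %% 2147483629

# draw one full true parameter state from a design
.draw_true_state <- function(design) {
  if (is.null(design$omega)) design$omega <- 1
  n <- design$n; p <- design$p + design$p_rare; q <- design$q
  beta <- stats::rnorm(design$p, design$mu_beta, design$sigma_beta)
  if (design$p_rare > 0L)
    beta <- c(beta,
              stats::rnorm(design$p_rare, design$mu_rare,
                           design$sigma_rare))
  Theta <- matrix(stats::rnorm(p * q), p, q)
  for (j in seq_len(min(q, p))) {
    Theta[j, seq_len(q) > j] <- 0
    Theta[j, j] <- abs(Theta[j, j])  # half-normal = positive-truncated N(0,1)
  }
  st <- list(alpha = stats::rnorm(n, design$mu_alpha, design$sigma_alpha),
             beta = beta,
             Z = matrix(stats::rnorm(n * q), n, q),
             Theta = Theta)
  if (design$family == "ordinal") st$cutoffs <- design$cutoffs
  if (design$family == "negbinomial") st$omega <- design$omega
  st
}

#' Generate one synthetic community under a design
#'
#' Draws a full true parameter state from the design's generative model
#' and simulates the response matrix: binary via the probit latent normal,
#' counts as Poisson at \eqn{\exp(\eta)}, ordinal by cutting a
#' unit-variance latent normal at the design cutoffs.  Deterministic for a
#' given `(design$seed, replicate)` pair; distinct replicates use
#' independent streams.
#'
#' @param design an [ord_design()].
#' @param replicate replicate index (default 1).
#' @return list with `y` (a [community_matrix()]) and `truth` (the
#'   generating parameter state, rare species appended last).
#' @export
sim_community <- function(design, replicate = 1L) {
  stopifnot(inherits(design, "ord_design"))
  set.seed(.replicate_seed(design$seed, replicate))
  st <- .draw_true_state(design)
  eta <- linear_predictor(st)
  n <- design$n; ptot <- design$p + design$p_rare
  yv <- switch(design$family,
    binary = (stats::rnorm(length(eta)) + eta > 0) + 0,
    poisson = stats::rpois(length(eta), exp(eta)),
    negbinomial = stats::rnbinom(length(eta), size = 1 / st$omega,
                                 mu = exp(eta)),
    ordinal = findInterval(stats::rnorm(length(eta)) + eta,
                           design$cutoffs) + 1)
  y <- matrix(yv, n, ptot)
  fam <- switch(design$family, binary = "binary",
                poisson = , negbinomial = "count", ordinal = "ordinal")
  spl <- c(paste0("sp", seq_len(design$p)),
           if (design$p_rare > 0L) paste0("rare", seq_len(design$p_rare)))
  list(y = community_matrix(y, family = fam, K = design$K,
                            species_labels = spl),
       truth = st)
}

#' Occurrence analytics for a rare-species design (Monte Carlo)
#'
#' Estimates, for the rare-species block of a binary design, (a) the
#' marginal probability that a rare species is present at a site and (b)
#' the probability that a rare species is absent from all `n` sites of a
#' survey, by simulating species (effect + loadings) and sites (effect +
#' latent factors) from the design's generative model.
#'
#' @param design a binary [ord_design()] with `p_rare > 0` (a design with
#'   `p_rare = 0` summarises its common species instead).
#' @param mc_draws number of Monte Carlo species draws (default 1e5).
#' @param seed RNG seed.
#' @return list with `occurrence` and `zero_fraction`, each a list of
#'   `estimate` and `se`.
#' @export
occurrence_summaries <- function(design, mc_draws = 1e5, seed = 1L) {
  stopifnot(inherits(design, "ord_design"), design$family == "binary")
  rare <- design$p_rare > 0L
  mu_b <- if (rare) design$mu_rare else design$mu_beta
  sd_b <- if (rare) design$sigma_rare else design$sigma_beta
  set.seed(seed)
  n <- design$n; q <- design$q
  M <- as.integer(mc_draws)
  # species-level draws
  beta <- stats::rnorm(M, mu_b, sd_b)
  Theta <- matrix(stats::rnorm(M * q), M, q)
  # site-level draws, independent per species
  alpha <- matrix(stats::rnorm(M * n, design$mu_alpha,
                               design$sigma_alpha), M, n)
  npres <- integer(M)
  for (i in seq_len(n)) {
    Zi <- matrix(stats::rnorm(M * q), M, q)
    eta <- alpha[, i] + beta + rowSums(Zi * Theta)
    npres <- npres + (stats::rnorm(M) + eta > 0)
  }
  occ <- sum(npres) / (M * n)
  zf <- mean(npres == 0L)
  list(occurrence = list(estimate = occ,
                         se = stats::sd(npres / n) / sqrt(M)),
       zero_fraction = list(estimate = zf,
                            se = sqrt(zf * (1 - zf) / M)),
       mc_draws = M, n = n)
}

#' Expected HPD width for a planned ordination study
#'
#' The study-design tool: for every requested (sites, species) cell it
#' simulates `design$reps` replicate communities from the generative
#' model, fits the latent factor model to each and averages the 95% (or
#' `level`) HPD widths of the latent factors over sites, dimensions and
#' replicates.  Population parameters (`mu_alpha`, `sigma_alpha`,
#' `mu_beta`, `sigma_beta`) can come from a pilot study via
#' [estimate_population_params()].  Count designs generate Poisson counts;
#' the fitted model is `design$family` (`"negbinomial"` fits the NB model
#' to those counts, matching the usual abundance analysis).
#'
#' @param design an [ord_design()]; its `n`, `p` are the defaults for the
#'   grid.
#' @param n_grid,p_grid site/species counts to cross (vectors); defaults
#'   `design$n` / `design$p`.  Rare species (`design$p_rare`) are added on
#'   top of each `p_grid` value.
#' @param settings an [mcmc_control()] used for every fit.  Default: 5000
#'   iterations (half burn-in, thin 5) for the conjugate binary/ordinal
#'   Gibbs sampler; 30000 iterations (half burn-in, thin 15) for the
#'   count-family Metropolis sampler, whose rotation-aligned width
#'   summaries need longer runs to stabilise.
#' @param level HPD probability content (default 0.95).
#' @param verbose print one line per cell.
#' @return data frame with one row per (n, p) cell: `n`, `p`, `p_rare`,
#'   `family`, `mean_width`, `sd_width` (across replicates), `reps`,
#'   `failed` (replicates whose fit errored; recorded, not fatal).
#' @export
hpd_width_design <- function(design, n_grid = NULL, p_grid = NULL,
                             settings = NULL, level = 0.95,
                             verbose = FALSE) {
  stopifnot(inherits(design, "ord_design"))
  if (is.null(settings))
    settings <- if (design$family %in% c("poisson", "negbinomial"))
      mcmc_control(30000L, 15000L, 15L) else mcmc_control(5000L, 2500L, 5L)
  n_grid <- as.integer(n_grid %||% design$n)
  p_grid <- as.integer(p_grid %||% design$p)
  grid <- expand.grid(n = n_grid, p = p_grid)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    dg <- design
    dg$n <- grid$n[g]; dg$p <- grid$p[g]
    ws <- rep(NA_real_, design$reps)
    for (r in seq_len(design$reps)) {
      ws[r] <- tryCatch({
        sim <- sim_community(dg, replicate = r)
        ctl <- settings
        ctl$seed <- .replicate_seed(dg$seed + 104729L * g, r)
        fit <- latentord(sim$y, family = dg$family, q = dg$q,
                         control = ctl)
        hpd_widths(fit, level = level)$mean_width
      }, error = function(e) NA_real_)
    }
    ok <- !is.na(ws)
    out[[g]] <- data.frame(
      n = dg$n, p = dg$p, p_rare = dg$p_rare, family = dg$family,
      mean_width = mean(ws[ok]),
      sd_width = if (sum(ok) > 1L) stats::sd(ws[ok]) else NA_real_,
      reps = sum(ok), failed = sum(!ok))
    if (verbose)
      message(sprintf("n=%d p=%d: mean width %.3f (sd %.3f, %d reps)",
                      dg$n, dg$p, out[[g]]$mean_width, out[[g]]$sd_width,
                      sum(ok)))
  }
  do.call(rbind, out)
}

#' Plug-in population parameters from a fitted model
#'
#' Computes the posterior mean of every site effect \eqn{\alpha_i} and
#' species effect \eqn{\beta_j} and returns their across-unit mean and
#' sample SD (denominator n-1) — the plug-in values of
#' \eqn{(\mu_\alpha, \sigma_\alpha, \mu_\beta, \sigma_\beta)} to feed a
#' design simulation for a comparable study.
#'
#' @param fit a fitted [latentord()] model.
#' @return named numeric vector `mu_alpha`, `sd_alpha`, `mu_beta`,
#'   `sd_beta`.
#' @export
estimate_population_params <- function(fit) {
  stopifnot(inherits(fit, "latentord"))
  a <- colMeans(fit$draws$alpha)
  b <- colMeans(fit$draws$beta)
  c(mu_alpha = mean(a), sd_alpha = stats::sd(a),
    mu_beta = mean(b), sd_beta = stats::sd(b))
}
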