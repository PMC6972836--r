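#' Highest posterior density interval of a sample
#'
#' Minimal-width interval containing a fraction `level` of the draws
#' (Chen-Shao sorted-window algorithm): among all windows of
#' \eqn{\lceil level \cdot m \rceil} consecutive order statistics the
#' narrowest is returned; ties are broken by the smallest lower endpoint.
#' The single minimal interval is always reported (no disjoint HPD sets).
#'
#' @param x numeric vector of at least 100 posterior draws.
#' @param level probability content, in (0,1); default 0.95.
#' @return numeric `c(lower, upper)`.
#' @examples
#' hpd_interval(0:99, 0.95)  # c(0, 94)
#' @export
hpd_interval <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  m <- length(x)
  if (m < 100L) stop("need at least 100 draws for an HPD interval")
  x <- sort(x)
  k <- ceiling(level * m)
  lo <- x[seq_len(m - k + 1L)]
  hi <- x[k:m]
  i <- which.min(hi - lo)  # which.min takes the first (smallest lower end)
  c(lower = lo[i], upper = hi[i])
}

#' Align latent factor draws by orthogonal Procrustes rotation
#'
#' The loading constraints (zero upper triangle, positive diagonal)
#' identify the rotation of the ordination only through the first `q`
#' species' loadings.  When `p` is much larger than `q` that tie is weak:
#' the posterior retains a near-flat rotational ridge and the sampled site
#' configurations slowly spin around the origin, which inflates raw
#' per-coordinate summaries without reflecting any positional uncertainty.
#' This function removes the ambiguity by rotating every retained draw of
#' the site configuration onto the posterior-mean configuration
#' (orthogonal Procrustes, reflections allowed; the reference mean is
#' re-estimated once from the aligned draws).  Translation is untouched —
#' alignment is orthogonal to [anchor_factors()].  Summaries of aligned
#' draws are stable in chain length; for small `p` where the constraint
#' already pins the rotation, alignment changes essentially nothing.
#'
#' @param fit a fitted [latentord()] model or an m x n x q array of latent
#'   factor draws.
#' @param iterations alignment refinement passes (default 2).
#' @return an m x n x q array of aligned draws.
#' @export
align_factors <- function(fit, iterations = 2L) {
  Z <- if (inherits(fit, "latentord")) fit$draws$Z else fit
  stopifnot(length(dim(Z)) == 3L)
  m <- dim(Z)[1L]
  ref <- apply(Z, c(2, 3), mean)
  al <- Z
  for (it in seq_len(iterations)) {
    for (t in seq_len(m)) {
      s <- svd(crossprod(Z[t, , , drop = TRUE], ref))
      al[t, , ] <- Z[t, , , drop = TRUE] %*% tcrossprod(s$u, s$v)
    }
    ref <- apply(al, c(2, 3), mean)
  }
  al
}

#' Per-coordinate HPD intervals and widths of the latent factors
#'
#' Applies [hpd_interval()] to every latent factor marginal
#' \eqn{z_{ik}} and reports the interval widths together with their grand
#' mean over all `n * q` coordinates — the headline uncertainty summary of
#' an ordination fit.  By default the draws are first rotation-aligned
#' (see [align_factors()]) so the summary measures positional rather than
#' rotational uncertainty and does not depend on chain length; widths are
#' computed on unanchored draws unless `anchor_site` is given.
#'
#' @param fit a fitted [latentord()] model, or an m x n x q array of
#'   latent factor draws.
#' @param level probability content (default 0.95).
#' @param align rotation-align the draws first (default `TRUE`).
#' @param anchor_site optional site index passed to [anchor_factors()]
#'   (after alignment) to summarise positions relative to a reference
#'   site.
#' @return an object of class `"hpd_summary"`: list with `intervals`
#'   (data frame: site, dimension, lower, upper, width), `widths`
#'   (n x q matrix), `mean_width` and `level`.
#' @export
hpd_widths <- function(fit, level = 0.95, align = TRUE,
                       anchor_site = NULL) {
  Z <- if (inherits(fit, "latentord")) fit$draws$Z else fit
  stopifnot(length(dim(Z)) == 3L)
  if (align) Z <- align_factors(Z)
  if (!is.null(anchor_site)) Z <- anchor_factors(Z, anchor_site)
  n <- dim(Z)[2L]; q <- dim(Z)[3L]
  sites <- if (inherits(fit, "latentord")) rownames(fit$y)
           else paste0("site", seq_len(n))
  ints <- expand.grid(site = sites, dimension = seq_len(q),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bounds <- t(vapply(seq_len(nrow(ints)),
    function(r) {
      i <- (r - 1L) %% n + 1L; k <- (r - 1L) %/% n + 1L
      hpd_interval(Z[, i, k], level)
    }, numeric(2)))
  ints$lower <- bounds[, 1L]
  ints$upper <- bounds[, 2L]
  ints$width <- ints$upper - ints$lower
  widths <- matrix(ints$width, n, q,
                   dimnames = list(sites, paste0("LF", seq_len(q))))
  structure(list(intervals = ints, widths = widths,
                 mean_width = mean(ints$width), level = level),
            class = "hpd_summary")
}

#' @export
print.hpd_summary <- function(x, ...) {
  cat(sprintf("%d%% HPD intervals for %d site x %d dimension latent factors\n",
              round(100 * x$level), nrow(x$widths), ncol(x$widths)))
  cat(sprintf("Mean width: %.3f\n", x$mean_width))
  invisible(x)
}

#' Export an HPD summary as a delimited table
#'
#' @param x an `"hpd_summary"` from [hpd_widths()].
#' @param path output file path.
#' @param sep delimiter (default comma).
#' @export
write_hpd <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "hpd_summary"))
  utils::write.table(x$intervals, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Anchor latent factor draws at a reference site
#'
#' Ordination is about relative, not absolute, positions.  Anchoring
#' translates every retained draw so the chosen reference site sits
#' exactly at the origin: \eqn{\tilde z_i^{(t)} = z_i^{(t)} -
#' z_{anchor}^{(t)}}.  This removes common shifts of the whole point
#' cloud, so summaries of anchored draws measure uncertainty in positions
#' relative to the anchor.
#'
#' @param fit a fitted [latentord()] model (returned with its `Z` draws
#'   replaced) or an m x n x q array of latent factor draws (returned as
#'   an array).
#' @param anchor_site site index (1-based) or site label.
#' @return same shape as the input, with anchored `Z` draws.
#' @export
anchor_factors <- function(fit, anchor_site) {
  is_fit <- inherits(fit, "latentord")
  Z <- if (is_fit) fit$draws$Z else fit
  stopifnot(length(dim(Z)) == 3L)
  n <- dim(Z)[2L]
  if (is.character(anchor_site)) {
    anchor_site <- match(anchor_site, if (is_fit) rownames(fit$y))
    if (is.na(anchor_site)) stop("unknown anchor site label")
  }
  if (anchor_site < 1L || anchor_site > n)
    stop("anchor site index out of range")
  ref <- Z[, anchor_site, , drop = FALSE]  # m x 1 x q
  Z <- Z - ref[, rep(1L, n), , drop = FALSE]
  if (is_fit) { fit$draws$Z <- Z; fit } else Z
}

#' Two-dimensional HPD region of a posterior point cloud
#'
#' Computes a closed region holding a fraction `level` of the draws of one
#' site's two latent factors, either as a kernel density contour
#' (`method = "kde"`, Gaussian kernel, normal-reference bandwidth; the
#' default, since posterior clouds are often visibly non-elliptical) or as
#' the normal-theory ellipse at the \eqn{\chi^2_2(level)} radius
#' (`method = "normal_ellipse"`, faster).
#'
#' @param draws m x 2 matrix of posterior draws (m >= 100).
#' @param level probability content (default 0.95).
#' @param method `"kde"` or `"normal_ellipse"`.
#' @param grid_n KDE grid resolution per axis.
#' @return list with `method`, `level`, `boundary` (list of closed polygon
#'   matrices; one ellipse polygon for the normal method), `fraction` (the
#'   realised fraction of draws enclosed) and, for the ellipse, `center`,
#'   `cov` and `area`.
#' @export
hpd_region_2d <- function(draws, level = 0.95,
                          method = c("kde", "normal_ellipse"),
                          grid_n = 101L) {
  method <- match.arg(method)
  draws <- as.matrix(draws)
  stopifnot(ncol(draws) == 2L, nrow(draws) >= 100L, level > 0, level < 1)
  S <- stats::cov(draws)
  if (rcond(S) < 1e-10) {
    warning("rank-deficient draws; falling back to an interval product")
    b1 <- hpd_interval(draws[, 1L], level)
    b2 <- hpd_interval(draws[, 2L], level)
    poly <- cbind(x = b1[c(1, 2, 2, 1, 1)], y = b2[c(1, 1, 2, 2, 1)])
    inside <- draws[, 1L] >= b1[1L] & draws[, 1L] <= b1[2L] &
      draws[, 2L] >= b2[1L] & draws[, 2L] <= b2[2L]
    return(list(method = "interval_product", level = level,
                boundary = list(poly), fraction = mean(inside)))
  }
  if (method == "normal_ellipse") {
    mu <- colMeans(draws)
    r2 <- stats::qchisq(level, df = 2)
    ev <- eigen(S, symmetric = TRUE)
    tt <- seq(0, 2 * pi, length.out = 181L)
    circ <- cbind(cos(tt), sin(tt)) %*% diag(sqrt(r2 * ev$values)) %*%
      t(ev$vectors)
    poly <- sweep(circ, 2L, mu, `+`)
    colnames(poly) <- c("x", "y")
    d2 <- stats::mahalanobis(draws, mu, S)
    return(list(method = method, level = level, boundary = list(poly),
                fraction = mean(d2 <= r2), center = mu, cov = S,
                area = pi * r2 * sqrt(det(S))))
  }
  # kde: density threshold chosen so a fraction `level` of the draws lie
  # at or above it; boundary from the corresponding density contour
  h <- c(MASS::bandwidth.nrd(draws[, 1L]), MASS::bandwidth.nrd(draws[, 2L]))
  pad <- h
  kd <- MASS::kde2d(draws[, 1L], draws[, 2L], h = h, n = grid_n,
                    lims = c(range(draws[, 1L]) + c(-1, 1) * pad[1L],
                             range(draws[, 2L]) + c(-1, 1) * pad[2L]))
  # bilinear interpolation of the density at the draws
  fx <- findInterval(draws[, 1L], kd$x, all.inside = TRUE)
  fy <- findInterval(draws[, 2L], kd$y, all.inside = TRUE)
  wx <- (draws[, 1L] - kd$x[fx]) / diff(kd$x[1:2])
  wy <- (draws[, 2L] - kd$y[fy]) / diff(kd$y[1:2])
  dens <- (1 - wx) * (1 - wy) * kd$z[cbind(fx, fy)] +
    wx * (1 - wy) * kd$z[cbind(fx + 1L, fy)] +
    (1 - wx) * wy * kd$z[cbind(fx, fy + 1L)] +
    wx * wy * kd$z[cbind(fx + 1L, fy + 1L)]
  thr <- stats::quantile(dens, probs = 1 - level, names = FALSE)
  cl <- grDevices::contourLines(kd, levels = thr)
  boundary <- lapply(cl, function(cc) cbind(x = cc$x, y = cc$y))
  list(method = method, level = level, boundary = boundary,
       fraction = mean(dens >= thr), density_threshold = thr)
}

#' Convergence diagnostics for a fitted ordination model
#'
#' Standard split-\eqn{\hat R} (the chain is split in halves) and effective
#' sample size from the initial-monotone-sequence autocorrelation estimate,
#' computed for every scalar parameter.
#'
#' @param fit a fitted [latentord()] model.
#' @return list with numeric vectors `rhat` and `ess` named by parameter,
#'   and `flagged`, the names of parameters with \eqn{\hat R > 1.1}.
#' @export
mcmc_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "latentord"))
  d <- fit$draws
  cols <- list()
  add <- function(mat, base) {
    mat <- as.matrix(mat)
    colnames(mat) <- paste0(base, "[", seq_len(ncol(mat)), "]")
    cols[[length(cols) + 1L]] <<- mat
  }
  add(d$alpha, "alpha"); add(d$beta, "beta")
  m <- dim(d$Z)[1L]
  add(matrix(d$Z, m), "Z"); add(matrix(d$Theta, m), "Theta")
  if (!is.null(d$omega)) add(d$omega, "omega")
  if (!is.null(d$cutoffs)) add(d$cutoffs, "cutoff")
  X <- do.call(cbind, cols)
  # drop structurally constant columns (e.g. theta_12 = 0)
  keep <- apply(X, 2L, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  rhat <- apply(X, 2L, .split_rhat)
  ess <- apply(X, 2L, .ess_imse)
  flagged <- names(rhat)[!is.na(rhat) & rhat > 1.1]
  if (length(flagged))
    warning("split-Rhat > 1.1 for ", length(flagged), " parameter(s)")
  list(rhat = rhat, ess = ess, flagged = flagged)
}

.split_rhat <- function(x) {
  m <- length(x) %/% 2L
  if (m < 2L) return(NA_real_)
  ch <- cbind(x[seq_len(m)], x[m + seq_len(m)])
  W <- mean(apply(ch, 2L, stats::var))
  B <- m * stats::var(colMeans(ch))
  if (W == 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

# effective sample size via initial monotone positive-sequence estimator
.ess_imse <- function(x) {
  m <- length(x)
  v <- stats::var(x)
  if (v == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(m - 2L, 200L), plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  # sum paired autocorrelations while the pair sums stay positive
  s <- 0
  t <- 1L
  while (t + 1L < length(ac)) {
    pair <- ac[t + 1L] + ac[t + 2L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  max(1, m / (1 + 2 * s))
}
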