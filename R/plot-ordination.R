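#' Uncertainty-aware ordination plot
#'
#' Plots the two-dimensional ordination of the sites from a fitted latent
#' factor model in one of four modes:
#' \describe{
#'   \item{`"points"`}{posterior-mean latent factors, labelled by site
#'     number — the conventional ordination diagram.}
#'   \item{`"cloud"`}{as `"points"`, with all retained posterior draws of
#'     the highlighted sites overlaid as a light point cloud, showing the
#'     full posterior spread behind the point estimate.}
#'   \item{`"ellipses"`}{as `"points"`, with the boundary of each
#'     highlighted site's 2-D HPD region (see [hpd_region_2d()]).}
#'   \item{`"anchored"`}{draws are first anchored at `anchor_site` (see
#'     [anchor_factors()]), which is marked at the origin; positions are
#'     relative to the anchor.}
#' }
#'
#' @param fit a fitted [latentord()] model with `q >= 2`; the first two
#'   latent dimensions are plotted.
#' @param mode plot mode, see above.
#' @param highlighted_sites site indices whose uncertainty is displayed in
#'   `"cloud"`/`"ellipses"`/`"anchored"` modes (default: all sites for
#'   ellipses, none for cloud).
#' @param level HPD probability content for `"ellipses"` (default 0.95).
#' @param anchor_site reference site, required for `"anchored"`.
#' @param region_method `"kde"` or `"normal_ellipse"`, passed to
#'   [hpd_region_2d()].
#' @param align rotation-align the draws first (default `TRUE`, see
#'   [align_factors()]); point clouds and HPD regions then display
#'   positional rather than rotational uncertainty.
#' @param output_path optional file path; the figure is written there with
#'   the device chosen by extension (.pdf, .svg or .png) instead of drawn
#'   on the current device.
#' @param ... further arguments passed to `plot()`.
#' @return invisibly, the n x 2 matrix of plotted site coordinates.
#' @export
plot_ordination <- function(fit, mode = c("points", "cloud", "ellipses",
                                          "anchored"),
                            highlighted_sites = NULL, level = 0.95,
                            anchor_site = NULL,
                            region_method = c("kde", "normal_ellipse"),
                            align = TRUE, output_path = NULL, ...) {
  mode <- match.arg(mode)
  region_method <- match.arg(region_method)
  stopifnot(inherits(fit, "latentord"))
  if (fit$q < 2L) stop("ordination plots need q >= 2")
  if (align) fit$draws$Z <- align_factors(fit$draws$Z)
  if (mode == "anchored") {
    if (is.null(anchor_site)) stop("anchored mode requires anchor_site")
    fit <- anchor_factors(fit, anchor_site)
  }
  Z <- fit$draws$Z[, , 1:2, drop = FALSE]
  pm <- apply(Z, c(2, 3), mean)
  n <- nrow(pm)
  if (is.null(highlighted_sites))
    highlighted_sites <- if (mode == "ellipses") seq_len(n) else integer(0)

  if (!is.null(output_path)) {
    ext <- tolower(tools::file_ext(output_path))
    switch(ext,
           pdf = grDevices::pdf(output_path, width = 7, height = 7),
           svg = grDevices::svg(output_path, width = 7, height = 7),
           png = grDevices::png(output_path, width = 700, height = 700),
           stop("unsupported figure format: .", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }

  xlim <- range(pm[, 1L]); ylim <- range(pm[, 2L])
  if (mode %in% c("cloud", "anchored") && length(highlighted_sites)) {
    xlim <- range(xlim, Z[, highlighted_sites, 1L])
    ylim <- range(ylim, Z[, highlighted_sites, 2L])
  }
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "Latent dimension 1", ylab = "Latent dimension 2",
                 ...)
  cols <- grDevices::hcl.colors(max(length(highlighted_sites), 1L),
                                "Dark 3")
  if (mode %in% c("cloud", "anchored")) {
    for (s in seq_along(highlighted_sites)) {
      i <- highlighted_sites[s]
      graphics::points(Z[, i, 1L], Z[, i, 2L], pch = 16, cex = 0.2,
                       col = grDevices::adjustcolor(cols[s], 0.15))
    }
  }
  if (mode == "ellipses") {
    for (s in seq_along(highlighted_sites)) {
      i <- highlighted_sites[s]
      reg <- hpd_region_2d(cbind(Z[, i, 1L], Z[, i, 2L]), level = level,
                           method = region_method)
      for (poly in reg$boundary)
        graphics::lines(poly[, 1L], poly[, 2L], col = cols[s])
    }
  }
  graphics::text(pm[, 1L], pm[, 2L], labels = seq_len(n), cex = 0.9)
  if (mode == "anchored") {
    ai <- if (is.character(anchor_site))
      match(anchor_site, rownames(fit$y)) else anchor_site
    graphics::points(0, 0, pch = 3, cex = 1.5, lwd = 2)
    graphics::text(0, 0, labels = ai, font = 2, pos = 4)
  }
  invisible(pm)
}
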