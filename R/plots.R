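#' Plot per-bin convex hulls of subsample mean shapes in PC space
#'
#' @param x a `rarefaction_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rarefaction_summary <- function(x, ...) {
  sc <- x$scores
  graphics::plot(sc$PC1, sc$PC2, type = "n",
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$pca$explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained[2L]),
                 ...)
  bins <- levels(sc$bin)
  cols <- grDevices::hcl.colors(length(bins), "Zissou 1", alpha = 0.35)
  for (i in seq_along(bins)) {
    h <- x$hulls[[bins[i]]]
    if (!is.null(h) && nrow(h) >= 3L)
      graphics::polygon(h[, 1L], h[, 2L], col = cols[i], border = NA)
  }
  graphics::points(sc$PC1, sc$PC2, pch = 16, cex = 0.3,
                   col = cols[as.integer(sc$bin)])
  graphics::legend("topright", legend = bins, fill = cols, bty = "n")
  invisible(x)
}

#' Plot a TPS deformation grid
#'
#' @param x a `deformation_grid`.
#' @param landmarks optional `k x 2` matrix overlaid as points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.deformation_grid <- function(x, landmarks = NULL, ...) {
  nx <- length(unique(x$x))
  ny <- length(unique(x$y))
  graphics::plot(x$wx, x$wy, type = "n", asp = 1, xlab = "", ylab = "", ...)
  wx <- matrix(x$wx, nx, ny)
  wy <- matrix(x$wy, nx, ny)
  for (i in seq_len(nx)) graphics::lines(wx[i, ], wy[i, ], col = "grey50")
  for (j in seq_len(ny)) graphics::lines(wx[, j], wy[, j], col = "grey50")
  if (!is.null(landmarks))
    graphics::points(landmarks, pch = 16, col = "black")
  invisible(x)
}

#' Plot shape PCA scores
#'
#' @param x a `shape_pca`.
#' @param axes which two components to show.
#' @param groups optional factor used for colours.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_pca <- function(x, axes = c(1, 2), groups = NULL, ...) {
  sc <- x$scores[, axes, drop = FALSE]
  col <- if (is.null(groups)) "black"
         else as.integer(factor(groups)) + 1L
  graphics::plot(sc, pch = 16, col = col,
                 xlab = sprintf("PC%d (%.1f%%)", axes[1L],
                                100 * x$explained[axes[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2L],
                                100 * x$explained[axes[2L]]),
                 ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))) + 1L,
                     pch = 16, bty = "n")
  invisible(x)
}
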