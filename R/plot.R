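#' Plot a seed contour or average contour
#'
#' @param x a [seed_contour] (or `average_contour`/`shape_model`, whose
#'   reconstruction is drawn).
#' @param add add to an existing plot.
#' @param ... further arguments to [graphics::polygon].
#' @export
plot.seed_contour <- function(x, add = FALSE, ...) {
  p <- x$points
  if (!add)
    graphics::plot(NA, xlim = range(p[, 1]), ylim = range(p[, 2]),
                   asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                   main = x$source_id)
  graphics::polygon(p[, 1], p[, 2], ...)
  invisible(x)
}

#' @export
plot.average_contour <- function(x, ...) {
  plot(x$reconstruction, ...)
  invisible(x)
}

#' Score scatter of a Fourier-coefficient PCA
#'
#' PC1/PC2 scores colored by group, with group centroids and the 95%
#' confidence ellipses for the group means.
#'
#' @param x a `pca_fourier` with group labels.
#' @param ... passed to [graphics::plot].
#' @export
plot.pca_fourier <- function(x, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  gl <- if (!is.null(x$groups)) factor(x$groups) else factor(rep(1, nrow(s)))
  cols <- seq_along(levels(gl)) + 1
  graphics::plot(s, col = cols[gl], pch = 16, asp = 1,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_fraction[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_fraction[2]),
                 ...)
  if (!is.null(x$ellipses)) {
    for (i in seq_along(x$ellipses)) {
      el <- x$ellipses[[i]]
      graphics::points(el$center[1], el$center[2], pch = 17, cex = 1.5,
                       col = cols[i])
      eg <- eigen(el$cov_mean, symmetric = TRUE)
      tt <- seq(0, 2 * pi, length.out = 181)
      circ <- cbind(cos(tt), sin(tt)) %*% diag(sqrt(el$radius2 * eg$values))
      pts <- circ %*% t(eg$vectors)
      graphics::lines(pts[, 1] + el$center[1], pts[, 2] + el$center[2],
                      col = cols[i])
    }
    graphics::legend("topright", legend = names(x$ellipses), col = cols,
                     pch = 16, bty = "n")
  }
  invisible(x)
}
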