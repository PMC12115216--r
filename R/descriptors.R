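#' Classical shape measurements for one seed contour
#'
#' Computes the eight descriptors used throughout the package, following
#' ImageJ's conventions: area \eqn{A} and perimeter \eqn{P} of the polygon;
#' length \eqn{L} and width \eqn{W} as the major and minor axis of the
#' best-fit (moment) ellipse; circularity \eqn{C = 4\pi A / P^2}; aspect
#' ratio \eqn{AR = L/W}; roundness \eqn{R = 4A/(\pi L^2)}; and solidity
#' \eqn{S = 1000\, A / A_{hull}}, reported on the conventional x1000 integer
#' scale (1000 = convex). The convex hull is computed on the polygon
#' vertices (exact), so solidity does not depend on raster resolution.
#'
#' The moment ellipse has the same second central area moments as the
#' polygon and is rescaled to equal area, which reproduces the axes of a
#' true ellipse exactly. Feret (caliper) lengths are available as an
#' alternative length/width definition for sensitivity checks.
#'
#' @param c a [seed_contour].
#' @param length_method `"ellipse"` (moment ellipse axes, default) or
#'   `"feret"` (max caliper length and its orthogonal extent).
#' @return A one-row data frame of class `shape_measurements` with columns
#'   `area_mm2`, `perimeter_mm`, `length_mm`, `width_mm`, `circularity`,
#'   `aspect_ratio`, `roundness`, `solidity`.
#' @export
measure <- function(c, length_method = c("ellipse", "feret")) {
  stopifnot(inherits(c, "seed_contour"))
  length_method <- match.arg(length_method)
  p <- c$points
  A <- polygon_area(p)
  if (A <= 0) stop("degenerate polygon: zero area")
  P <- polygon_perimeter(p)
  if (length_method == "ellipse") {
    m <- polygon_second_moments(p)
    M <- matrix(c(m$mu20, m$mu11, m$mu11, m$mu02), 2, 2)
    ev <- eigen(M, symmetric = TRUE)$values
    a <- 2 * sqrt(max(ev)); b <- 2 * sqrt(min(ev))
    # rescale to equal area (ImageJ convention); preserves the axis ratio
    f <- sqrt(A / (pi * a * b))
    L <- 2 * a * f; W <- 2 * b * f
  } else {
    hull <- p[grDevices::chull(p), , drop = FALSE]
    d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    L <- sqrt(max(d2))
    u <- (hull[ij[2], ] - hull[ij[1], ]) / L
    proj <- p[, 1] * (-u[2]) + p[, 2] * u[1]
    W <- diff(range(proj))
  }
  hull <- p[grDevices::chull(p), , drop = FALSE]
  S <- round(1000 * A / polygon_area(hull))
  res <- data.frame(area_mm2 = A, perimeter_mm = P, length_mm = L,
                    width_mm = W, circularity = 4 * pi * A / P^2,
                    aspect_ratio = L / W, roundness = 4 * A / (pi * L^2),
                    solidity = S)
  class(res) <- c("shape_measurements", class(res))
  res
}

#' Per-metric mean and coefficient of variation over a population
#'
#' @param measurements a data frame of stacked [measure] rows (or a list of
#'   them), one row per seed.
#' @return Data frame with one row per metric: `metric`, `mean`, `cv`
#'   (percent, 100 * sample sd / mean).
#' @export
population_summary <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- do.call(rbind, measurements)
  if (is.null(measurements) || nrow(measurements) == 0)
    stop("population_summary needs at least one measurement")
  num <- measurements[vapply(measurements, is.numeric, TRUE)]
  mn <- vapply(num, mean, 0)
  sdv <- if (nrow(num) > 1) vapply(num, stats::sd, 0) else rep(0, ncol(num))
  data.frame(metric = names(num), mean = unname(mn),
             cv = unname(ifelse(mn == 0, 0, 100 * sdv / mn)),
             row.names = NULL)
}

#' Write a per-seed measurement table to CSV
#'
#' One row per seed with the eight descriptors (solidity on the x1000
#' scale), plus the seed identifier.
#'
#' @param contours list of [seed_contour] objects.
#' @param path output CSV path.
#' @param ... passed to [measure].
#' @return The table, invisibly.
#' @export
write_measurements_csv <- function(contours, path, ...) {
  tab <- do.call(rbind, lapply(contours, measure, ...))
  tab <- cbind(seed_id = vapply(contours, function(x) x$source_id, ""), tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
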