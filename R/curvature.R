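#' Extract the lower profile of a seed contour
#'
#' Returns the open sub-path running along the lower side of the outline
#' from the leftmost to the rightmost point, ordered left to right. The
#' contour is expected in standard orientation (major axis along x, as
#' produced by reconstructing normalized Fourier coefficients), so the
#' profile spans base and beak. Ties in the horizontal extremes are
#' resolved by the lowest y.
#'
#' @param c a [seed_contour].
#' @return An n x 2 matrix of (x, y), open path, x increasing overall.
#' @export
extract_lower_profile <- function(c) {
  stopifnot(inherits(c, "seed_contour"))
  p <- c$points
  n <- nrow(p)
  pick_extreme <- function(xs) {
    cand <- which(p[, 1] == xs)
    cand[which.min(p[cand, 2])]
  }
  il <- pick_extreme(min(p[, 1]))
  ir <- pick_extreme(max(p[, 1]))
  if (il == ir) stop("degenerate contour: no horizontal extent")
  arc <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1:to)
  }
  a1 <- arc(il, ir); a2 <- arc(ir, il)
  m1 <- mean(p[a1, 2]); m2 <- mean(p[a2, 2])
  idx <- if (m1 <= m2) a1 else rev(a2)   # lower arc, ordered left -> right
  p[idx, , drop = FALSE]
}

#' Least-squares Bezier fit to an open point sequence
#'
#' Fits a single Bezier curve of the given degree by linear least squares
#' in the Bernstein basis, with chord-length parameterization and both
#' endpoints interpolated exactly.
#'
#' @param points n x 2 matrix of ordered points (n >= degree + 1).
#' @param degree polynomial degree (default 10).
#' @return An object of class `bezier_fit`: `control` ((degree+1) x 2
#'   control points), `degree`, `rms_residual`, `chord_params`.
#' @export
fit_bezier <- function(points, degree = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < degree + 1)
    stop(sprintf("underdetermined fit: %d points for degree %d; lower the degree",
                 n, degree))
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[n] <= 0) stop("degenerate profile: zero length")
  u <- s / s[n]
  B <- bernstein_matrix(u, degree)
  # endpoint interpolation: solve only for interior control points
  interior <- 2:degree
  rhs <- points - B[, 1, drop = FALSE] %*% points[1, , drop = FALSE] -
    B[, degree + 1, drop = FALSE] %*% points[n, , drop = FALSE]
  ctrl_int <- qr.solve(B[, interior, drop = FALSE], rhs)
  control <- rbind(points[1, ], ctrl_int, points[n, ])
  fitted <- B %*% control
  rms <- sqrt(mean(rowSums((fitted - points)^2)))
  structure(list(control = unname(control), degree = degree,
                 rms_residual = rms, chord_params = u),
            class = "bezier_fit")
}

bernstein_matrix <- function(u, degree) {
  k <- 0:degree
  outer(u, k, function(uu, kk)
    choose(degree, kk) * uu^kk * (1 - uu)^(degree - kk))
}

# Evaluate a Bezier curve and its first two derivatives at parameters t.
bezier_derivatives <- function(fit, t) {
  d <- fit$degree
  P <- fit$control
  d1 <- d * (P[-1, , drop = FALSE] - P[-(d + 1), , drop = FALSE])
  d2 <- (d - 1) * (d1[-1, , drop = FALSE] - d1[-d, , drop = FALSE])
  list(xy = bernstein_matrix(t, d) %*% P,
       v = bernstein_matrix(t, d - 1) %*% d1,
       a = bernstein_matrix(t, d - 2) %*% d2)
}

#' Curvature statistics of a fitted profile curve
#'
#' Signed curvature \eqn{\kappa(t) = (x'y'' - y'x'') / (x'^2 + y'^2)^{3/2}}
#' evaluated on a dense grid over the central parameter interval (default
#' \[0.2, 0.8\], avoiding the unstable curve extremes). For a profile in mm
#' the units are 1/mm: a circle of radius 1 mm has curvature 1, a circle of
#' radius 0.1 mm curvature 10, a straight line 0. The sign convention is
#' positive where the profile is convex (bulging away from the seed body);
#' negative values flag non-convex regions such as the flanks of the beak.
#'
#' @param curve a `bezier_fit` (from [fit_bezier]).
#' @param t_range evaluation interval within \[0, 1\].
#' @param n_grid grid density (default 601).
#' @return An object of class `curvature_profile`: `max_curv`, `min_curv`,
#'   `mean_curv` (1/mm), `max_to_mean_ratio`, plus the evaluation grid
#'   (`t`, `kappa`) and `t_range`.
#' @export
curvature_stats <- function(curve, t_range = c(0.2, 0.8), n_grid = 601) {
  stopifnot(inherits(curve, "bezier_fit"),
            length(t_range) == 2, t_range[1] < t_range[2])
  t <- seq(t_range[1], t_range[2], length.out = n_grid)
  d <- bezier_derivatives(curve, t)
  speed2 <- rowSums(d$v^2)
  if (any(speed2 < 1e-12))
    stop("vanishing speed on the curvature grid; the fit is degenerate")
  kappa <- (d$v[, 1] * d$a[, 2] - d$v[, 2] * d$a[, 1]) / speed2^1.5
  mk <- mean(kappa)
  structure(list(max_curv = max(kappa), min_curv = min(kappa),
                 mean_curv = mk,
                 max_to_mean_ratio = if (mk != 0) max(kappa) / mk else NA_real_,
                 t = t, kappa = kappa, t_range = t_range,
                 degree = curve$degree, rms_residual = curve$rms_residual),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf(
    "curvature (1/mm) on t in [%.2f, %.2f]: max %.3f, min %.3f, mean %.3f, max/mean %.2f\n",
    x$t_range[1], x$t_range[2], x$max_curv, x$min_curv, x$mean_curv,
    x$max_to_mean_ratio))
  invisible(x)
}

#' Curvature profile of a seed contour's lower side
#'
#' Convenience wrapper: extracts the lower profile, fits the Bezier curve
#' and returns the curvature statistics.
#'
#' @param c a [seed_contour] in standard orientation.
#' @param degree Bezier degree (default 10).
#' @param t_range central evaluation interval.
#' @return A `curvature_profile`.
#' @export
seed_curvature <- function(c, degree = 10, t_range = c(0.2, 0.8)) {
  prof <- extract_lower_profile(c)
  curvature_stats(fit_bezier(prof, degree), t_range)
}
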