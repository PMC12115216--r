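#' Pose of a shape for overlap scoring
#'
#' A rigid-plus-scale transform applied to a contour before overlap
#' computation: points are scaled, rotated about the origin, then
#' translated.
#'
#' @param dx,dy translation (mm).
#' @param theta rotation (radians, counterclockwise).
#' @param scale positive scale factor.
#' @return An object of class `pose`.
#' @export
pose <- function(dx = 0, dy = 0, theta = 0, scale = 1) {
  stopifnot(scale > 0)
  structure(list(dx = dx, dy = dy, theta = theta, scale = scale),
            class = "pose")
}

apply_pose <- function(points, pose) {
  p <- rotate_points(points * pose$scale, pose$theta)
  cbind(p[, 1] + pose$dx, p[, 2] + pose$dy)
}

as_polygon <- function(shape) {
  if (inherits(shape, c("average_contour", "shape_model")))
    shape <- shape$reconstruction
  if (inherits(shape, "seed_contour")) return(shape$points)
  if (is.matrix(shape) && ncol(shape) == 2) return(shape)
  stop("expected a seed_contour, average_contour/shape_model, or n x 2 matrix")
}

#' Percent area overlap (J value) of two shapes at a given pose
#'
#' J = 100 * area(intersection) / area(union) of the two closed outlines,
#' where the union is the total surface occupied by either shape. The areas
#' are computed by scanline strip integration (exact along x, composite
#' midpoint rule across `n_strips` horizontal strips); intersection and
#' union share the same strips, so identical shapes score exactly 100 and
#' disjoint shapes exactly 0.
#'
#' @param shape_a,shape_b [seed_contour] objects (or models / matrices).
#' @param pose a [pose] applied to `shape_b` first.
#' @param n_strips strip count of the area integrator.
#' @return J value in \[0, 100\].
#' @export
overlap_ratio <- function(shape_a, shape_b, pose = seedmorph::pose(),
                          n_strips = 400) {
  a <- as_polygon(shape_a)
  b <- apply_pose(as_polygon(shape_b), pose)
  if (polygon_area(a) <= 0 || polygon_area(b) <= 0)
    stop("degenerate polygon in overlap computation")
  o <- overlap_areas_cpp(a[, 1], a[, 2], b[, 1], b[, 2], as.integer(n_strips))
  if (o[2] <= 0) return(0)
  100 * o[1] / o[2]
}

# J for pre-extracted polygons, skipping validation (hot path).
overlap_j <- function(a, b, n_strips) {
  o <- overlap_areas_cpp(a[, 1], a[, 2], b[, 1], b[, 2], n_strips)
  if (o[2] <= 0) 0 else 100 * o[1] / o[2]
}

#' Register a seed onto a model by maximizing overlap
#'
#' The algorithmic counterpart of superimposing a model on a seed image
#' "looking for maximum similarity": initialization aligns centroids,
#' equalizes areas (unless `fixed_scale`) and tries all rotations on a
#' 1-degree grid; the best grid pose is then refined by Nelder-Mead over
#' (dx, dy, theta, log scale). The returned pose is never worse than the
#' best grid pose. Ties between equal-J rotations keep the smaller
#' |rotation|.
#'
#' @param model reference shape ([seed_contour], model, or matrix).
#' @param seed shape to be posed onto the model.
#' @param fixed_scale if `TRUE`, scale is held at 1 (strict same-scale
#'   comparison); default optimizes scale, as the manual overlay implicitly
#'   resizes the model.
#' @param n_strips area-integrator resolution.
#' @param rotation_step grid step in degrees.
#' @param refine_maxit Nelder-Mead iteration cap for the local refinement.
#' @return A [pose] with attributes `j` (J at the pose), `j_init` (J of the
#'   best grid initialization), and `converged` (`FALSE` flags a refinement
#'   stopped at its iteration cap; the best evaluated pose is returned
#'   either way and is never worse than the initialization).
#' @export
register <- function(model, seed, fixed_scale = FALSE, n_strips = 400,
                     rotation_step = 1, refine_maxit = 200) {
  a <- as_polygon(model)
  b <- as_polygon(seed)
  ca <- polygon_centroid(a); cb <- polygon_centroid(b)
  s0 <- if (fixed_scale) 1 else sqrt(polygon_area(a) / polygon_area(b))
  a0 <- cbind(a[, 1] - ca[1], a[, 2] - ca[2])
  b0 <- cbind(b[, 1] - cb[1], b[, 2] - cb[2]) * s0
  thetas <- seq(0, 360 - rotation_step, by = rotation_step) * pi / 180
  jgrid <- vapply(thetas, function(th)
    overlap_j(a0, rotate_points(b0, th), n_strips), 0)
  # wrap to (-pi, pi]; ties keep the smaller |rotation|
  tw <- ifelse(thetas > pi, thetas - 2 * pi, thetas)
  best <- order(-jgrid, abs(tw))[1]
  th0 <- tw[best]; j_init <- jgrid[best]
  obj <- function(par) {
    f <- if (fixed_scale) 1 else exp(par[4])
    rp <- rotate_points(b0 * f, par[3])
    -overlap_j(a0, cbind(rp[, 1] + par[1], rp[, 2] + par[2]), n_strips)
  }
  span <- sqrt(polygon_area(a))
  opt <- stats::optim(c(0, 0, th0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = refine_maxit, reltol = 1e-6,
                                     parscale = c(0.05 * span, 0.05 * span,
                                                  0.05, 0.05)))
  converged <- opt$convergence == 0
  if (-opt$value >= j_init) {
    par <- opt$par; j_best <- -opt$value
  } else {
    par <- c(0, 0, th0, 0); j_best <- j_init
  }
  s_fin <- if (fixed_scale) 1 else s0 * exp(par[4])
  # compose: x' = s R (x - cb) + ca + d  ==  s R x + t
  rc <- rotate_points(matrix(cb, 1, 2), par[3]) * s_fin
  p <- pose(dx = ca[1] + par[1] - rc[1], dy = ca[2] + par[2] - rc[2],
            theta = par[3], scale = s_fin)
  attr(p, "j") <- j_best
  attr(p, "j_init") <- j_init
  attr(p, "converged") <- converged
  p
}

#' J-index of a seed population against a model
#'
#' Each seed is registered onto the model (pose maximizing overlap) and
#' scored; the population J-index is the mean of the per-seed values, with
#' its coefficient of variation.
#'
#' @param model a `shape_model`, [average_contour] or [seed_contour].
#' @param seeds list of [seed_contour] objects (n >= 1).
#' @param ... passed to [register].
#' @return An object of class `jindex_result`: data frame `per_seed`
#'   (seed_id, j, dx, dy, theta_deg, scale), `mean_j`, `cv_j`,
#'   `model_label`, `population_label`.
#' @export
jindex_population <- function(model, seeds, ...) {
  if (inherits(seeds, "seed_contour")) seeds <- list(seeds)
  if (length(seeds) == 0) stop("empty seed list")
  rows <- lapply(seeds, function(s) {
    p <- register(model, s, ...)
    data.frame(seed_id = s$source_id, j = attr(p, "j"), dx = p$dx, dy = p$dy,
               theta_deg = p$theta * 180 / pi, scale = p$scale)
  })
  tab <- do.call(rbind, rows)
  mlab <- if (!is.null(model$label)) model$label else "model"
  structure(list(per_seed = tab, mean_j = mean(tab$j),
                 cv_j = if (nrow(tab) > 1 && mean(tab$j) > 0)
                   100 * stats::sd(tab$j) / mean(tab$j) else 0,
                 model_label = mlab,
                 population_label = attr(seeds, "label") %||% "population"),
            class = "jindex_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.jindex_result <- function(x, ...) {
  cat(sprintf("J-index of '%s' vs model '%s': mean %.1f (CV %.1f), n = %d\n",
              x$population_label, x$model_label, x$mean_j, x$cv_j,
              nrow(x$per_seed)))
  invisible(x)
}

#' Validate an average contour against its member seeds
#'
#' Scores the seeds a population average was derived from against that
#' average, the standard internal-consistency check for an Ac.
#'
#' @param ac an [average_contour].
#' @param seeds the member [seed_contour] objects.
#' @param ... passed to [register].
#' @return A `jindex_result`.
#' @export
validate_ac <- function(ac, seeds, ...) {
  stopifnot(inherits(ac, "average_contour"))
  jindex_population(ac, seeds, ...)
}
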