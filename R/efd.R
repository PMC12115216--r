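#' Elliptic Fourier decomposition of a closed contour
#'
#' Computes Kuhl-Giardina elliptic Fourier coefficients of a closed polygon,
#' treating the outline as a pair of periodic functions x(t), y(t) of arc
#' length. Each harmonic k contributes four coefficients: `A` (cosine, x),
#' `B` (sine, x), `C` (cosine, y), `D` (sine, y). Eight harmonics suffice to
#' describe the smooth pyriform outlines of grape seeds, including the
#' concave flanks of the beak.
#'
#' @param c a [seed_contour] (>= 2 * n_harmonics + 1 vertices).
#' @param n_harmonics number of harmonics (default 8).
#' @param parameterization `"arc"` (default): the outline is parameterized
#'   by cumulative chord length, the classic Kuhl-Giardina convention.
#'   `"uniform"`: vertices are taken as equally spaced in the curve
#'   parameter, which makes the transform exact on analytically
#'   parameterized inputs (an ellipse sampled uniformly in angle is exactly
#'   harmonic 1). The two coincide for contours resampled to uniform arc
#'   length, the package's standard preprocessing.
#' @return An object of class `efd`: list with `coeffs` (n_harmonics x 4
#'   matrix, columns A, B, C, D), `dc` (x0, y0 of the outline centroid
#'   term), `size_mm` (semi-major axis of harmonic 1; populated by
#'   [normalize_coeffs]), `normalized` (logical), `label`.
#' @export
efd_transform <- function(c, n_harmonics = 8,
                          parameterization = c("arc", "uniform")) {
  stopifnot(inherits(c, "seed_contour"))
  parameterization <- match.arg(parameterization)
  p <- c$points
  if (nrow(p) < 2 * n_harmonics + 1)
    stop(sprintf("need at least %d points for %d harmonics",
                 2 * n_harmonics + 1, n_harmonics))
  pc <- rbind(p, p[1, , drop = FALSE])
  dx <- diff(pc[, 1]); dy <- diff(pc[, 2])
  dt <- if (parameterization == "arc") sqrt(dx^2 + dy^2)
        else rep(1, length(dx))
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t <- c(0, cumsum(dt))
  T <- t[length(t)]
  t0 <- t[-length(t)]; t1 <- t[-1]
  co <- matrix(0, n_harmonics, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  for (k in seq_len(n_harmonics)) {
    w <- 2 * pi * k / T
    f <- T / (2 * pi^2 * k^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    co[k, "A"] <- f * sum(dx / dt * dcos)
    co[k, "B"] <- f * sum(dx / dt * dsin)
    co[k, "C"] <- f * sum(dy / dt * dcos)
    co[k, "D"] <- f * sum(dy / dt * dsin)
  }
  # DC term (outline centroid of the parameterized curve)
  xi <- cumsum(dx) - dx / 2
  a0 <- sum(dt * (xi + pc[1, 1])) / T
  yi <- cumsum(dy) - dy / 2
  c0 <- sum(dt * (yi + pc[1, 2])) / T
  structure(list(coeffs = co, dc = c(a0, c0), size_mm = NA_real_,
                 normalized = FALSE, label = c$source_id),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("efd '%s': %d harmonics, %s (size %.3g mm)\n", x$label,
              nrow(x$coeffs), if (x$normalized) "normalized" else "raw",
              x$size_mm))
  invisible(x)
}

# Rotate the parameter (start point) by theta and the plane by psi,
# following the classic first-harmonic normalization convention:
# [A* B*; C* D*] = [[cos psi, sin psi], [-sin psi, cos psi]] %*%
#                  [A B; C D] %*% [[cos k.theta, -sin k.theta],
#                                  [sin k.theta,  cos k.theta]]
efd_apply_rotations <- function(co, theta, psi) {
  out <- co
  rot_s <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2,
                  byrow = TRUE)
  for (k in seq_len(nrow(co))) {
    m <- matrix(co[k, ], 2, 2, byrow = TRUE)       # [A B; C D]
    rot_t <- matrix(c(cos(k * theta), -sin(k * theta),
                      sin(k * theta), cos(k * theta)), 2, 2, byrow = TRUE)
    m2 <- rot_s %*% m %*% rot_t
    out[k, ] <- c(m2[1, ], m2[2, ])
  }
  out
}

#' Normalize elliptic Fourier coefficients
#'
#' Standardizes the coefficients with the first-harmonic procedure: the
#' starting point is shifted to the crossing of the harmonic-1 ellipse's
#' major axis, the shape is rotated so that axis lies along x, the
#' translation term is dropped, and size is divided out (the harmonic-1
#' semi-major axis length, stored in `size_mm`, so mm-scale quantities can
#' be recovered). After normalization the coefficients are invariant to
#' input rotation, translation, scale, and starting point. Reflection is
#' deliberately not normalized away: seeds are photographed in a consistent
#' lateral view, so chirality is a real signal.
#'
#' The 180-degree ambiguity of the major axis is resolved by orienting the
#' x-skewness of the reconstructed outline to be non-negative, which points
#' the seed beak in a fixed direction for any input pose.
#'
#' @param e an `efd` object (idempotent on normalized input).
#' @return A normalized `efd` object.
#' @export
normalize_coeffs <- function(e) {
  stopifnot(inherits(e, "efd"))
  co <- e$coeffs
  a1 <- co[1, "A"]; b1 <- co[1, "B"]; c1 <- co[1, "C"]; d1 <- co[1, "D"]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-20) stop("degenerate first harmonic")
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  best <- NULL
  for (th in c(theta, theta + pi)) {
    co1 <- efd_apply_rotations(co[1, , drop = FALSE], th, 0)
    psi <- atan2(co1[1, "C"], co1[1, "A"])
    cand <- efd_apply_rotations(co, th, psi)
    E <- unname(cand[1, "A"])
    cand <- cand / E
    # orientation tie-break: non-negative x-skewness of the reconstruction
    xs <- efd_eval(cand, c(0, 0), 256)[, 1]
    sk <- mean((xs - mean(xs))^3)
    score <- if (abs(sk) < 1e-12) 0 else sign(sk)
    if (is.null(best) || score > best$score)
      best <- list(co = cand, E = E, score = score)
  }
  size0 <- if (is.na(e$size_mm)) 1 else e$size_mm
  structure(list(coeffs = best$co, dc = c(0, 0),
                 size_mm = size0 * best$E, normalized = TRUE,
                 label = e$label),
            class = "efd")
}

# Evaluate the truncated Fourier series at n uniform parameter values.
efd_eval <- function(co, dc, n_points) {
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- rep(dc[1], n_points); y <- rep(dc[2], n_points)
  for (k in seq_len(nrow(co))) {
    x <- x + co[k, "A"] * cos(k * t) + co[k, "B"] * sin(k * t)
    y <- y + co[k, "C"] * cos(k * t) + co[k, "D"] * sin(k * t)
  }
  cbind(x, y)
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' Evaluates the truncated series at uniform parameter values. For
#' normalized coefficients the stored `size_mm` scale is reapplied (unless
#' `rescale = FALSE`), so reconstructions are in mm.
#'
#' @param e an `efd`, [average_contour] or [build_model] result.
#' @param n_points number of points on the reconstruction.
#' @param rescale multiply a normalized shape back to mm scale.
#' @return A [seed_contour].
#' @export
reconstruct <- function(e, n_points = 360, rescale = TRUE) {
  if (inherits(e, c("average_contour", "shape_model"))) e <- e$coeffs
  stopifnot(inherits(e, "efd"))
  p <- efd_eval(e$coeffs, e$dc, n_points)
  if (e$normalized && rescale && is.finite(e$size_mm)) p <- p * e$size_mm
  seed_contour(p, source_id = e$label)
}

#' Average contour (Ac) of a seed population
#'
#' The mean shape of a population: the element-wise arithmetic mean of the
#' members' normalized elliptic Fourier coefficients (and of their sizes),
#' reconstructed as a closed curve. This is the computational route to the
#' population-average silhouette that image-averaging produces graphically.
#'
#' @param coeff_list list of normalized `efd` objects with equal harmonic
#'   count.
#' @param label name for the population (e.g. cultivar).
#' @param n_points reconstruction density.
#' @return An object of class `average_contour`: `coeffs` (normalized
#'   `efd`), `n_seeds`, `label`, `reconstruction` (a [seed_contour]).
#' @export
average_contour <- function(coeff_list, label = "Ac", n_points = 360) {
  stopifnot(length(coeff_list) >= 1)
  norm <- vapply(coeff_list, function(e) isTRUE(e$normalized), TRUE)
  if (!all(norm)) stop("all coefficient sets must be normalized (mixed states)")
  nh <- vapply(coeff_list, function(e) nrow(e$coeffs), 0L)
  if (length(unique(nh)) != 1) stop("harmonic counts differ")
  co <- Reduce(`+`, lapply(coeff_list, `[[`, "coeffs")) / length(coeff_list)
  sz <- mean(vapply(coeff_list, `[[`, 0, "size_mm"))
  eff <- structure(list(coeffs = co, dc = c(0, 0), size_mm = sz,
                        normalized = TRUE, label = label), class = "efd")
  structure(list(coeffs = eff, n_seeds = length(coeff_list), label = label,
                 reconstruction = reconstruct(eff, n_points)),
            class = "average_contour")
}

#' @export
print.average_contour <- function(x, ...) {
  cat(sprintf("average_contour '%s' over %d seeds (mean size %.3g mm)\n",
              x$label, x$n_seeds, x$coeffs$size_mm))
  invisible(x)
}

#' Build a reference shape model from average contours
#'
#' A shape model is the coefficient-wise mean of two or more population
#' average contours, reconstructed as a closed reference curve -- e.g. a
#' model built from the Acs of two harvests of one cultivar, or of two
#' related cultivars.
#'
#' @param acs list of [average_contour] objects (n >= 2).
#' @param name model name.
#' @param n_points reconstruction density.
#' @return An object of class `shape_model` (same fields as
#'   `average_contour` plus `member_labels`).
#' @export
build_model <- function(acs, name, n_points = 360) {
  if (length(acs) < 2) stop("a model needs at least 2 average contours")
  stopifnot(all(vapply(acs, inherits, TRUE, "average_contour")))
  ac <- average_contour(lapply(acs, `[[`, "coeffs"), label = name,
                        n_points = n_points)
  structure(c(ac, list(member_labels = vapply(acs, `[[`, "", "label"))),
            class = c("shape_model", "average_contour"))
}

#' Tabulate normalized Fourier coefficients
#'
#' One row per seed (or Ac), columns `A1..A8, B1..B8, C1..C8, D1..D8`,
#' suitable as PCA input or CSV export.
#'
#' @param coeff_list list of `efd` objects.
#' @return Data frame with a `label` column and 4 * n_harmonics coefficient
#'   columns.
#' @export
coefficient_table <- function(coeff_list) {
  nh <- nrow(coeff_list[[1]]$coeffs)
  rows <- lapply(coeff_list, function(e) {
    v <- c(e$coeffs[, "A"], e$coeffs[, "B"], e$coeffs[, "C"], e$coeffs[, "D"])
    names(v) <- c(paste0("A", 1:nh), paste0("B", 1:nh),
                  paste0("C", 1:nh), paste0("D", 1:nh))
    v
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(label = vapply(coeff_list, `[[`, "", "label"), out)
}
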