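# Internal planar-polygon helpers shared by all modules.
# Polygons are n x 2 matrices of (x, y) vertices, implicitly closed
# (first vertex is not repeated), mathematical orientation (y up).

#' @useDynLib seedmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(p) abs(polygon_signed_area(p))

polygon_perimeter <- function(p) {
  d <- p - p[c(2:nrow(p), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Exact second central area moments (mu20, mu02, mu11), normalized by area,
# via Green's theorem. Used for the moment (best-fit) ellipse.
polygon_second_moments <- function(p) {
  ctr <- polygon_centroid(p)
  x <- p[, 1] - ctr[1]; y <- p[, 2] - ctr[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  ixx <- sum(cr * (x^2 + x * xn + xn^2)) / 12       # integral of x^2 dA
  iyy <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  ixy <- sum(cr * (2 * x * y + x * yn + xn * y + 2 * xn * yn)) / 24
  s <- sign(a)
  list(area = abs(a),
       mu20 = s * ixx / abs(a), mu02 = s * iyy / abs(a), mu11 = s * ixy / abs(a))
}

ensure_ccw <- function(p) {
  if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# Uniform arc-length resampling of a closed polygon to n points.
resample_closed <- function(p, n) {
  p <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate (zero-length) contour")
  keep <- c(TRUE, seg > 0)            # drop duplicated vertices
  s <- s[keep]; p <- p[keep, , drop = FALSE]
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(s, p[, 1], xout = target)$y,
        stats::approx(s, p[, 2], xout = target)$y)
}

rotate_points <- function(p, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(p[, 1] * ct - p[, 2] * st, p[, 1] * st + p[, 2] * ct)
}

# Simplicity check (no self-intersection), delegated to compiled code.
is_simple_polygon <- function(p) {
  polygon_is_simple_cpp(as.numeric(p[, 1]), as.numeric(p[, 2]))
}

# Symmetric Hausdorff distance between two point sets (used to quantify
# reconstruction error of truncated Fourier series).
hausdorff_distance <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}
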