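# Analytic fixture shapes used across the test files.

circle_contour <- function(r = 1, n = 360, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  seed_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
               source_id = "circle")
}

ellipse_contour <- function(a = 2, b = 1, n = 360, phase = 0, rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + phase
  p <- cbind(a * cos(th), b * sin(th))
  if (rot != 0) {
    p <- p %*% t(matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2,
                        byrow = TRUE))
  }
  seed_contour(p, source_id = "ellipse")
}

square_contour <- function(side = 1, origin = c(0, 0)) {
  seed_contour(rbind(origin,
                     origin + c(side, 0),
                     origin + c(side, side),
                     origin + c(0, side)),
               source_id = "square")
}

# a template seed contour perturbed reproducibly (shape-level fixture)
noisy_seed <- function(morphotype = "heben_like", seed = 1, n_points = 240) {
  pop <- sample_population(build_template(morphotype), 1,
                           coeff_noise_cv = 0.05, size_cv = 0.03,
                           rng_seed = seed)
  reconstruct(pop$seeds[[1]], n_points)
}
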