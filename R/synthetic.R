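# Synthetic seed populations of known morphotype. Templates are fixed
# normalized Fourier coefficient sets (see templates.R for the frozen
# constants and scripts/tune_templates.R for their provenance); populations
# are templates with per-seed coefficient noise on harmonics 2+ and a
# lognormal-free multiplicative size factor on the scale term.

#' Build a morphotype template
#'
#' Returns one of the fixed, versioned coefficient sets the generator is
#' built around. `"heben_like"` emulates the high-solidity morphotype
#' (target AR 1.62, solidity 975 on the x1000 scale, rounded beak);
#' `"chenin_like"` the lower-solidity morphotype with a straighter beak
#' (AR 1.68, solidity 955); `"sylvestris_like"` the wild-type seed (low AR,
#' high solidity, vestigial beak).
#'
#' @param morphotype one of `"heben_like"`, `"chenin_like"`,
#'   `"sylvestris_like"`.
#' @return An object of class `morphotype_template`: `name`, `coeffs`
#'   (normalized `efd`), `nominal_length_mm`, `target_solidity`,
#'   `target_aspect_ratio`.
#' @export
build_template <- function(morphotype) {
  if (!morphotype %in% names(.seed_templates))
    stop(sprintf("unknown morphotype '%s'; valid labels: %s", morphotype,
                 paste(names(.seed_templates), collapse = ", ")))
  tpl <- .seed_templates[[morphotype]]
  eff <- structure(list(coeffs = tpl$coeffs, dc = c(0, 0),
                        size_mm = tpl$size_mm, normalized = TRUE,
                        label = morphotype), class = "efd")
  structure(list(name = morphotype, coeffs = eff,
                 nominal_length_mm = tpl$nominal_length_mm,
                 target_solidity = tpl$target_solidity,
                 target_aspect_ratio = tpl$target_aspect_ratio),
            class = "morphotype_template")
}

#' @export
print.morphotype_template <- function(x, ...) {
  cat(sprintf("morphotype_template '%s': target AR %.2f, solidity %d, length %.1f mm\n",
              x$name, x$target_aspect_ratio, x$target_solidity,
              x$nominal_length_mm))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a synthetic seed population from a template
#'
#' Each seed is the template with independent zero-mean multiplicative
#' Gaussian noise on every coefficient of harmonics 2 and above (sd =
#' `coeff_noise_cv` x |coefficient|) and a multiplicative size factor with
#' coefficient of variation `size_cv` on the scale term. Draws whose
#' reconstruction self-intersects are redrawn (at most `max_retries` per
#' seed). With both noise levels 0 every seed equals the template. Fully
#' deterministic given `rng_seed`.
#'
#' @param template a `morphotype_template` (from [build_template]).
#' @param n number of seeds (>= 1).
#' @param coeff_noise_cv shape-noise level (default 0.05).
#' @param size_cv size-noise level (default 0.03).
#' @param rng_seed integer seed.
#' @param max_retries redraw cap per seed.
#' @return An object of class `synthetic_population`: `template`, `seeds`
#'   (list of normalized `efd` objects), `true_label`, `rng_seed`.
#' @export
sample_population <- function(template, n, coeff_noise_cv = 0.05,
                              size_cv = 0.03, rng_seed = 1,
                              max_retries = 100) {
  stopifnot(inherits(template, "morphotype_template"), n >= 1,
            coeff_noise_cv >= 0, size_cv >= 0)
  base <- template$coeffs
  nh <- nrow(base$coeffs)
  seeds <- with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(max_retries)) {
        co <- base$coeffs
        if (coeff_noise_cv > 0 && nh > 1) {
          idx <- 2:nh
          co[idx, ] <- co[idx, ] *
            (1 + coeff_noise_cv * matrix(stats::rnorm(length(idx) * 4),
                                         length(idx), 4))
        }
        sz <- base$size_mm * max(0.1, 1 + size_cv * stats::rnorm(1))
        e <- structure(list(coeffs = co, dc = c(0, 0), size_mm = sz,
                            normalized = TRUE,
                            label = sprintf("%s_%03d", template$name, i)),
                       class = "efd")
        if (coeff_noise_cv == 0 ||
            is_simple_polygon(efd_eval(co, c(0, 0), 200)))
          return(e)
      }
      stop(sprintf(
        "no simple contour within %d retries at coeff_noise_cv = %g",
        max_retries, coeff_noise_cv))
    })
  })
  structure(list(template = template, seeds = seeds,
                 true_label = template$name, rng_seed = rng_seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("synthetic_population '%s': %d seeds (rng_seed %d)\n",
              x$true_label, length(x$seeds), x$rng_seed))
  invisible(x)
}

#' Reconstruct the member contours of a synthetic population
#'
#' @param pop a `synthetic_population`.
#' @param n_points points per contour.
#' @return List of [seed_contour] objects in mm, labelled by the
#'   population.
#' @export
population_contours <- function(pop, n_points = 360) {
  stopifnot(inherits(pop, "synthetic_population"))
  out <- lapply(pop$seeds, reconstruct, n_points = n_points)
  attr(out, "label") <- pop$true_label
  out
}

#' Rasterize a synthetic population to a binary image
#'
#' Lays the member seeds out on a non-touching grid and renders filled
#' silhouettes, producing input shaped like a multi-seed photograph plus
#' the ground-truth contours. Round-tripping through [extract_contours]
#' recovers each seed's area to well within 1%.
#'
#' @param pop a `synthetic_population`.
#' @param px_per_mm resolution; each seed must span at least 100 px in
#'   length.
#' @param n_cols seeds per grid row.
#' @param margin_mm blank margin around each seed within its cell.
#' @return List: `image` (0/1 matrix, row 1 = top), `contours`
#'   (ground-truth [seed_contour] list in image mm coordinates, y up),
#'   `manifest` (data frame: seed_id, true_label, rng_seed), `px_per_mm`.
#' @export
rasterize_population <- function(pop, px_per_mm = 50, n_cols = 5,
                                 margin_mm = 1.5) {
  stopifnot(inherits(pop, "synthetic_population"), px_per_mm > 0)
  cons <- population_contours(pop)
  exts <- vapply(cons, function(s) apply(s$points, 2, function(v) diff(range(v))),
                 numeric(2))
  if (max(exts) * px_per_mm < 100)
    stop("px_per_mm too low: seeds must span at least 100 px")
  cell_mm <- max(exts) + 2 * margin_mm
  if (cell_mm <= 0) stop("layout too small")
  n <- length(cons)
  n_rows <- ceiling(n / n_cols)
  wpx <- ceiling(n_cols * cell_mm * px_per_mm)
  hpx <- ceiling(n_rows * cell_mm * px_per_mm)
  img <- matrix(0L, hpx, wpx)
  placed <- vector("list", n)
  h_mm <- hpx / px_per_mm
  for (i in seq_len(n)) {
    r <- (i - 1) %/% n_cols; cc <- (i - 1) %% n_cols
    ctr <- c((cc + 0.5) * cell_mm, h_mm - (r + 0.5) * cell_mm)  # y up
    p <- cons[[i]]$points
    p <- cbind(p[, 1] - mean(range(p[, 1])) + ctr[1],
               p[, 2] - mean(range(p[, 2])) + ctr[2])
    placed[[i]] <- seed_contour(p, source_id = cons[[i]]$source_id,
                                px_per_mm = px_per_mm)
    ppx <- cbind(p[, 1] * px_per_mm, (h_mm - p[, 2]) * px_per_mm)
    mask <- fill_polygon_cpp(ppx[, 1], ppx[, 2], hpx, wpx)
    img[mask] <- 1L
  }
  manifest <- data.frame(
    seed_id = vapply(cons, `[[`, "", "source_id"),
    true_label = pop$true_label, rng_seed = pop$rng_seed)
  list(image = img, contours = placed, manifest = manifest,
       px_per_mm = px_per_mm)
}

#' Write a binary mask as PNG
#'
#' @param image 0/1 matrix (row 1 = top).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
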