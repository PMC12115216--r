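test_that("overlap identities: self = 100, disjoint = 0, half overlap = 33.33", {
  sq <- square_contour(1)
  expect_identical(overlap_ratio(sq, sq), 100)
  far <- square_contour(1, origin = c(5, 5))
  expect_identical(overlap_ratio(sq, far), 0)
  half <- square_contour(1, origin = c(0.5, 0))
  expect_equal(overlap_ratio(sq, half), 100 * 0.5 / 1.5, tolerance = 1e-6)
})

test_that("overlap is symmetric in its arguments", {
  a <- noisy_seed("heben_like", seed = 1)
  b <- noisy_seed("chenin_like", seed = 2)
  po <- pose(dx = 0.3, dy = -0.2, theta = 0.4, scale = 1.1)
  posed_b <- seed_contour(seedmorph:::apply_pose(b$points, po))
  expect_equal(overlap_ratio(a, b, po), overlap_ratio(posed_b, a),
               tolerance = 1e-9)
})

test_that("registration recovers rigid and scaled copies of a model", {
  mod <- reconstruct(build_template("heben_like")$coeffs, 200)
  moved <- seed_contour(seedmorph:::rotate_points(mod$points, 1.2) +
                          matrix(c(3, -2), nrow(mod$points), 2, byrow = TRUE))
  p1 <- register(mod, moved, rotation_step = 2)
  expect_gte(attr(p1, "j"), 99.9)

  big <- seed_contour(mod$points * 2)
  p2 <- register(mod, big, rotation_step = 2)
  expect_gte(attr(p2, "j"), 99.9)
  expect_equal(p2$scale, 0.5, tolerance = 0.01)

  # fixed-scale mode cannot rescale a doubled copy back
  p3 <- register(mod, big, fixed_scale = TRUE, rotation_step = 6)
  expect_identical(p3$scale, 1)
  expect_lt(attr(p3, "j"), 50)
})

test_that("registration never falls below its grid initialization", {
  mod <- reconstruct(build_template("chenin_like")$coeffs, 150)
  for (s in 1:4) {
    seed <- noisy_seed(sample(c("heben_like", "sylvestris_like"), 1), seed = s,
                       n_points = 150)
    p <- register(mod, seed, rotation_step = 6, refine_maxit = 60)
    expect_gte(attr(p, "j"), attr(p, "j_init"))
    expect_true(attr(p, "j") >= 0 && attr(p, "j") <= 100)
  }
})

test_that("high-frequency contour noise lowers J against a smooth model", {
  mod <- reconstruct(build_template("heben_like")$coeffs, 300)
  p <- mod$points
  th <- atan2(p[, 2] - mean(p[, 2]), p[, 1] - mean(p[, 1]))
  jag <- seed_contour(p * (1 + 0.02 * sin(24 * th)))
  j_smooth <- attr(register(mod, mod, rotation_step = 6), "j")
  j_jagged <- attr(register(mod, jag, rotation_step = 6), "j")
  expect_lt(j_jagged, j_smooth)
})

test_that("population scoring returns per-seed poses, mean and CV", {
  mod <- reconstruct(build_template("heben_like")$coeffs, 150)
  copies <- lapply(1:3, function(i) mod)
  jr <- jindex_population(mod, copies, rotation_step = 6)
  expect_equal(jr$mean_j, 100, tolerance = 1e-6)
  expect_equal(jr$cv_j, 0, tolerance = 1e-6)
  expect_identical(names(jr$per_seed),
                   c("seed_id", "j", "dx", "dy", "theta_deg", "scale"))
  expect_error(jindex_population(mod, list()), "empty")
})

test_that("an Ac validates at J = 100 against its own zero-noise population", {
  pop <- sample_population(build_template("chenin_like"), 4, 0, 0, rng_seed = 1)
  ac <- average_contour(pop$seeds, "ac")
  jr <- validate_ac(ac, population_contours(pop, 150), rotation_step = 6)
  expect_true(all(jr$per_seed$j > 99.9))
})

test_that("image-average and Fourier-average Acs validate within one J point", {
  pop <- sample_population(build_template("heben_like"), 12, 0.05, 0.03,
                           rng_seed = 21)
  cons <- population_contours(pop, 150)
  ac_fourier <- average_contour(pop$seeds, "fourier_ac", n_points = 150)

  # image route: average the aligned binary masks, threshold at 0.5
  ppm <- 20
  ext <- 12                                  # mm canvas, seeds are ~7 mm
  acc <- matrix(0, ext * ppm, ext * ppm)
  for (s in cons) {
    p <- s$points
    ctr <- seedmorph:::polygon_centroid(p)
    px <- cbind((p[, 1] - ctr[1] + ext / 2) * ppm,
                (ext / 2 - (p[, 2] - ctr[2])) * ppm)
    acc <- acc + seedmorph:::fill_polygon_cpp(px[, 1], px[, 2],
                                              nrow(acc), ncol(acc))
  }
  ac_img <- extract_contours((acc / length(cons) >= 0.5) * 1,
                             px_per_mm = ppm)[[1]]

  j_f <- validate_ac(ac_fourier, cons, rotation_step = 6)$mean_j
  j_i <- jindex_population(ac_img, cons, rotation_step = 6)$mean_j
  expect_lte(abs(j_f - j_i), 1)
})
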