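test_that("an angle-parameterized ellipse is a pure first-harmonic curve", {
  e <- efd_transform(ellipse_contour(2, 1, 720), 8, parameterization = "uniform")
  expect_lt(abs(abs(e$coeffs[1, "A"]) - 2), 1e-3)
  expect_lt(abs(abs(e$coeffs[1, "D"]) - 1), 1e-3)
  expect_lt(max(abs(e$coeffs[2:8, ])), 1e-12)
})

test_that("eight harmonics reconstruct a circle to sub-centipixel accuracy", {
  circ <- circle_contour(1, 360)
  rec <- reconstruct(efd_transform(circ, 8), 360)
  expect_lt(seedmorph:::hausdorff_distance(rec$points, circ$points), 0.01)
  expect_lt(abs(seedmorph:::polygon_area(rec$points) - pi) / pi, 0.01)
})

test_that("normalized coefficients are invariant to pose and start point", {
  base <- resample_contour(noisy_seed("chenin_like", seed = 8, n_points = 400),
                           360)
  n0 <- normalize_coeffs(efd_transform(base))
  p <- base$points

  rotated <- seed_contour(seedmorph:::rotate_points(p, 2.3) +
                            matrix(c(5, -3), nrow(p), 2, byrow = TRUE))
  n1 <- normalize_coeffs(efd_transform(rotated))
  expect_lt(max(abs(n1$coeffs - n0$coeffs)), 1e-6)

  scaled <- seed_contour(p * 0.37)
  n2 <- normalize_coeffs(efd_transform(scaled))
  expect_lt(max(abs(n2$coeffs - n0$coeffs)), 1e-6)
  expect_equal(n2$size_mm / n0$size_mm, 0.37, tolerance = 1e-6)

  rolled <- seed_contour(p[c(150:360, 1:149), ])
  n3 <- normalize_coeffs(efd_transform(rolled))
  expect_lt(max(abs(n3$coeffs - n0$coeffs)), 1e-6)
})

test_that("normalization is idempotent and rejects a degenerate first harmonic", {
  n0 <- normalize_coeffs(efd_transform(resample_contour(noisy_seed(), 240)))
  n1 <- normalize_coeffs(n0)
  expect_equal(n1$coeffs, n0$coeffs, tolerance = 1e-10)
  expect_equal(n1$size_mm, n0$size_mm, tolerance = 1e-10)

  bad <- n0
  bad$coeffs[1, ] <- 0
  expect_error(normalize_coeffs(bad), "degenerate")
})

test_that("coefficient averaging is exactly linear", {
  e1 <- normalize_coeffs(efd_transform(resample_contour(noisy_seed(seed = 1), 240)))
  e2 <- normalize_coeffs(efd_transform(resample_contour(noisy_seed(seed = 2), 240)))
  same <- average_contour(list(e1, e1, e1), "same")
  expect_equal(same$coeffs$coeffs, e1$coeffs)
  mid <- average_contour(list(e1, e2), "mid")
  expect_identical(mid$coeffs$coeffs, (e1$coeffs + e2$coeffs) / 2)
  expect_identical(mid$coeffs$size_mm, (e1$size_mm + e2$size_mm) / 2)

  raw <- efd_transform(resample_contour(noisy_seed(seed = 3), 240))
  expect_error(average_contour(list(e1, raw), "mixed"), "normalized")
})

test_that("the average contour of a zero-noise population is the template", {
  tpl <- build_template("heben_like")
  pop <- sample_population(tpl, 10, 0, 0, rng_seed = 2)
  ac <- average_contour(pop$seeds, "heben_ac")
  expect_equal(ac$coeffs$coeffs, tpl$coeffs$coeffs, tolerance = 1e-12)
  expect_equal(ac$coeffs$size_mm, tpl$coeffs$size_mm, tolerance = 1e-12)
})

test_that("models are coefficient midpoints of their member Acs", {
  e1 <- normalize_coeffs(efd_transform(resample_contour(noisy_seed(seed = 4), 240)))
  e2 <- normalize_coeffs(efd_transform(resample_contour(noisy_seed(seed = 5), 240)))
  ac1 <- average_contour(list(e1), "ac1")
  ac2 <- average_contour(list(e2), "ac2")
  mod <- build_model(list(ac1, ac2), "m")
  expect_identical(mod$coeffs$coeffs, (e1$coeffs + e2$coeffs) / 2)
  expect_identical(mod$member_labels, c("ac1", "ac2"))

  mod_same <- build_model(list(ac1, ac1), "m2")
  expect_equal(mod_same$coeffs$coeffs, ac1$coeffs$coeffs)
  expect_error(build_model(list(ac1), "m3"), "at least 2")
})

test_that("reconstruction error shrinks as harmonics are added", {
  for (s in 1:6) {
    con <- noisy_seed("chenin_like", seed = 20 + s, n_points = 300)
    hd <- vapply(c(2, 4, 8), function(h)
      seedmorph:::hausdorff_distance(
        reconstruct(efd_transform(con, h), 300)$points, con$points), 0)
    expect_true(all(diff(hd) <= 1e-9))
  }
})

test_that("harmonic-1-only coefficients reconstruct to an ellipse", {
  e <- efd_transform(ellipse_contour(2, 1, 720), 8, parameterization = "uniform")
  e$coeffs[2:8, ] <- 0
  rc <- reconstruct(e, 240)
  k <- curvature_stats(fit_bezier(extract_lower_profile(rc), 10))
  expect_gt(k$min_curv, 0)        # constant-sign curvature
  m <- measure(rc)
  expect_lt(abs(m$aspect_ratio - 2), 0.01)
})

test_that("coefficient tables carry the standard column layout", {
  tab <- coefficient_table(list(build_template("heben_like")$coeffs))
  expect_identical(names(tab)[1:2], c("label", "A1"))
  expect_length(names(tab), 33)
  expect_identical(names(tab)[c(10, 18, 26)], c("B1", "C1", "D1"))
})
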