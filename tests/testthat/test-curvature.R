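test_that("the lower profile of symmetric shapes is the lower arc, left to right", {
  prof <- extract_lower_profile(circle_contour(1, 360))
  expect_equal(nrow(prof), 181, tolerance = 2)
  expect_true(all(prof[2:(nrow(prof) - 1), 2] < 0))
  expect_true(prof[1, 1] < prof[nrow(prof), 1])

  pe <- extract_lower_profile(ellipse_contour(2, 1, 360))
  expect_equal(pe[1, ], c(-2, 0), tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(pe[nrow(pe), ], c(2, 0), tolerance = 0.01, ignore_attr = TRUE)
})

test_that("Bezier fits reproduce lines and circular arcs", {
  pts <- cbind(seq(0, 5, length.out = 60), seq(1, 3.5, length.out = 60))
  ks <- curvature_stats(fit_bezier(pts, 10))
  expect_lt(max(abs(c(ks$max_curv, ks$min_curv, ks$mean_curv))), 1e-8)

  th <- seq(pi, 2 * pi, length.out = 100)
  arc <- cbind(cos(th), sin(th))
  fit <- fit_bezier(arc, 10)
  expect_lt(fit$rms_residual, 0.01 * pi)     # < 1% of profile length
  ka <- curvature_stats(fit)
  expect_lt(abs(ka$mean_curv - 1), 0.01)
  expect_lt(abs(ka$max_curv - 1), 0.01)

  expect_error(fit_bezier(arc[1:8, ], 10), "degree")
})

test_that("curvature statistics are stable under point density and pose", {
  prof <- extract_lower_profile(reconstruct(build_template("heben_like")$coeffs, 400))
  prof2 <- extract_lower_profile(reconstruct(build_template("heben_like")$coeffs, 800))
  k1 <- curvature_stats(fit_bezier(prof, 10))
  k2 <- curvature_stats(fit_bezier(prof2, 10))
  expect_lt(abs(k2$max_curv - k1$max_curv) / abs(k1$max_curv), 0.02)

  # rotation/translation of the open profile leaves curvature unchanged
  moved <- seedmorph:::rotate_points(prof, 0.03) +
    matrix(c(2, -1), nrow(prof), 2, byrow = TRUE)
  k3 <- curvature_stats(fit_bezier(moved, 10))
  expect_equal(k3$max_curv, k1$max_curv, tolerance = 1e-6)
  expect_equal(k3$min_curv, k1$min_curv, tolerance = 1e-6)
})

test_that("curvature scales as the inverse of uniform scaling", {
  prof <- extract_lower_profile(reconstruct(build_template("chenin_like")$coeffs, 240))
  k1 <- curvature_stats(fit_bezier(prof, 10))
  k2 <- curvature_stats(fit_bezier(prof * 3, 10))
  expect_equal(k2$max_curv, k1$max_curv / 3, tolerance = 1e-8)
  expect_equal(k2$min_curv, k1$min_curv / 3, tolerance = 1e-8)
  expect_equal(k2$max_to_mean_ratio, k1$max_to_mean_ratio, tolerance = 1e-8)
})

test_that("negative minimum curvature flags non-convex beak flanks", {
  k_heben <- seed_curvature(reconstruct(build_template("heben_like")$coeffs, 240))
  expect_lt(k_heben$min_curv, 0)
  k_ell <- curvature_stats(fit_bezier(extract_lower_profile(
    ellipse_contour(1.6, 1, 240)), 10))
  expect_gte(k_ell$min_curv, 0)
  expect_true(k_heben$min_curv <= k_heben$mean_curv)
  expect_true(k_heben$mean_curv <= k_heben$max_curv)
})

test_that("the chenin-like morphotype has the sharper curvature signature", {
  k_h <- seed_curvature(reconstruct(build_template("heben_like")$coeffs, 240))
  k_c <- seed_curvature(reconstruct(build_template("chenin_like")$coeffs, 240))
  expect_gt(abs(k_c$min_curv), abs(k_h$min_curv))
  expect_gt(k_c$max_to_mean_ratio, k_h$max_to_mean_ratio)
})

test_that("reconstructed seed outlines have few non-convex regions", {
  for (m in c("heben_like", "chenin_like", "sylvestris_like")) {
    rc <- reconstruct(build_template(m)$coeffs, 300)
    k <- seed_curvature(rc)
    runs <- rle(sign(k$kappa))
    expect_lte(sum(runs$values < 0), 3)
  }
})
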