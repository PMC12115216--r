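test_that("extraction finds calibrated contours in a binary mask", {
  img <- matrix(0, 14, 14)
  img[3:12, 3:12] <- 1                      # 10 x 10 px filled square
  cons <- extract_contours(img, px_per_mm = 1)
  expect_length(cons, 1)
  expect_lt(abs(seedmorph:::polygon_area(cons[[1]]$points) - 100) / 100, 0.02)
})

test_that("small components are filtered and border-touching ones excluded", {
  img <- matrix(0, 40, 80)
  disc <- function(img, cx, cy, r) {
    for (x in 1:ncol(img)) for (y in 1:nrow(img))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) img[y, x] <- 1
    img
  }
  img <- disc(img, 15, 20, 8)
  img <- disc(img, 40, 20, 8)
  img <- disc(img, 65, 20, 2)               # below min_area
  cons <- extract_contours(img, px_per_mm = 1, min_area_mm2 = 50)
  expect_length(cons, 2)

  img2 <- disc(matrix(0, 40, 40), 20, 1, 6) # touches the top border
  expect_warning(
    expect_message(cons2 <- extract_contours(img2, px_per_mm = 1),
                   "border-touching"),
    "no qualifying")
  expect_length(cons2, 0)
})

test_that("non-binary images are thresholded at the midpoint with a message", {
  img <- matrix(0.1, 20, 20)
  img[6:15, 6:15] <- c(0.8, 0.9)            # two foreground gray levels
  expect_message(cons <- extract_contours(img, px_per_mm = 1), "midpoint")
  expect_length(cons, 1)
})

test_that("TPS files round-trip coordinates and specimen order", {
  tri <- seed_contour(rbind(c(0, 0), c(2, 0), c(1, 1.5)), source_id = "tri")
  sq <- square_contour(2)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(list(tri, sq), path)
  back <- read_tps(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$points, tri$points, tolerance = 1e-6)
  expect_equal(back[[2]]$points, sq$points, tolerance = 1e-6)
  expect_identical(vapply(back, `[[`, "", "source_id"), c("tri", "square"))

  empty <- withr::local_tempfile(fileext = ".tps")
  writeLines(character(), empty)
  expect_identical(read_tps(empty), list())

  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=0", "POINTS=5", "0 0", "1 0", "1 1", "ID=x"), bad)
  expect_error(read_tps(bad), "specimen 1")
})

test_that("arc-length resampling preserves area and perimeter", {
  sq <- square_contour(1)
  rs <- resample_contour(sq, 400)
  expect_identical(nrow(rs$points), 400L)
  expect_lt(abs(seedmorph:::polygon_area(rs$points) - 1), 0.005)

  circ <- circle_contour(1, 1000)
  rs2 <- resample_contour(circ, 128)
  expect_lt(abs(seedmorph:::polygon_perimeter(rs2$points) - 2 * pi) / (2 * pi),
            0.01)

  # idempotence in area
  once <- resample_contour(noisy_seed(), 256)
  twice <- resample_contour(once, 256)
  a1 <- seedmorph:::polygon_area(once$points)
  a2 <- seedmorph:::polygon_area(twice$points)
  expect_lt(abs(a2 - a1) / a1, 0.001)
})

test_that("contours are normalized to counterclockwise orientation", {
  p <- circle_contour(1, 100)$points
  cw <- seed_contour(p[rev(seq_len(nrow(p))), ], source_id = "cw")
  expect_gt(seedmorph:::polygon_signed_area(cw$points), 0)
  # reversal leaves normalized descriptors unchanged
  e1 <- normalize_coeffs(efd_transform(resample_contour(noisy_seed(), 240)))
  rev_pts <- noisy_seed()$points
  rev_c <- seed_contour(rev_pts[rev(seq_len(nrow(rev_pts))), ])
  e2 <- normalize_coeffs(efd_transform(resample_contour(rev_c, 240)))
  expect_equal(e1$coeffs, e2$coeffs, tolerance = 1e-8)
})

test_that("pixel calibration scales coordinates exactly", {
  img <- matrix(0, 14, 14); img[3:12, 3:12] <- 1
  c1 <- extract_contours(img, px_per_mm = 1)[[1]]
  c2 <- extract_contours(img, px_per_mm = 2)[[1]]
  expect_equal(c1$points / 2, c2$points)
})
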