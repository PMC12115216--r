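test_that("Mann-Whitney matches exhaustive enumeration for small samples", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$U, 0)
  expect_equal(res$p, 0.1)                      # 2/20 by enumeration

  set.seed(77)
  for (na in c(2, 4, 7)) for (nb in c(3, 5, 7)) {
    a <- sample(1000, na); b <- sample(2000, nb)  # distinct values, no ties
    res <- mann_whitney(a, b)
    expect_equal(res$p, enumerate_mw_p(a, b), tolerance = 1e-12,
                 label = sprintf("p for n=(%d,%d)", na, nb))
  }
})

test_that("Mann-Whitney symmetry and degenerate input behave as documented", {
  a <- c(3, 9, 14, 20); b <- c(1, 7, 15)
  r1 <- mann_whitney(a, b); r2 <- mann_whitney(b, a)
  expect_equal(r1$p, r2$p)
  expect_identical(r2$U, length(a) * length(b) - r1$U)
  expect_warning(res <- mann_whitney(c(2, 2), c(2, 2)), "identical")
  expect_identical(res$p, 1)
})

test_that("letter codes separate exactly the significant pairs", {
  p2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_identical(unname(letter_codes(p2)), c("a", "a"))
  p2[1, 2] <- p2[2, 1] <- 0.01
  expect_identical(unname(letter_codes(p2)), c("a", "b"))

  # three groups, only pair (1,3) significant: 2 shares a letter with both
  p3 <- matrix(1, 3, 3); p3[1, 3] <- p3[3, 1] <- 0.001
  lt <- letter_codes(p3)
  shares <- function(i, j)
    length(intersect(strsplit(lt[i], "")[[1]], strsplit(lt[j], "")[[1]])) > 0
  expect_false(shares(1, 3))
  expect_true(shares(1, 2))
  expect_true(shares(2, 3))
})

test_that("PCA on collinear data loads everything on one component", {
  set.seed(5)
  u <- rnorm(30)
  tab <- as.data.frame(outer(u, rnorm(32)))
  names(tab) <- c(paste0("A", 1:8), paste0("B", 1:8), paste0("C", 1:8),
                  paste0("D", 1:8))
  res <- pca_fourier(tab)
  expect_equal(res$variance_fraction[1], 1, tolerance = 1e-10)
})

test_that("PCA reconstruction reproduces the centered table", {
  set.seed(6)
  tab <- as.data.frame(matrix(rnorm(40 * 6), 40, 6))
  names(tab) <- paste0("A", 1:6)
  res <- pca_fourier(tab)
  rec <- res$scores %*% t(res$loadings)
  centered <- as.matrix(tab) - matrix(res$center, 40, 6, byrow = TRUE)
  expect_lt(max(abs(rec - centered)), 1e-8)
})

test_that("isotropic data spreads variance evenly and constant columns drop", {
  set.seed(7)
  tab <- as.data.frame(matrix(rnorm(4000 * 4), 4000, 4))
  names(tab) <- paste0("A", 1:4)
  res <- pca_fourier(tab)
  expect_true(all(abs(res$variance_fraction - 0.25) < 0.02))
  expect_true(all(diff(res$variance_fraction) <= 0))

  tab$A5 <- 1
  expect_warning(res2 <- pca_fourier(tab), "constant")
  expect_identical(ncol(res2$loadings), 4L)
})

test_that("group comparison tables carry means, CVs and letters", {
  set.seed(8)
  g1 <- data.frame(metric_a = rnorm(20, 10), metric_b = rnorm(20, 5))
  g2 <- g1
  cmp_same <- compare_groups(list(one = g1, two = g2))
  expect_true(all(tapply(cmp_same$letters, cmp_same$metric,
                         function(x) length(unique(x)) == 1)))

  g3 <- data.frame(metric_a = rnorm(20, 30), metric_b = rnorm(20, 5))
  cmp_diff <- compare_groups(list(one = g1, three = g3))
  pa <- attr(cmp_diff, "pairwise")$metric_a
  expect_lt(pa[1, 2], 0.01)
  la <- cmp_diff$letters[cmp_diff$metric == "metric_a"]
  expect_false(la[1] == la[2])

  expect_warning(compare_groups(list(one = g1, tiny = g1[1, ], three = g3)),
                 "n < 2")
})
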