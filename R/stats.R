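#' Mann-Whitney U test (two-sided)
#'
#' Thin wrapper over [stats::wilcox.test] with the conventions used for
#' group comparisons here: exact p when the smaller sample has at most 8
#' observations and there are no ties, normal approximation with continuity
#' and tie correction otherwise. Two identical samples return p = 1 with a
#' warning.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param exact_max largest min-sample size for which the exact p is used.
#' @return List with `U` (statistic for `sample_a`), `p`, `n_a`, `n_b`,
#'   `method`.
#' @export
mann_whitney <- function(sample_a, sample_b, exact_max = 8) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be non-empty")
  ties <- any(duplicated(c(sample_a, sample_b)))
  if (length(unique(c(sample_a, sample_b))) == 1) {
    warning("all values identical across both samples; p = 1")
    return(list(U = length(sample_a) * length(sample_b) / 2, p = 1,
                n_a = length(sample_a), n_b = length(sample_b),
                method = "degenerate"))
  }
  use_exact <- !ties && min(length(sample_a), length(sample_b)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = use_exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(sample_a), n_b = length(sample_b),
       method = if (use_exact) "exact" else "normal approximation")
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Greedy insertion algorithm: groups not significantly different share at
#' least one letter; each significant pair shares none.
#'
#' @param pairwise_p symmetric matrix of two-sided p-values (diagonal
#'   ignored), dimnames give group names.
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter codes.
#' @export
letter_codes <- function(pairwise_p, alpha = 0.05) {
  g <- nrow(pairwise_p)
  stopifnot(g == ncol(pairwise_p))
  nm <- rownames(pairwise_p) %||% paste0("group", seq_len(g))
  sig <- pairwise_p < alpha
  diag(sig) <- FALSE
  # sets[[k]] = the groups carrying letter k; split every set that holds a
  # significantly different pair, then absorb sets contained in others
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (!sig[i, j]) next
    new_sets <- list()
    for (s in sets) {
      if (all(c(i, j) %in% s))
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      else new_sets <- c(new_sets, list(s))
    }
    new_sets <- unique(new_sets[vapply(new_sets, length, 0L) > 0])
    keep <- vapply(seq_along(new_sets), function(k)
      !any(vapply(seq_along(new_sets), function(l)
        l != k && all(new_sets[[k]] %in% new_sets[[l]]) &&
          length(new_sets[[k]]) < length(new_sets[[l]]), TRUE)), TRUE)
    sets <- new_sets[keep]
  }
  sets <- sets[order(vapply(sets, min, 0L))]
  out <- vapply(seq_len(g), function(i)
    paste(letters[which(vapply(sets, function(s) i %in% s, TRUE))],
          collapse = ""), "")
  stats::setNames(out, nm)
}

#' PCA on a table of elliptic Fourier coefficients
#'
#' Principal component analysis of the per-cultivar coefficient table
#' (columns `A1..A8, B1..B8, C1..C8, D1..D8`). The default is covariance
#' PCA (centered, not variance-scaled): after normalization the
#' coefficients share a common dimensionless scale, so inflating
#' small-amplitude harmonics by scaling is not wanted; correlation PCA is
#' available via `scale.`. Constant columns are dropped with a warning.
#' Group centroids and 95% confidence ellipses for the group *means*
#' (chi-square quantile on the covariance of the mean) are returned for the
#' first two components; mean ellipses are small for large groups and need
#' not contain individual observations.
#'
#' @param coeff_table data frame or matrix of coefficients (rows =
#'   cultivars); a `label` column, if present, is used as row labels.
#' @param group_labels optional factor of group memberships.
#' @param scale. use correlation PCA (default `FALSE`).
#' @return An object of class `pca_fourier`: `scores`, `loadings`,
#'   `variance_fraction`, `centroids`, `ellipses` (per group: center, 2x2
#'   covariance of the mean, squared radius), `groups`.
#' @export
pca_fourier <- function(coeff_table, group_labels = NULL, scale. = FALSE) {
  tab <- as.data.frame(coeff_table)
  labs <- if ("label" %in% names(tab)) tab$label else rownames(tab)
  tab <- tab[vapply(tab, is.numeric, TRUE)]
  if (nrow(tab) < 3) stop("PCA needs at least 3 rows")
  const <- vapply(tab, function(x) stats::var(x) == 0, TRUE)
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(names(tab)[const], collapse = ", ")))
    tab <- tab[!const]
  }
  pc <- stats::prcomp(tab, center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  rownames(scores) <- labs
  out <- list(scores = scores, loadings = pc$rotation,
              variance_fraction = vf, center = pc$center,
              groups = group_labels, centroids = NULL, ellipses = NULL)
  if (!is.null(group_labels)) {
    gl <- factor(group_labels)
    cen <- t(vapply(levels(gl), function(g)
      colMeans(scores[gl == g, 1:2, drop = FALSE]), numeric(2)))
    ell <- lapply(levels(gl), function(g) {
      s2 <- scores[gl == g, 1:2, drop = FALSE]
      n <- nrow(s2)
      list(center = colMeans(s2),
           cov_mean = stats::cov(s2) / n,
           radius2 = stats::qchisq(0.95, df = 2), n = n)
    })
    names(ell) <- levels(gl)
    out$centroids <- cen
    out$ellipses <- ell
  }
  class(out) <- "pca_fourier"
  out
}

#' @export
print.pca_fourier <- function(x, ...) {
  cat(sprintf("PCA on %d x %d coefficient table\n", nrow(x$scores),
              ncol(x$loadings)))
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$variance_fraction[1], 100 * x$variance_fraction[2]))
  invisible(x)
}

#' Does a 95% mean-confidence ellipse contain a point?
#'
#' @param ellipse one element of `pca_fourier$ellipses` (fields `center`,
#'   `cov_mean`, `radius2`).
#' @param point length-2 numeric.
#' @return Logical.
#' @export
ellipse_contains <- function(ellipse, point) {
  d <- point - ellipse$center
  drop(t(d) %*% solve(ellipse$cov_mean) %*% d) <= ellipse$radius2
}

#' Compare metric distributions between groups
#'
#' For each metric: group means and CVs, pairwise Mann-Whitney tests and a
#' compact letter display at alpha = 0.05 (no multiple-testing
#' correction). Groups with fewer than 2 observations are excluded with a
#' warning.
#'
#' @param measurements_by_group named list of data frames (one per group)
#'   sharing numeric metric columns.
#' @param metrics character vector of columns to compare (default: all
#'   shared numeric columns).
#' @param alpha significance level for the letters.
#' @return Data frame with one row per group x metric: `metric`, `group`,
#'   `n`, `mean`, `cv`, `letters`, plus attribute `"pairwise"` holding the
#'   p-value matrices.
#' @export
compare_groups <- function(measurements_by_group, metrics = NULL,
                           alpha = 0.05) {
  stopifnot(is.list(measurements_by_group),
            length(measurements_by_group) >= 2)
  sizes <- vapply(measurements_by_group, nrow, 0L)
  if (any(sizes < 2)) {
    warning(sprintf("excluding group(s) with n < 2: %s",
                    paste(names(measurements_by_group)[sizes < 2],
                          collapse = ", ")))
    measurements_by_group <- measurements_by_group[sizes >= 2]
  }
  gnames <- names(measurements_by_group)
  if (is.null(metrics)) {
    num <- lapply(measurements_by_group, function(d)
      names(d)[vapply(d, is.numeric, TRUE)])
    metrics <- Reduce(intersect, num)
  }
  rows <- list(); pmats <- list()
  for (m in metrics) {
    vals <- lapply(measurements_by_group, `[[`, m)
    ng <- length(vals)
    pm <- matrix(1, ng, ng, dimnames = list(gnames, gnames))
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng)
      pm[i, j] <- pm[j, i] <-
        suppressWarnings(mann_whitney(vals[[i]], vals[[j]])$p)
    lt <- letter_codes(pm, alpha)
    pmats[[m]] <- pm
    for (g in seq_along(gnames)) {
      v <- vals[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = gnames[g], n = length(v), mean = mean(v),
        cv = if (mean(v) != 0) 100 * stats::sd(v) / mean(v) else 0,
        letters = lt[g], row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pairwise") <- pmats
  out
}
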