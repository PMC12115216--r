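#' Split cultivars into high and low aspect-ratio classes
#'
#' The observed range of population aspect ratios splits into a high band
#' (roughly 1.58-2.40) and a low band (roughly 1.28-1.57). The boundary is
#' 1.575 so that values rounding to 1.58 fall in the high class; AR is
#' rounded to 2 decimals before the comparison, matching the reporting
#' precision that defines the bands.
#'
#' @param cultivar_ars named numeric vector of aspect ratios (>= 1).
#' @param boundary class boundary (default 1.575).
#' @return Named character vector, `"high"` or `"low"` per cultivar.
#' @export
split_by_aspect_ratio <- function(cultivar_ars, boundary = 1.575) {
  stopifnot(all(cultivar_ars >= 1))
  out <- ifelse(round(cultivar_ars, 2) >= boundary, "high", "low")
  names(out) <- names(cultivar_ars)
  out
}

#' Rank cultivars by AR class and descending solidity
#'
#' The catalogue ordering: the high-AR class first, within it by descending
#' solidity, then the low-AR class by descending solidity. Ties are broken
#' alphabetically by cultivar name so the ordering is deterministic.
#'
#' @param cultivars data frame with columns `name`, `ar_class`
#'   (`"high"`/`"low"`) and `solidity`.
#' @return The data frame with an added integer `rank` column, sorted by
#'   rank.
#' @export
order_by_solidity <- function(cultivars) {
  stopifnot(all(c("name", "ar_class", "solidity") %in% names(cultivars)))
  o <- order(factor(cultivars$ar_class, levels = c("high", "low")),
             -cultivars$solidity, cultivars$name)
  out <- cultivars[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign a morphotype group from two J-index values
#'
#' Threshold rules on the J-index of a cultivar's average contour against
#' the two reference models: Group 1 if both values are below 90 (strict);
#' otherwise Group 2 (3) if the J with the first (second) model exceeds 94
#' (strict); values in \[90, 94\] with neither model above 94 fall in Group
#' 4, split into 4a (first model scores at least as high) and 4b. When both
#' models exceed 94 the larger J wins, with ties going to Group 2 -- the
#' threshold rules alone do not cover that corner, so the resolution is
#' recorded here as the package's convention.
#'
#' @param j_heben,j_chenin J-index values in \[0, 100\] against the first
#'   (Heben-type) and second (Chenin-type) model.
#' @param lower,upper group thresholds (defaults 90 and 94).
#' @return One of `"G1"`, `"G2"`, `"G3"`, `"G4a"`, `"G4b"` (vectorized).
#' @export
assign_group <- function(j_heben, j_chenin, lower = 90, upper = 94) {
  stopifnot(lower < upper)
  if (any(j_heben < 0 | j_heben > 100 | j_chenin < 0 | j_chenin > 100))
    stop("J-index values must lie in [0, 100]")
  out <- character(length(j_heben))
  for (i in seq_along(j_heben)) {
    jh <- j_heben[i]; jc <- j_chenin[i]
    out[i] <-
      if (jh < lower && jc < lower) "G1"
      else if (jh > upper && (jc <= upper || jh >= jc)) "G2"
      else if (jc > upper) "G3"
      else if (jh >= jc) "G4a"
      else "G4b"
  }
  out
}

#' Classify a set of cultivars from their summary table
#'
#' Combines the AR split, the solidity ordering and the J-index group
#' rules into one table.
#'
#' @param tab data frame with columns `name`, `aspect_ratio`, `solidity`,
#'   `j_heben`, `j_chenin`.
#' @param ar_boundary boundary for [split_by_aspect_ratio].
#' @param lower,upper thresholds for [assign_group].
#' @return Data frame adding `ar_class`, `rank`, `group`, sorted by rank.
#' @export
classify_cultivars <- function(tab, ar_boundary = 1.575, lower = 90,
                               upper = 94) {
  stopifnot(all(c("name", "aspect_ratio", "solidity", "j_heben", "j_chenin")
                %in% names(tab)))
  tab$ar_class <- unname(split_by_aspect_ratio(
    stats::setNames(tab$aspect_ratio, tab$name), ar_boundary))
  tab <- order_by_solidity(tab)
  tab$group <- assign_group(tab$j_heben, tab$j_chenin, lower, upper)
  tab
}
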