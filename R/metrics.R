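#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table \eqn{n_{ij}} with row sums \eqn{a_i}
#' and column sums \eqn{b_j}:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - [\sum_i\binom{a_i}{2}
#'   \sum_j\binom{b_j}{2}]/\binom{n}{2}}{\frac12[\sum_i\binom{a_i}{2} +
#'   \sum_j\binom{b_j}{2}] - [\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}]
#'   /\binom{n}{2}}}
#' The two partitions need not have the same number of clusters; the index is
#' 1 for identical partitions up to relabeling, symmetric in its arguments,
#' and invariant to label permutation. In the degenerate case where both
#' partitions put all items in one cluster the formula is 0/0; the partitions
#' are then identical and 1 is returned.
#'
#' @param p,q label vectors of equal length (>= 2); any label type.
#' @return the ARI, a real number `<= 1`.
#' @export
adjusted_rand_index <- function(p, q) {
  if (length(p) != length(q))
    stop("partitions must have equal length", call. = FALSE)
  if (length(p) < 2) stop("need at least 2 items", call. = FALSE)
  tab <- table(p, q)
  choose2 <- function(x) x * (x - 1) / 2
  index <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  expected <- a * b / choose2(length(p))
  maximum <- (a + b) / 2
  if (maximum == expected) return(1) # both single-cluster (or equivalent)
  (index - expected) / (maximum - expected)
}
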