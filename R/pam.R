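#' BUILD initialization for PAM
#'
#' Greedy deterministic initialization: the first medoid is the point with
#' the smallest total dissimilarity to all points; each subsequent medoid is
#' the point whose addition maximally reduces the objective
#' \eqn{TD = \sum_i d(x_i, nearest\ medoid)}. All ties are broken by the
#' lowest cell index.
#'
#' @param D a `DissimilarityMatrix`.
#' @param k number of medoids, `1 <= k <= n`.
#' @return a list with `medoids` (1-based cell indices, in selection order),
#'   `d_nearest`, `td`, and `td_trace` (TD after each addition).
#' @export
pam_build <- function(D, k) {
  k <- as.integer(k)
  if (k < 1 || k > D$n) stop("k must be between 1 and n", call. = FALSE)
  res <- cpp_pam_build(D$data, D$n, k)
  list(medoids = res$medoids + 1L, d_nearest = res$d_nearest,
       td = res$td, td_trace = res$td_trace)
}

#' FASTPAM1 swap phase
#'
#' Deterministic swap phase: at each iteration every (non-medoid, medoid)
#' exchange is scored in a single pass over the points using cached
#' distances to the nearest (`d_nearest`) and second-nearest (`d_second`)
#' medoid, and the single swap with the largest strict TD reduction is
#' applied. Stops when no swap reduces TD (strict `> 0` reduction in double
#' precision) or after `max_iter` iterations.
#'
#' @param D a `DissimilarityMatrix`.
#' @param medoids initial 1-based medoid cell indices (distinct).
#' @param max_iter iteration cap; a result that hits it without reaching a
#'   local optimum is flagged `converged = FALSE`.
#' @return a `PamResult`: list with `medoids`, `labels` (cluster index in
#'   `1..k`, the position of the assigned medoid), `td`, `iterations`,
#'   `td_trace` (TD before the first swap and after each swap, strictly
#'   decreasing), `converged`.
#' @export
pam_fastpam1 <- function(D, medoids, max_iter = 1000L) {
  medoids <- as.integer(medoids)
  if (anyDuplicated(medoids) || any(medoids < 1L) || any(medoids > D$n))
    stop("medoids must be distinct indices in 1..n", call. = FALSE)
  res <- cpp_fastpam1(D$data, D$n, medoids - 1L, as.integer(max_iter))
  medo <- res$medoids + 1L
  out <- list(medoids = medo,
              labels = cpp_assign(D$data, D$n, medo - 1L) + 1L,
              td = res$td, iterations = res$iterations,
              td_trace = res$td_trace, converged = res$converged,
              ids = D$ids)
  class(out) <- "PamResult"
  out
}

#' PAM clustering (initialization + FASTPAM1 swaps)
#'
#' `init = "BUILD"` gives the fully deterministic PAM-BS variant. `init =
#' "LAB"` (linear approximate BUILD) picks each medoid greedily from a random
#' subsample of `10 + ceiling(sqrt(n))` candidate/reference points, trading
#' initialization quality for speed; it consumes the seed.
#'
#' @param D a `DissimilarityMatrix`.
#' @param k number of clusters.
#' @param init `"BUILD"` (default) or `"LAB"`.
#' @param max_iter swap-iteration cap.
#' @param seed RNG seed, used by LAB only.
#' @return a `PamResult` (see [pam_fastpam1()]).
#' @export
pam <- function(D, k, init = c("BUILD", "LAB"), max_iter = 1000L, seed = 1L) {
  init <- match.arg(init)
  med0 <- if (init == "BUILD") pam_build(D, k)$medoids
          else lab_init(D, k, seed)
  pam_fastpam1(D, med0, max_iter = max_iter)
}

# LAB: BUILD restricted to a fresh random subsample of size 10 + ceil(sqrt(n))
# per medoid; reductions are evaluated over the subsample only.
lab_init <- function(D, k, seed) {
  n <- D$n
  s <- min(n, 10L + as.integer(ceiling(sqrt(n))))
  med <- integer(0)
  dnear <- rep(Inf, n)
  with_local_seed(seed, {
    for (step in seq_len(k)) {
      pool <- setdiff(seq_len(n), med)
      sub <- sort(sample(pool, min(s, length(pool))))
      best <- -Inf
      bc <- sub[1]
      for (c in sub) {
        drow <- cpp_diss_row(D$data, n, c - 1L)
        red <- if (step == 1) -sum(drow[sub]) else
          sum(pmax(dnear[sub] - drow[sub], 0))
        if (red > best) { best <- red; bc <- c }
      }
      med <- c(med, bc)
      drow <- cpp_diss_row(D$data, n, bc - 1L)
      dnear <- pmin(dnear, drow)
    }
  })
  med
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Nearest-medoid label assignment
#'
#' Assigns each cell to its nearest medoid; ties go to the medoid with the
#' lower cell index.
#'
#' @param D a `DissimilarityMatrix`.
#' @param medoids 1-based medoid cell indices.
#' @return integer labels in `1..k` (position of the assigned medoid).
#' @export
assign_labels <- function(D, medoids) {
  cpp_assign(D$data, D$n, as.integer(medoids) - 1L) + 1L
}

#' Recompute the TD objective for a medoid set
#' @param D a `DissimilarityMatrix`.
#' @param medoids 1-based medoid cell indices.
#' @return sum over cells of the dissimilarity to the nearest medoid.
#' @export
td_objective <- function(D, medoids) {
  sum(vapply(seq_len(D$n), function(i) min(diss(D, i, medoids)), numeric(1)))
}

#' Swap gain table at a medoid configuration
#'
#' Exposes FASTPAM1's incremental bookkeeping: entry `(c, m)` is the TD
#' change of swapping non-medoid cell `c` in for `medoids[m]` (negative =
#' improvement), computed from the cached nearest / second-nearest distances
#' exactly as the swap phase does. Rows of current medoids are `NA`.
#'
#' @param D a `DissimilarityMatrix`.
#' @param medoids 1-based medoid cell indices.
#' @return an `n x k` numeric matrix of TD deltas.
#' @export
swap_gain_table <- function(D, medoids) {
  cpp_swap_deltas(D$data, D$n, as.integer(medoids) - 1L)
}

#' @exportS3Method base::print
print.PamResult <- function(x, ...) {
  cat(sprintf("PamResult: k = %d, n = %d, TD = %.6g, %d swap iteration(s)%s\n",
              length(x$medoids), length(x$labels), x$td, x$iterations,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}
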