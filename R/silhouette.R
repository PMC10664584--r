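#' Per-cell silhouette widths
#'
#' For cell \eqn{i} in cluster \eqn{I}: \eqn{a(i)} is its mean dissimilarity
#' to the other members of \eqn{I}, \eqn{b(i)} the minimum over other
#' clusters \eqn{J} of its mean dissimilarity to the members of \eqn{J}, and
#' \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} when \eqn{|I| > 1} and 0
#' otherwise (singletons). Values lie in \eqn{[-1, 1]}; close to +1 means the
#' cell sits well inside its cluster.
#'
#' @param D a `DissimilarityMatrix`.
#' @param labels per-cell cluster labels (any type; coerced to consecutive
#'   integer codes).
#' @param workers accepted for interface symmetry; the computation is
#'   per-cell independent, so the result never depends on it.
#' @return a `SilhouetteResult`: list with `s` (per-cell widths),
#'   `cluster_mean` (named by cluster), and `global_mean`.
#' @export
silhouette <- function(D, labels, workers = 1L) {
  if (length(labels) != D$n)
    stop("labels must have one entry per cell", call. = FALSE)
  f <- factor(labels)
  if (nlevels(f) < 2)
    warning("only one cluster present; all silhouette values are 0")
  codes <- as.integer(f) - 1L
  s <- cpp_silhouette(D$data, D$n, codes, nlevels(f))
  cm <- tapply(s, f, mean)
  out <- list(s = as.numeric(s),
              cluster_mean = cm[levels(f)],
              global_mean = mean(s))
  class(out) <- "SilhouetteResult"
  out
}

#' @exportS3Method base::print
print.SilhouetteResult <- function(x, ...) {
  cat(sprintf("SilhouetteResult: %d cells, %d clusters, mean s = %.4f\n",
              length(x$s), length(x$cluster_mean), x$global_mean))
  invisible(x)
}

#' Iterative silhouette-based cell filter
#'
#' Repeats: compute silhouettes; if at least `target_frac` of the current
#' cells have silhouette strictly greater than `threshold`, stop; otherwise
#' drop the `floor(drop_frac * n_current)` (at least 1) cells with the lowest
#' silhouette — ties at the drop boundary resolved by lower cell index — and
#' optionally re-cluster the survivors by re-running PAM on the extracted
#' dissimilarity submatrix (pairwise values are copied, never recomputed).
#' The defaults implement the rule "remove the 15% of cells with the lowest
#' silhouette until at least 60% of the remaining cells have silhouette
#' higher than 0.7". The loop terminates because each round strictly reduces
#' the cell count; if cells run out before the criterion is met, the last
#' state with at least 2 cells is returned flagged `met = FALSE`.
#'
#' @param D a `DissimilarityMatrix`.
#' @param labels initial per-cell cluster labels.
#' @param drop_frac fraction of current cells removed per round (0 < x < 1).
#' @param target_frac required fraction of cells above `threshold`.
#' @param threshold silhouette threshold (strictly-greater comparison).
#' @param recluster `NULL` to keep (subset) the incoming labels, or a list of
#'   [pam()] arguments (at least `k`) to re-run PAM each round.
#' @return list with `kept` (1-based indices into the original cells),
#'   `labels` (for the survivors), `met` (criterion reached?), `n_rounds`,
#'   and `history` (data frame of per-round cell counts and pass fractions).
#' @export
silhouette_filter <- function(D, labels, drop_frac = 0.15, target_frac = 0.60,
                              threshold = 0.7, recluster = NULL) {
  stopifnot(drop_frac > 0, drop_frac < 1)
  kept <- seq_len(D$n)
  cur_D <- D
  cur_labels <- labels
  history <- data.frame(round = integer(0), n_cells = integer(0),
                        frac_above = numeric(0))
  round <- 0L
  repeat {
    sil <- silhouette(cur_D, cur_labels)
    frac <- mean(sil$s > threshold)
    history <- rbind(history,
                     data.frame(round = round, n_cells = length(kept),
                                frac_above = frac))
    if (frac >= target_frac)
      return(list(kept = kept, labels = cur_labels, met = TRUE,
                  n_rounds = round, history = history))
    n_drop <- max(1L, floor(drop_frac * length(kept)))
    if (length(kept) - n_drop < 2)
      return(list(kept = kept, labels = cur_labels, met = FALSE,
                  n_rounds = round, history = history))
    # lowest silhouettes out; ties at the boundary -> lower cell index
    drop_local <- order(sil$s, seq_along(sil$s))[seq_len(n_drop)]
    keep_local <- setdiff(seq_along(kept), drop_local)
    kept <- kept[keep_local]
    cur_D <- subset_dissimilarity(cur_D, keep_local)
    if (is.null(recluster)) {
      cur_labels <- cur_labels[keep_local]
    } else {
      args <- recluster
      args$k <- min(args$k, cur_D$n)
      fit <- do.call(pam, c(list(D = cur_D), args))
      cur_labels <- fit$labels
    }
    round <- round + 1L
  }
}

#' Mean silhouette across a range of k
#'
#' Convenience scan used to guide the choice of the number of clusters:
#' clusters each k with PAM-BS and reports the global mean silhouette.
#'
#' @param D a `DissimilarityMatrix`.
#' @param ks integer vector of cluster numbers to try.
#' @param ... passed to [pam()].
#' @return data frame with columns `k`, `mean_silhouette`, `td`.
#' @export
silhouette_by_k <- function(D, ks, ...) {
  rows <- lapply(ks, function(k) {
    fit <- pam(D, k, ...)
    data.frame(k = k, mean_silhouette = silhouette(D, fit$labels)$global_mean,
               td = fit$td)
  })
  do.call(rbind, rows)
}
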