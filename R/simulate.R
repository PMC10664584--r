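#' Simulation configuration
#'
#' Parameters of the synthetic single-cell experiment generator. Defaults
#' describe a small, well-separated three-population tissue: each cluster has
#' 10 private marker genes whose mean is `exp(3)` (about 20-fold) above the
#' base mean, counts are negative binomial with variance
#' \eqn{\mu + \phi\mu^2}, and per-sample cell numbers are drawn log-normally
#' around the target to mimic uneven library sizes.
#'
#' @param n_cells total cells targeted across all samples.
#' @param n_genes number of genes.
#' @param k_true number of true cell populations.
#' @param n_markers_per_cluster private marker genes per population
#'   (`k_true * n_markers_per_cluster <= n_genes`).
#' @param marker_log_fold natural-log fold change of marker means.
#' @param base_mean baseline NB mean per gene.
#' @param nb_dispersion NB dispersion \eqn{\phi} (variance
#'   \eqn{\mu + \phi\mu^2}).
#' @param n_samples_per_condition samples in each of the two conditions
#'   (condition = the binary time2 phenotype).
#' @param condition_effect per-cluster log-fold abundance shift applied to
#'   condition 1 through a softmax on the cluster probabilities.
#' @param seed RNG seed.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_cells = 600, n_genes = 120, k_true = 3,
                       n_markers_per_cluster = 10, marker_log_fold = 3,
                       base_mean = 1, nb_dispersion = 0.3,
                       n_samples_per_condition = 4,
                       condition_effect = rep(0, k_true), seed = 1) {
  stopifnot(n_cells > 0, n_genes > 0, k_true > 0, n_markers_per_cluster >= 0,
            base_mean > 0, nb_dispersion > 0, n_samples_per_condition > 0)
  if (k_true * n_markers_per_cluster > n_genes)
    stop("infeasible config: k_true * n_markers_per_cluster exceeds n_genes",
         call. = FALSE)
  condition_effect <- rep_len(condition_effect, k_true)
  structure(list(n_cells = n_cells, n_genes = n_genes, k_true = k_true,
                 n_markers_per_cluster = n_markers_per_cluster,
                 marker_log_fold = marker_log_fold, base_mean = base_mean,
                 nb_dispersion = nb_dispersion,
                 n_samples_per_condition = n_samples_per_condition,
                 condition_effect = condition_effect, seed = seed),
            class = "SimConfig")
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

sim_sample_metadata <- function(n_per_condition) {
  ns <- 2 * n_per_condition
  cond <- rep(0:1, each = n_per_condition)
  # days bracket the day-20 split; phases follow the canonical labels
  day <- ifelse(cond == 0, 15 + seq_len(ns) %% 6, 21 + seq_len(ns) %% 6)
  phase <- ifelse(cond == 0, ifelse(seq_len(ns) %% 2 == 0, 3, 4), 5)
  sample_metadata(sprintf("S%02d", seq_len(ns)), day = day, phase = phase)
}

#' Simulate a single-cell experiment with known structure
#'
#' Draws, for each sample, a log-normal number of cells around the per-sample
#' target; assigns each cell to one of `k_true` populations with
#' probabilities `softmax(log(1/k) + time2 * condition_effect)`; and draws
#' gene counts from a negative binomial whose mean is the population's
#' expression profile (base mean, multiplied by `exp(marker_log_fold)` on
#' that population's private markers). Fully reproducible from the seed.
#'
#' @param cfg a `SimConfig`.
#' @return list with `matrix` (an `ExpressionMatrix`), `labels` (true
#'   population of each cell), and `metadata` (a `SampleMetadata` table).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_local_seed(cfg$seed, {
    meta <- sim_sample_metadata(cfg$n_samples_per_condition)
    ns <- nrow(meta)
    target <- cfg$n_cells / ns
    cells_per_sample <- pmax(1L, round(exp(rnorm(ns, log(target), 0.2))))

    k <- cfg$k_true
    mu <- matrix(cfg$base_mean, k, cfg$n_genes)
    if (cfg$n_markers_per_cluster > 0)
      for (cl in seq_len(k)) {
        mk <- (cl - 1) * cfg$n_markers_per_cluster +
          seq_len(cfg$n_markers_per_cluster)
        mu[cl, mk] <- cfg$base_mean * exp(cfg$marker_log_fold)
      }

    labels <- integer(0)
    samples <- character(0)
    for (s in seq_len(ns)) {
      pr <- softmax(log(rep(1 / k, k)) +
                    meta$time2[s] * cfg$condition_effect)
      nc <- cells_per_sample[s]
      labels <- c(labels, sample.int(k, nc, replace = TRUE, prob = pr))
      samples <- c(samples, rep(meta$sample_id[s], nc))
    }
    n <- length(labels)
    counts <- matrix(rnbinom(n * cfg$n_genes,
                             mu = mu[labels, , drop = FALSE],
                             size = 1 / cfg$nb_dispersion),
                     nrow = n)
    m <- expression_matrix(counts,
                           cell_ids = sprintf("c%05d", seq_len(n)),
                           gene_ids = sprintf("g%04d", seq_len(cfg$n_genes)),
                           sample_of_cell = samples)
    list(matrix = m, labels = labels, metadata = meta)
  })
}

#' Simulate a cluster-by-sample abundance table
#'
#' Generates the count table the differential-abundance models consume,
#' without simulating expression. Two generators are available:
#' `"multinomial"` draws each sample's cells from a multinomial with
#' softmax-shifted cluster probabilities (the same abundance model as
#' [simulate_experiment()]); `"nb"` draws each cluster/sample count from a
#' negative binomial with mean `lib_size * proportion`, adding
#' extra-multinomial noise. In both cases the attribute `true_beta` records
#' the realized per-cluster natural-log proportion ratios
#' `log(p1 / p0)` between the two conditions — the estimand of the NB GLM
#' with a total-cells offset (note that under a softmax shift of `effect` on
#' one cluster this differs from `effect` itself, because the remaining
#' proportions renormalize).
#'
#' @param n_clusters number of clusters.
#' @param samples_per_condition samples in each of the two conditions.
#' @param cells_per_sample expected cells per sample.
#' @param effect per-cluster log-fold shift applied to condition 1 (softmax).
#' @param model `"multinomial"` or `"nb"`.
#' @param nb_dispersion NB dispersion for `model = "nb"`.
#' @param seed RNG seed.
#' @return an `AbundanceTable` with attribute `true_beta`.
#' @export
simulate_abundance <- function(n_clusters = 10, samples_per_condition = 8,
                               cells_per_sample = 2000,
                               effect = rep(0, n_clusters),
                               model = c("multinomial", "nb"),
                               nb_dispersion = 0.05, seed = 1) {
  model <- match.arg(model)
  effect <- rep_len(effect, n_clusters)
  with_local_seed(seed, {
    meta <- sim_sample_metadata(samples_per_condition)
    ns <- nrow(meta)
    base <- log(rep(1 / n_clusters, n_clusters))
    p0 <- softmax(base)
    p1 <- softmax(base + effect)
    counts <- matrix(0L, n_clusters, ns,
                     dimnames = list(seq_len(n_clusters), meta$sample_id))
    for (s in seq_len(ns)) {
      pr <- if (meta$time2[s] == 1) p1 else p0
      if (model == "multinomial") {
        counts[, s] <- as.integer(rmultinom(1, cells_per_sample, pr))
      } else {
        lib <- max(1, round(exp(rnorm(1, log(cells_per_sample), 0.2))))
        counts[, s] <- rnbinom(n_clusters, mu = lib * pr,
                               size = 1 / nb_dispersion)
      }
    }
    tab <- structure(list(counts = counts, metadata = meta),
                     class = "AbundanceTable")
    attr(tab, "true_beta") <- log(p1 / p0)
    tab
  })
}
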