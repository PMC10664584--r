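#' Cluster-by-sample cell count table
#'
#' Tabulates clustered cells into a cluster x sample matrix joined to the
#' sample metadata. Every sample present in `meta` gets a column (zero if no
#' cell of it was clustered), and every observed cluster a row, so column
#' sums equal the number of clustered cells per sample.
#'
#' @param labels per-cell cluster labels.
#' @param cell_sample_ids per-cell sample identifiers (same length).
#' @param meta a `SampleMetadata` table covering all sample ids.
#' @return an `AbundanceTable`: list with `counts` (cluster x sample integer
#'   matrix) and `metadata` (rows aligned with the columns of `counts`).
#' @export
cluster_sample_counts <- function(labels, cell_sample_ids, meta) {
  if (length(labels) == 0) stop("empty label set", call. = FALSE)
  if (length(labels) != length(cell_sample_ids))
    stop("labels and cell_sample_ids must have equal length", call. = FALSE)
  unknown <- setdiff(unique(cell_sample_ids), meta$sample_id)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  counts <- table(cluster = factor(labels),
                  sample = factor(cell_sample_ids, levels = meta$sample_id))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(counts = counts, metadata = meta), class = "AbundanceTable")
}

#' @exportS3Method base::print
print.AbundanceTable <- function(x, ...) {
  cat(sprintf("AbundanceTable: %d clusters x %d samples (%s cells)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# Design matrices for the three supported models. time uses the numeric day
# of the cycle; time2 the 0/1 split at day 20; phase a treatment-coded factor
# with the lowest level as reference.
build_design <- function(meta, design = c("time", "time2", "phase")) {
  design <- match.arg(design)
  dm <- switch(design,
    time = {
      if (any(is.na(meta$day))) stop("design 'time' needs day for every sample",
                                     call. = FALSE)
      model.matrix(~day, data = meta)
    },
    time2 = {
      if (any(is.na(meta$time2)))
        stop("design 'time2' needs time2 (or day) for every sample",
             call. = FALSE)
      model.matrix(~time2, data = meta)
    },
    phase = {
      ph <- droplevels(factor(meta$phase))
      if (nlevels(ph) < 2)
        stop("design 'phase' needs at least 2 observed levels", call. = FALSE)
      model.matrix(~ph)
    })
  if (qr(dm)$rank < ncol(dm))
    stop("design matrix is not of full rank", call. = FALSE)
  dm
}

fit_dgelist <- function(tab, dm, dispersion = c("common", "tagwise"),
                        lib_size = NULL) {
  dispersion <- match.arg(dispersion)
  if (ncol(tab$counts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(lib_size)) lib_size <- pmax(colSums(tab$counts), 1)
  y <- edgeR::DGEList(counts = tab$counts, lib.size = lib_size)
  y <- edgeR::estimateGLMCommonDisp(y, dm)
  if (is.na(y$common.dispersion)) y$common.dispersion <- 0.05
  if (dispersion == "tagwise")
    y <- edgeR::estimateGLMTagwiseDisp(y, dm)
  y
}

da_result <- function(tab, fit_table, stat_col, test_kind, design_name, df,
                      dispersion) {
  all_zero <- rowSums(tab$counts) == 0
  p <- fit_table$PValue
  p[all_zero] <- 1
  est <- if ("logFC" %in% names(fit_table)) fit_table$logFC * log(2) else NA_real_
  out <- data.frame(cluster = rownames(tab$counts),
                    estimate = est,
                    dispersion = dispersion,
                    stat = pmax(fit_table[[stat_col]], 0),
                    df = df,
                    p = p,
                    q = p.adjust(p, method = "BH"),
                    all_zero = all_zero,
                    row.names = NULL)
  attr(out, "test_kind") <- test_kind
  attr(out, "design_name") <- design_name
  class(out) <- c("DAResult", "data.frame")
  out
}

#' Differential abundance: negative binomial likelihood-ratio test
#'
#' Fits, per cluster, a negative binomial GLM with log link to the
#' cluster-by-sample cell counts, with offset `log(total clustered cells per
#' sample)` (counts are compositional within a sample, so the sample's cell
#' total is the exposure; no further normalization factors are applied). The
#' null hypothesis that the tested coefficient(s) are zero is assessed with a
#' likelihood-ratio chi-square test (df = number of tested coefficients: 1
#' for `time` / `time2`, 2 for the joint `phase` test, 1 per pairwise
#' contrast), and p-values are Benjamini-Hochberg adjusted across clusters.
#' Fitting, dispersion estimation (common Cox-Reid profile dispersion, with
#' optional tagwise shrinkage) and testing are delegated to edgeR.
#'
#' Reported `estimate` is the natural-log fold change of the tested
#' coefficient (NA for multi-df tests); `q` is the BH-adjusted p-value.
#' All-zero clusters get p = 1 and are flagged in the `all_zero` column.
#'
#' @param tab an `AbundanceTable`.
#' @param design `"time"`, `"time2"` or `"phase"`.
#' @param coef columns of the design matrix to test; defaults to all
#'   non-intercept columns. `integer(0)` tests nothing (statistic 0, p = 1).
#' @param contrast optional numeric contrast vector (overrides `coef`).
#' @param dispersion `"common"` (default) or `"tagwise"`.
#' @param lib_size optional per-sample exposure overriding the column totals
#'   (the offset is its log); the test statistic is invariant to scaling it
#'   by a constant.
#' @return a `DAResult` data frame.
#' @export
nb_glm_lrt <- function(tab, design = c("time", "time2", "phase"), coef = NULL,
                       contrast = NULL, dispersion = c("common", "tagwise"),
                       lib_size = NULL) {
  design <- match.arg(design)
  dm <- build_design(tab$metadata, design)
  y <- fit_dgelist(tab, dm, dispersion, lib_size)
  fit <- edgeR::glmFit(y, dm)
  if (is.null(coef) && is.null(contrast)) coef <- seq_len(ncol(dm))[-1]
  if (!is.null(contrast)) {
    res <- edgeR::glmLRT(fit, contrast = contrast)
    df <- 1L
  } else if (length(coef) == 0) {
    k <- nrow(tab$counts)
    tabres <- data.frame(logFC = rep(0, k), LR = rep(0, k),
                         PValue = rep(1, k))
    return(da_result(tab, tabres, "LR", "LRT",
                     paste0(design, "_null"), 0L, y$common.dispersion))
  } else {
    res <- edgeR::glmLRT(fit, coef = coef)
    df <- length(coef)
  }
  name <- if (design == "phase" && df > 1) "phase_joint" else design
  da_result(tab, res$table, "LR", "LRT", name, df, y$common.dispersion)
}

#' Differential abundance: quasi-likelihood F-test
#'
#' Same models and offsets as [nb_glm_lrt()], but inference uses edgeR's
#' quasi-likelihood framework: cluster-wise quasi-dispersions are estimated
#' and empirical-Bayes squeezed, and coefficients are tested with an F-test,
#' which accounts for the uncertainty of the dispersion estimates and is the
#' more conservative of the two procedures. Requires at least one residual
#' degree of freedom (more samples than design columns).
#'
#' @inheritParams nb_glm_lrt
#' @return a `DAResult` data frame.
#' @export
nb_glm_ql <- function(tab, design = c("time", "time2", "phase"), coef = NULL,
                      contrast = NULL, dispersion = c("common", "tagwise"),
                      lib_size = NULL) {
  design <- match.arg(design)
  dm <- build_design(tab$metadata, design)
  if (ncol(tab$counts) - ncol(dm) < 1)
    stop("quasi-likelihood test needs residual df >= 1 (more samples than ",
         "design columns)", call. = FALSE)
  y <- fit_dgelist(tab, dm, dispersion, lib_size)
  fit <- edgeR::glmQLFit(y, dm)
  if (is.null(coef) && is.null(contrast)) coef <- seq_len(ncol(dm))[-1]
  if (!is.null(contrast)) {
    res <- edgeR::glmQLFTest(fit, contrast = contrast)
    df <- 1L
  } else if (length(coef) == 0) {
    k <- nrow(tab$counts)
    tabres <- data.frame(logFC = rep(0, k), F = rep(0, k), PValue = rep(1, k))
    return(da_result(tab, tabres, "F", "QL",
                     paste0(design, "_null"), 0L, y$common.dispersion))
  } else {
    res <- edgeR::glmQLFTest(fit, coef = coef)
    df <- length(coef)
  }
  name <- if (design == "phase" && df > 1) "phase_joint" else design
  da_result(tab, res$table, "F", "QL", name, df, y$common.dispersion)
}

#' Pairwise phase contrasts
#'
#' One 1-df test per unordered pair of observed phase levels, on the
#' treatment (dummy) coding of the phase factor. Declared levels with no
#' samples are skipped with a warning.
#'
#' @param tab an `AbundanceTable` whose metadata has a phase column with at
#'   least 2 observed levels.
#' @param test `"lrt"` or `"ql"`.
#' @param dispersion passed through to the fitting function.
#' @return named list of `DAResult` objects, one per level pair
#'   (`"A_vs_B"`).
#' @export
phase_contrasts <- function(tab, test = c("lrt", "ql"),
                            dispersion = c("common", "tagwise")) {
  test <- match.arg(test)
  ph_all <- tab$metadata$phase
  if (!is.factor(ph_all)) ph_all <- factor(ph_all)
  empty <- setdiff(levels(ph_all), levels(droplevels(ph_all)))
  if (length(empty))
    warning("phase level(s) without samples skipped: ",
            paste(empty, collapse = ", "))
  ph <- droplevels(ph_all)
  lev <- levels(ph)
  if (length(lev) < 2) stop("need at least 2 observed phase levels",
                            call. = FALSE)
  dm <- build_design(tab$metadata, "phase")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  fitter <- if (test == "lrt") nb_glm_lrt else nb_glm_ql
  out <- lapply(pairs, function(pr) {
    colv <- function(l) {
      v <- numeric(ncol(dm))
      cn <- paste0("ph", l)
      if (cn %in% colnames(dm)) v[colnames(dm) == cn] <- 1
      v
    }
    ctr <- colv(pr[2]) - colv(pr[1])
    r <- fitter(tab, design = "phase", contrast = ctr, dispersion = dispersion)
    attr(r, "design_name") <- sprintf("phase_pairwise(%s,%s)", pr[1], pr[2])
    r
  })
  names(out) <- vapply(pairs, function(pr) paste0(pr[1], "_vs_", pr[2]), "")
  out
}

#' Write a DAResult to TSV
#' @param res a `DAResult`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_da_result <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
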