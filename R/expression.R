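# Expression stratification: TPM from counts, log2(TPM+1), replicate-level
# QC by squared Pearson correlation, per-gene mean log-TPM, and the
# category contrast (Welch t-test + ECDFs).

#' Transcripts per million from a counts matrix
#'
#' Standard TPM: per-gene length-normalized rate, rescaled so every sample
#' (column) sums to one million.
#'
#' @param counts genes x samples matrix of non-negative counts
#' @param gene_lengths per-gene lengths in bp (recycled over columns); when
#'   named, names must match rownames(counts)
#' @return TPM matrix with the same dimnames
#' @export
tpm_from_counts <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    stopifnot(all(rownames(counts) %in% names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / gene_lengths
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    nm <- colnames(counts)[zero] %||% which(zero)
    stop(sprintf("sample(s) with all-zero counts: %s", paste(nm, collapse = ", ")),
         call. = FALSE)
  }
  sweep(rate, 2, totals, "/") * 1e6
}

#' log2(TPM + 1)
#' @param tpm a TPM matrix
#' @return transformed matrix
#' @export
log_tpm <- function(tpm) log2(tpm + 1)

#' Replicate quality control
#'
#' For every condition with at least two replicates, computes all pairwise
#' squared Pearson correlations of the log-TPM profiles. A replicate group
#' whose minimum pairwise R-squared falls below the threshold is removed as
#' a group (the stricter reading of replicate removal). Single-replicate
#' conditions are retained and flagged as not assessable.
#'
#' @param log_tpm genes x samples log-TPM matrix (columns named by sample)
#' @param samples data.frame with sample_id, condition_id, replicate_id
#' @param r2_threshold minimum acceptable pairwise R-squared (default 0.9)
#' @return list with filtered `log_tpm`, `samples`, and a `report`
#'   data.frame (condition_id, n_replicates, min_r2, status, samples)
#' @export
replicate_qc <- function(log_tpm, samples, r2_threshold = 0.9) {
  stopifnot(all(samples$sample_id %in% colnames(log_tpm)))
  conds <- unique(samples$condition_id)
  report <- lapply(conds, function(cond) {
    ids <- samples$sample_id[samples$condition_id == cond]
    if (length(ids) < 2) {
      return(data.frame(condition_id = cond, n_replicates = length(ids),
                        min_r2 = NA_real_, status = "qc_not_applicable",
                        samples = paste(ids, collapse = ","),
                        stringsAsFactors = FALSE))
    }
    r2 <- stats::cor(log_tpm[, ids, drop = FALSE])^2
    min_r2 <- min(r2[upper.tri(r2)])
    data.frame(condition_id = cond, n_replicates = length(ids),
               min_r2 = min_r2,
               status = if (min_r2 < r2_threshold) "removed" else "retained",
               samples = paste(ids, collapse = ","), stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  drop_conds <- report$condition_id[report$status == "removed"]
  if (length(drop_conds) > 0 && length(drop_conds) == length(conds)) {
    warning("replicate QC removed every condition", call. = FALSE)
  }
  keep <- samples[!samples$condition_id %in% drop_conds, , drop = FALSE]
  rownames(keep) <- NULL
  list(log_tpm = log_tpm[, keep$sample_id, drop = FALSE],
       samples = keep, report = report)
}

#' Per-gene mean log-TPM
#'
#' Replicates are averaged within each condition first, then the mean is
#' taken across conditions, so unevenly replicated conditions carry equal
#' weight.
#'
#' @param log_tpm genes x samples log-TPM matrix
#' @param samples data.frame with sample_id, condition_id
#' @return named numeric vector (per gene)
#' @export
mean_expression <- function(log_tpm, samples) {
  stopifnot(all(samples$sample_id %in% colnames(log_tpm)))
  conds <- unique(samples$condition_id)
  cond_means <- vapply(conds, function(cond) {
    ids <- samples$sample_id[samples$condition_id == cond]
    rowMeans(log_tpm[, ids, drop = FALSE])
  }, numeric(nrow(log_tpm)))
  cond_means <- matrix(cond_means, nrow = nrow(log_tpm),
                       dimnames = list(rownames(log_tpm), conds))
  rowMeans(cond_means)
}

#' Compare mean expression between categories
#'
#' Two-sample unequal-variance (Welch) t-test of mean log-TPM between two
#' categories (default y-ome vs well-annotated; the statistic is positive
#' when the first group is higher), plus the per-category ECDFs used for
#' cumulative-distribution plots.
#'
#' @param means named per-gene mean log-TPM (from [mean_expression()])
#' @param categories data.frame with gene_id, category
#' @param groups the two categories to contrast
#' @return list with `statistic`, `p_value`, `df`, `group_means`, `n`,
#'   `ecdfs` (per final category with >= 1 gene), `missing` (genes in the
#'   category table absent from the expression matrix)
#' @export
compare_categories <- function(means, categories,
                               groups = c("yome", "well_annotated")) {
  stopifnot(length(groups) == 2)
  cat_map <- stats::setNames(categories$category, categories$gene_id)
  present <- names(means)[names(means) %in% names(cat_map)]
  vals <- means[present]
  cats <- cat_map[present]
  x <- vals[cats == groups[1]]
  y <- vals[cats == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each compared category needs at least 2 genes with expression", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  ecdfs <- lapply(split(vals, cats), stats::ecdf)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       group_means = stats::setNames(c(mean(x), mean(y)), groups),
       n = stats::setNames(c(length(x), length(y)), groups),
       ecdfs = ecdfs,
       missing = setdiff(categories$gene_id, names(means)))
}

#' Expression percentile threshold
#'
#' Returns the (100 - q)th percentile of the mean expression values under
#' the empirical-CDF linear-interpolation convention (R quantile type 4)
#' and the genes strictly above it ("top q percent").
#'
#' @param means named per-gene mean log-TPM
#' @param q top percentile size, 0 < q < 100 (default 20)
#' @return list with `threshold` and `genes`
#' @export
percentile_threshold <- function(means, q = 20) {
  stopifnot(q > 0, q < 100)
  threshold <- unname(stats::quantile(means, probs = 1 - q / 100, type = 4))
  list(threshold = threshold, genes = names(means)[means > threshold])
}
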