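#' Select highly variable genes by dispersion
#'
#' Ranks genes by the variance-to-mean ratio of their normalized values and
#' returns the top `n_hvg` gene names. Genes with zero mean are never
#' selected.
#'
#' @param normalized A cells x genes matrix from [normalize_log()].
#' @param n_hvg Number of genes to keep (capped at the panel size).
#' @return Character vector of gene names.
#' @export
select_hvg <- function(normalized, n_hvg = 2000L) {
  mu <- Matrix::colMeans(normalized)
  ex2 <- Matrix::colMeans(normalized^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(normalized) / max(nrow(normalized) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_hvg <- min(n_hvg, ncol(normalized))
  colnames(normalized)[order(disp, decreasing = TRUE)[seq_len(n_hvg)]]
}

#' Cluster cells on a PCA of highly variable genes
#'
#' Selects HVGs by dispersion, standardizes them, projects onto the leading
#' principal components, and clusters with k-means. Deterministic for a fixed
#' seed.
#'
#' @param normalized A cells x genes matrix from [normalize_log()].
#' @param n_clusters Number of clusters.
#' @param n_hvg Number of highly variable genes (default 2000).
#' @param n_pcs Number of principal components (must be below
#'   `min(cells, genes)`).
#' @param method Only `"kmeans"` is implemented.
#' @param seed Integer seed.
#' @return Integer cluster labels (1-based), named by barcode.
#' @export
cluster_cells <- function(normalized, n_clusters = 3L, n_hvg = 2000L,
                          n_pcs = 10L, method = c("kmeans"), seed = 1L) {
  method <- match.arg(method)
  assert_that(nrow(normalized) >= 2, "need at least 2 cells to cluster")
  assert_that(n_pcs < min(dim(normalized)),
              "n_pcs must be below min(cells, genes)", class = "xenosig_config_error")
  hvg <- select_hvg(normalized, n_hvg)
  x <- as.matrix(normalized[, hvg, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    # all selected genes constant: every cell is identical in feature space
    labs <- rep(1L, nrow(normalized))
    names(labs) <- rownames(normalized)
    return(labs)
  }
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  set.seed(seed)
  km <- stats::kmeans(pc$x, centers = n_clusters, nstart = 10L, iter.max = 100L)
  labs <- as.integer(km$cluster)
  names(labs) <- rownames(normalized)
  labs
}

#' Drop contaminant clusters
#'
#' Flags clusters as non-target (e.g. non-hepatocyte) when their mean marker
#' score exceeds `marker_fold` times the across-cluster median of that score,
#' or when their median detected-gene count falls below the
#' `low_gene_quantile` quantile of all cells. Missing markers are skipped
#' with a warning.
#'
#' @param normalized A cells x genes matrix from [normalize_log()].
#' @param labels Cluster labels as returned by [cluster_cells()].
#' @param markers Contaminant marker genes (defaults to the immune,
#'   stellate and endothelial markers Ptprc, Dcn, Pecam1).
#' @param detected_genes Optional per-cell detected-gene counts (from
#'   [compute_cell_qc()]); when `NULL` the low-gene-count rule is skipped.
#' @param marker_fold Multiple of the across-cluster median marker score
#'   above which a cluster is dropped (`Inf` disables the rule).
#' @param low_gene_quantile Quantile of all cells' detected genes below which
#'   a cluster's median flags it (`NULL` or 0 disables).
#' @return A logical keep-mask over cells (`TRUE` = retained), named by
#'   barcode, with the dropped cluster ids in attribute `"dropped_clusters"`.
#' @export
exclude_contaminant_clusters <- function(normalized, labels,
                                         markers = c("Ptprc", "Dcn", "Pecam1"),
                                         detected_genes = NULL,
                                         marker_fold = 3,
                                         low_gene_quantile = 0.10) {
  assert_that(length(labels) == nrow(normalized),
              "labels must have one entry per cell")
  present <- intersect(markers, colnames(normalized))
  missing <- setdiff(markers, colnames(normalized))
  if (length(missing) > 0)
    rlang::warn(sprintf("markers absent from panel, skipped: %s",
                        paste(missing, collapse = ", ")))
  drop_marker <- drop_lowgene <- character(0)
  cl <- sort(unique(labels))
  if (length(present) > 0 && is.finite(marker_fold)) {
    score <- signature_score(normalized, present)
    cl_mean <- vapply(cl, function(k) mean(score[labels == k]), numeric(1))
    med <- stats::median(cl_mean)
    drop_marker <- cl[cl_mean > marker_fold * med]
  }
  if (!is.null(detected_genes) && !is.null(low_gene_quantile) && low_gene_quantile > 0) {
    assert_that(length(detected_genes) == nrow(normalized),
                "detected_genes must have one entry per cell")
    cutoff <- stats::quantile(detected_genes, low_gene_quantile, names = FALSE)
    cl_med <- vapply(cl, function(k) stats::median(detected_genes[labels == k]), numeric(1))
    drop_lowgene <- cl[cl_med < cutoff]
  }
  dropped <- union(drop_marker, drop_lowgene)
  assert_that(length(dropped) < length(cl),
              "all clusters were flagged as contaminants", class = "xenosig_empty_error")
  mask <- !(labels %in% dropped)
  names(mask) <- rownames(normalized)
  attr(mask, "dropped_clusters") <- dropped
  mask
}
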