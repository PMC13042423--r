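#' QC threshold presets
#'
#' Published per-cell thresholds for the three dataset types, plus a
#' `synthetic_hepatocyte` preset scaled to the desk-size panels produced by
#' [simulate_bundle()]. A cell is kept iff its mitochondrial fraction does not
#' exceed `max_mito_fraction`, its detected gene count lies in
#' `[min_genes, max_genes]`, and its total UMI does not exceed `max_umi`; all
#' published wordings are strict ("exceeding", "fewer than", "greater than"),
#' so boundary values are kept.
#'
#' @param name One of `"mouse_hepatocyte"` (mito > 0.05, < 2000 or > 10000
#'   genes, > 100000 UMI excluded), `"mouse_hsc"` (0.05 / 2000 / 7000 /
#'   50000), `"human_hepatocyte"` (0.05 / 1500 / 6000 / 40000), or
#'   `"synthetic_hepatocyte"` (0.05 / 50 / 10000 / 20000).
#' @param max_mito_fraction,min_genes,max_genes,max_umi Optional overrides of
#'   the preset values.
#' @return A list of class `qc_preset`.
#' @export
qc_preset <- function(name, max_mito_fraction = NULL, min_genes = NULL,
                      max_genes = NULL, max_umi = NULL) {
  presets <- list(
    mouse_hepatocyte = list(max_mito_fraction = 0.05, min_genes = 2000L,
                            max_genes = 10000L, max_umi = 100000L),
    mouse_hsc = list(max_mito_fraction = 0.05, min_genes = 2000L,
                     max_genes = 7000L, max_umi = 50000L),
    human_hepatocyte = list(max_mito_fraction = 0.05, min_genes = 1500L,
                            max_genes = 6000L, max_umi = 40000L),
    synthetic_hepatocyte = list(max_mito_fraction = 0.05, min_genes = 50L,
                                max_genes = 10000L, max_umi = 20000L))
  assert_that(name %in% names(presets),
              sprintf("unknown QC preset '%s' (use one of: %s)", name,
                      paste(names(presets), collapse = ", ")),
              class = "xenosig_config_error")
  p <- presets[[name]]
  p$max_mito_fraction <- max_mito_fraction %||% p$max_mito_fraction
  p$min_genes <- min_genes %||% p$min_genes
  p$max_genes <- max_genes %||% p$max_genes
  p$max_umi <- max_umi %||% p$max_umi
  p$name <- name
  assert_that(p$min_genes < p$max_genes, "min_genes must be below max_genes",
              class = "xenosig_config_error")
  assert_that(p$min_genes > 0 && p$max_umi > 0, "thresholds must be positive",
              class = "xenosig_config_error")
  structure(p, class = "qc_preset")
}

#' Per-cell QC metrics
#'
#' @param counts A [count_matrix()] whose gene metadata carries the `mito`
#'   flag.
#' @return A tibble with one row per cell: `barcode`, `detected_genes` (genes
#'   with count > 0), `total_umi` (row sum), and `mito_fraction`
#'   (mitochondrial UMI / total UMI; 0 for an all-zero cell).
#' @export
compute_cell_qc <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  detected <- Matrix::rowSums(m > 0)
  total <- Matrix::rowSums(m)
  mito <- Matrix::rowSums(m[, counts$gene_meta$mito, drop = FALSE])
  tibble::tibble(barcode = counts$cell_meta$barcode,
                 detected_genes = unname(as.integer(detected)),
                 total_umi = unname(as.numeric(total)),
                 mito_fraction = unname(ifelse(total > 0, mito / total, 0)))
}

#' Apply a QC preset to per-cell metrics
#'
#' @param qc_table The output of [compute_cell_qc()].
#' @param preset A [qc_preset()].
#' @return `qc_table` augmented with a logical `keep` column and a `reason`
#'   column listing the violated thresholds (comma-separated, `""` for kept
#'   cells).
#' @export
apply_qc_filter <- function(qc_table, preset) {
  stopifnot(inherits(preset, "qc_preset"))
  assert_that(all(c("detected_genes", "total_umi", "mito_fraction") %in% names(qc_table)),
              "qc_table must come from compute_cell_qc()")
  fail_mito <- if (is.null(preset$max_mito_fraction)) rep(FALSE, nrow(qc_table)) else
    qc_table$mito_fraction > preset$max_mito_fraction
  fail_low <- qc_table$detected_genes < preset$min_genes
  fail_high <- qc_table$detected_genes > preset$max_genes
  fail_umi <- qc_table$total_umi > preset$max_umi
  reason <- apply(cbind(mito = fail_mito, low_genes = fail_low,
                        high_genes = fail_high, high_umi = fail_umi), 1L,
                  function(f) paste(names(f)[f], collapse = ","))
  dplyr::mutate(tibble::as_tibble(qc_table),
                keep = !(fail_mito | fail_low | fail_high | fail_umi),
                reason = reason)
}

#' Library-size normalization with log transform
#'
#' Scales each cell to 10,000 counts and applies `log1p` (the default
#' single-cell normalization): `log(1 + 1e4 * x / total)`. All-zero cells
#' yield all-zero rows. Sparsity is preserved.
#'
#' @param counts A [count_matrix()] or a cells x genes (sparse) matrix.
#' @param scale_factor Counts-per-cell target (default 1e4).
#' @return A sparse `dgCMatrix` of normalized values, cells x genes.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  total <- Matrix::rowSums(m)
  scl <- ifelse(total > 0, scale_factor / total, 0)
  out <- Matrix::Diagonal(x = scl) %*% m
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  methods::as(out, "generalMatrix")
}
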