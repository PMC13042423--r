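#' Two-sided Wilcoxon rank-sum test
#'
#' For small samples (both groups of size at most 8) the p-value is computed
#' by exact enumeration of all group assignments of the pooled (tie-aware)
#' ranks: `p = min(1, 2 * min(P(W <= w), P(W >= w)))` for the observed rank
#' sum `w`. For larger samples a tie-corrected normal approximation (no
#' continuity correction) is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_max Enumerate exactly when both groups are at most this size.
#' @return A two-sided p-value.
#' @export
rank_sum_test <- function(a, b, exact_max = 8L) {
  assert_that(length(a) > 0 && length(b) > 0, "both groups must be non-empty",
              class = "xenosig_empty_error")
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a); nb <- length(b); n <- na + nb
  w <- sum(r[seq_len(na)])
  if (na <= exact_max && nb <= exact_max) {
    idx <- utils::combn(n, na)
    ws <- colSums(matrix(r[idx], nrow = na))
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    return(p)
  }
  mu <- na * (n + 1) / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_corr)
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Log2 fold change of de-logged group means
#'
#' Computes `log2((mean(expm1(a)) + pc) / (mean(expm1(b)) + pc))` on
#' log-normalized values, the convention of the reference single-cell
#' workflow; the pseudocount guards the zero-mean case.
#'
#' @param a,b Numeric vectors of log-normalized expression (non-empty).
#' @param pseudocount Small constant added to both means (default 1e-9).
#' @return A single log2 fold change.
#' @export
log2_fold_change <- function(a, b, pseudocount = 1e-9) {
  assert_that(length(a) > 0 && length(b) > 0, "both groups must be non-empty",
              class = "xenosig_empty_error")
  log2((mean(expm1(a)) + pseudocount) / (mean(expm1(b)) + pseudocount))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wraps `stats::p.adjust`), with
#' input validation: all p-values must lie in `[0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
              "p-values must lie in [0, 1]", class = "xenosig_domain_error")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene two-group differential expression
#'
#' Runs the Wilcoxon rank-sum test and de-logged log2 fold change for every
#' gene between two cell groups of a normalized matrix, with BH correction
#' across tested genes. Genes detected (value > 0) in fewer than `min_pct` of
#' cells in both groups are skipped, mirroring the reference workflow's
#' prefilter.
#'
#' @param normalized A cells x genes matrix from [normalize_log()].
#' @param group Logical or two-level vector over cells; `TRUE` (or the first
#'   level) is group A.
#' @param min_pct Detection-fraction prefilter (0 disables).
#' @param pseudocount Passed to [log2_fold_change()].
#' @return A tibble with `gene`, `pct_a`, `pct_b`, `log2fc`, `p`, `q`,
#'   ordered as in the input panel; skipped genes are absent and counted in
#'   attribute `"n_skipped"`.
#' @export
deg_test <- function(normalized, group, min_pct = 0.10, pseudocount = 1e-9) {
  if (!is.logical(group)) {
    lv <- unique(group)
    assert_that(length(lv) == 2, "group must be logical or have exactly two levels")
    group <- group == lv[1]
  }
  assert_that(length(group) == nrow(normalized), "group must have one entry per cell")
  assert_that(any(group) && any(!group), "both groups must be non-empty",
              class = "xenosig_empty_error")
  xa <- as.matrix(normalized[group, , drop = FALSE])
  xb <- as.matrix(normalized[!group, , drop = FALSE])
  pct_a <- colMeans(xa > 0)
  pct_b <- colMeans(xb > 0)
  tested <- pct_a >= min_pct | pct_b >= min_pct
  genes <- colnames(normalized)[tested]
  p <- vapply(which(tested), function(j) rank_sum_test(xa[, j], xb[, j]), numeric(1))
  lfc <- vapply(which(tested), function(j) log2_fold_change(xa[, j], xb[, j], pseudocount),
                numeric(1))
  out <- tibble::tibble(gene = genes, pct_a = pct_a[tested], pct_b = pct_b[tested],
                        log2fc = lfc, p = p, q = bh_adjust(p))
  attr(out, "n_skipped") <- sum(!tested)
  out
}

#' Call up/down differentially expressed genes
#'
#' Applies the published thresholds with strict inequalities: up-regulated
#' genes have `log2fc > lfc_threshold` and `q < alpha`; down-regulated genes
#' have `log2fc < -lfc_threshold` and `q < alpha`.
#'
#' @param table A tibble with `gene`, `log2fc`, `p`, `q` (e.g. from
#'   [deg_test()]).
#' @param lfc_threshold Log2 fold-change threshold (default 0.3).
#' @param alpha FDR threshold (default 0.05).
#' @return An object of class `deg_signature`: list with `up` and `down` gene
#'   vectors, the annotated `table` (with a `call` column), and the
#'   thresholds.
#' @export
call_degs <- function(table, lfc_threshold = 0.3, alpha = 0.05) {
  assert_that(all(c("gene", "log2fc", "q") %in% names(table)),
              "table needs gene, log2fc and q columns")
  call <- dplyr::case_when(
    table$log2fc > lfc_threshold & table$q < alpha ~ "up",
    table$log2fc < -lfc_threshold & table$q < alpha ~ "down",
    TRUE ~ "ns")
  table <- dplyr::mutate(tibble::as_tibble(table), call = call)
  structure(list(up = table$gene[call == "up"],
                 down = table$gene[call == "down"],
                 table = table,
                 lfc_threshold = lfc_threshold, alpha = alpha),
            class = "deg_signature")
}

#' @export
print.deg_signature <- function(x, ...) {
  cat(sprintf("<deg_signature> %d up, %d down of %d tested (|log2FC| > %g, FDR < %g)\n",
              length(x$up), length(x$down), nrow(x$table), x$lfc_threshold, x$alpha))
  invisible(x)
}
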