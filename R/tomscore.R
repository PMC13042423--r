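#' Transfer a mouse DEG signature into the human gene space
#'
#' Converts the up- and down-regulated gene lists independently with the
#' chosen method; a human gene reached from both an up and a down mouse gene
#' is removed from both lists (it must not contribute to both scores) and
#' reported.
#'
#' @param signature A [call_degs()] result (or a list with `up` and `down`
#'   character vectors).
#' @param method `"mgi"` (homology-class table) or `"saturn"` (macrogene
#'   weight pairs).
#' @param table Homology table, required for `method = "mgi"`.
#' @param pairs [pair_genes()] tibble, required for `method = "saturn"`.
#' @return A list of class `transferred_signature`: `up`, `down` (human
#'   symbols), `collisions` (removed from both), `method`, and the two
#'   conversion reports.
#' @export
transfer_signature <- function(signature, method = c("mgi", "saturn"),
                               table = NULL, pairs = NULL) {
  method <- match.arg(method)
  assert_that(length(signature$up) > 0 && length(signature$down) > 0,
              "signature must have non-empty up and down lists",
              class = "xenosig_empty_error")
  conv <- switch(method,
    mgi = {
      assert_that(!is.null(table), "method 'mgi' needs a homology table")
      list(up = convert_symbols_mgi(signature$up, table),
           down = convert_symbols_mgi(signature$down, table))
    },
    saturn = {
      assert_that(!is.null(pairs), "method 'saturn' needs a gene-pair table")
      list(up = convert_symbols_saturn(signature$up, pairs),
           down = convert_symbols_saturn(signature$down, pairs))
    })
  collisions <- intersect(conv$up$converted, conv$down$converted)
  up <- setdiff(conv$up$converted, collisions)
  down <- setdiff(conv$down$converted, collisions)
  assert_that(length(up) > 0 && length(down) > 0,
              "a converted gene list is empty", class = "xenosig_empty_error")
  if (length(collisions) > 0)
    rlang::warn(sprintf("%d gene(s) mapped from both lists were removed: %s",
                        length(collisions),
                        paste(utils::head(collisions, 5), collapse = ", ")))
  structure(list(up = up, down = down, collisions = collisions,
                 method = method, reports = conv),
            class = "transferred_signature")
}

#' Per-cell Tom scores in a human dataset
#'
#' Scores every cell for the transferred up- and down-regulated gene sets
#' with GSVA and defines the Tom score as their difference,
#' `tom = gsva_up - gsva_down`: high values mark cells resembling the mouse
#' reference (p16-high-like) population. Cells are grouped into
#' high/medium/low Tom-score tertiles, and the Pearson correlation between
#' the up and down scores across cells is reported.
#'
#' @param expr A cells x genes normalized human expression matrix.
#' @param up,down Human gene lists (or pass a `transferred_signature` as
#'   `up`).
#' @param params A [gsva_params()].
#' @param method Conversion-method tag stored in the result.
#' @param cut_mode Passed to [classify_groups()].
#' @return An object of class `tom_result`: `cells` (tibble: barcode,
#'   gsva_up, gsva_down, tom, group), `cor_updown` (Pearson r), `method`,
#'   `params`.
#' @export
compute_tom_scores <- function(expr, up, down = NULL, params = gsva_params(),
                               method = NULL, cut_mode = "tertile") {
  if (inherits(up, "transferred_signature")) {
    method <- method %||% up$method
    down <- up$down
    up <- up$up
  }
  sets <- list(signature_up = up, signature_down = down)
  res <- gsva_scores(expr, sets, params)
  assert_that(all(c("signature_up", "signature_down") %in% rownames(res$scores)),
              "both gene lists must be scorable", class = "xenosig_empty_error")
  gsva_up <- res$scores["signature_up", ]
  gsva_down <- res$scores["signature_down", ]
  tom <- gsva_up - gsva_down
  cells <- tibble::tibble(barcode = colnames(res$scores),
                          gsva_up = unname(gsva_up),
                          gsva_down = unname(gsva_down),
                          tom = unname(tom),
                          group = classify_groups(tom, cut_mode))
  structure(list(cells = cells,
                 cor_updown = stats::cor(gsva_up, gsva_down),
                 method = method %||% "custom", params = params),
            class = "tom_result")
}

#' @export
print.tom_result <- function(x, ...) {
  cat(sprintf("<tom_result:%s> %d cells, mean tom %.3f, cor(up, down) = %.3f\n",
              x$method, nrow(x$cells), mean(x$cells$tom), x$cor_updown))
  invisible(x)
}

#' Classify Tom scores into high/medium/low groups
#'
#' Default is a tertile split (ties resolved by the quantile cut points, so
#' equal scores land in the same group; an all-constant vector is entirely
#' `"medium"`). Fixed numeric cutoffs are supported via
#' `cut_mode = c(low_cut, high_cut)`.
#'
#' @param tom Numeric score vector (at least 3 cells for tertiles).
#' @param cut_mode `"tertile"` or a numeric length-2 vector of cut points.
#' @return A factor with levels `low`, `medium`, `high`.
#' @export
classify_groups <- function(tom, cut_mode = "tertile") {
  if (is.character(cut_mode) && identical(cut_mode, "tertile")) {
    assert_that(length(tom) >= 3, "tertile grouping needs at least 3 cells",
                class = "xenosig_empty_error")
    cuts <- stats::quantile(tom, c(1 / 3, 2 / 3), names = FALSE)
  } else {
    assert_that(is.numeric(cut_mode) && length(cut_mode) == 2,
                "cut_mode must be 'tertile' or two numeric cut points")
    cuts <- sort(cut_mode)
  }
  grp <- ifelse(tom <= cuts[1] & tom < cuts[2], "low",
                ifelse(tom > cuts[2], "high", "medium"))
  factor(grp, levels = c("low", "medium", "high"))
}

#' Summarize Tom scores by cluster
#'
#' @param result A [compute_tom_scores()] result.
#' @param clusters Cluster labels aligned with the scored cells.
#' @return A tibble with one row per cluster: `cluster`, `n`, `mean_tom`,
#'   `frac_high`, `frac_medium`, `frac_low`, sorted by `mean_tom`
#'   (descending).
#' @export
summarize_by_cluster <- function(result, clusters) {
  stopifnot(inherits(result, "tom_result"))
  assert_that(length(clusters) == nrow(result$cells),
              "clusters must have one label per scored cell")
  df <- dplyr::mutate(result$cells, cluster = clusters)
  out <- dplyr::summarise(dplyr::group_by(df, .data$cluster),
                          n = dplyr::n(),
                          mean_tom = mean(.data$tom),
                          frac_high = mean(.data$group == "high"),
                          frac_medium = mean(.data$group == "medium"),
                          frac_low = mean(.data$group == "low"),
                          .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$mean_tom))
}
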