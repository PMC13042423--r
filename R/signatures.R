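#' Mean-expression signature score
#'
#' The score of a cell for a gene list is the mean of its normalized
#' expression over the listed genes present in the panel (duplicates in the
#' list are collapsed first). This is the generic scoring used for stellate
#' activation/quiescence marker sets and for zonation marker scores.
#'
#' @param normalized A cells x genes matrix from [normalize_log()].
#' @param genes Character vector of gene symbols.
#' @return A numeric per-cell score vector named by barcode.
#' @export
signature_score <- function(normalized, genes) {
  genes <- unique(genes)
  present <- intersect(genes, colnames(normalized))
  assert_that(length(present) > 0, "none of the listed genes are in the panel",
              class = "xenosig_empty_error")
  s <- Matrix::rowMeans(normalized[, present, drop = FALSE])
  stats::setNames(as.numeric(s), rownames(normalized))
}

#' Liver zonation marker sets
#'
#' The periportal (zone 1: Sds, Cyp2f2), mid-lobular (zone 2: Hamp, Igfbp2)
#' and pericentral (zone 3: Glul, Cyp2e1) marker genes, upper-cased for the
#' human panel.
#'
#' @param species `"mouse"` or `"human"`.
#' @return A named list of three character vectors.
#' @export
zonation_markers <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  sets <- list(zone1 = c("Sds", "Cyp2f2"),
               zone2 = c("Hamp", "Igfbp2"),
               zone3 = c("Glul", "Cyp2e1"))
  if (species == "human") sets <- lapply(sets, toupper)
  sets
}

#' Assign hepatocytes to lobule zones
#'
#' Scores each cell for the three zonation marker sets via
#' [signature_score()] and labels it with the arg-max zone; exact ties yield
#' `"unassigned"`. Errors if a zone has no marker present in the panel.
#'
#' @param normalized A cells x genes matrix from [normalize_log()].
#' @param marker_sets A named list of three marker vectors (default
#'   [zonation_markers()] for mouse).
#' @return A tibble with `barcode`, `zone` (`zone1`/`zone2`/`zone3`/
#'   `unassigned`), and the three `score_*` columns.
#' @export
assign_zones <- function(normalized, marker_sets = zonation_markers("mouse")) {
  assert_that(length(marker_sets) == 3 && !is.null(names(marker_sets)),
              "marker_sets must be a named list of three marker vectors")
  scores <- lapply(names(marker_sets), function(z) {
    present <- intersect(unique(marker_sets[[z]]), colnames(normalized))
    assert_that(length(present) > 0,
                sprintf("no marker of %s is present in the panel", z),
                class = "xenosig_empty_error")
    signature_score(normalized, present)
  })
  names(scores) <- names(marker_sets)
  sm <- do.call(cbind, scores)
  top <- apply(sm, 1L, max)
  n_top <- rowSums(sm == top)
  zone <- unname(ifelse(n_top > 1, "unassigned",
                        colnames(sm)[max.col(sm, ties.method = "first")]))
  out <- tibble::tibble(barcode = rownames(normalized), zone = zone)
  for (z in colnames(sm)) out[[paste0("score_", z)]] <- unname(sm[, z])
  out
}
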