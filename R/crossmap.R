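#' Convert mouse symbols to human symbols via a homology-class table
#'
#' Each mouse symbol maps to every human symbol sharing its homology class
#' key (the MGI DB.Class.Key convention): 1:1 pairs give a single symbol,
#' many-to-many groups give all members. The output is deduplicated in order
#' of first appearance; unmapped symbols are reported.
#'
#' @param genes Character vector of mouse symbols.
#' @param table A homology table with columns `mouse_symbol`, `human_symbol`,
#'   `class_key` (e.g. from [make_homology_table()]).
#' @return A list of class `symbol_conversion`: `converted` (character),
#'   `mapping` (tibble of resolved mouse/human/key rows), `unmapped`
#'   (character), `method = "mgi"`.
#' @export
convert_symbols_mgi <- function(genes, table) {
  assert_that(all(c("mouse_symbol", "human_symbol", "class_key") %in% names(table)),
              "table needs mouse_symbol, human_symbol, class_key columns")
  assert_that(all(nzchar(table$class_key)), "class keys must be non-empty")
  tab <- dplyr::filter(tibble::as_tibble(table), !is.na(.data$human_symbol))
  hits <- dplyr::inner_join(tibble::tibble(mouse_symbol = genes),
                            dplyr::select(tibble::as_tibble(table),
                                          "mouse_symbol", "class_key"),
                            by = "mouse_symbol", relationship = "many-to-many")
  hits <- dplyr::inner_join(dplyr::distinct(hits),
                            dplyr::select(tab, "human_symbol", "class_key"),
                            by = "class_key", relationship = "many-to-many")
  hits <- dplyr::distinct(hits)
  converted <- unique(hits$human_symbol[order(match(hits$mouse_symbol, genes))])
  unmapped <- setdiff(genes, hits$mouse_symbol)
  if (length(converted) == 0)
    rlang::warn("no input symbol could be converted")
  structure(list(converted = converted,
                 mapping = tibble::as_tibble(hits[, c("mouse_symbol", "human_symbol",
                                                      "class_key")]),
                 unmapped = unmapped, method = "mgi"),
            class = "symbol_conversion")
}

#' Convert mouse symbols via macrogene-weight gene pairs
#'
#' Maps each mouse symbol to every human symbol it is paired with in a
#' [pair_genes()] result (cosine similarity of macrogene weight columns above
#' the threshold). Deduplication and reporting follow
#' [convert_symbols_mgi()].
#'
#' @param genes Character vector of mouse symbols.
#' @param pairs A tibble from [pair_genes()] (columns `mouse`, `human`,
#'   `similarity`).
#' @return A `symbol_conversion` list with `method = "saturn"`.
#' @export
convert_symbols_saturn <- function(genes, pairs) {
  assert_that(all(c("mouse", "human") %in% names(pairs)),
              "pairs needs 'mouse' and 'human' columns")
  hits <- dplyr::distinct(dplyr::inner_join(tibble::tibble(mouse = genes),
                                            tibble::as_tibble(pairs), by = "mouse",
                                            relationship = "many-to-many"))
  converted <- unique(hits$human[order(match(hits$mouse, genes))])
  unmapped <- setdiff(genes, hits$mouse)
  if (length(converted) == 0)
    rlang::warn("no input symbol could be converted")
  structure(list(converted = converted,
                 mapping = tibble::as_tibble(hits), unmapped = unmapped,
                 method = "saturn"),
            class = "symbol_conversion")
}

#' @export
print.symbol_conversion <- function(x, ...) {
  cat(sprintf("<symbol_conversion:%s> %d symbols converted, %d unmapped\n",
              x$method, length(x$converted), length(x$unmapped)))
  invisible(x)
}

#' Initialize gene-to-macrogene weights from protein embeddings
#'
#' Macrogenes are groups of genes with similar protein embeddings: the
#' embeddings (spanning both species) are k-means-clustered into `M`
#' centroids and each gene receives a non-negative weight per macrogene,
#' `softplus(-d / h)` of its distance `d` to the centroid, so nearer
#' centroids get larger weights. `h` defaults to an eighth of the median
#' gene-centroid distance: sharp enough that a gene's weight profile is
#' dominated by its nearby centroids (so unrelated genes decorrelate) while
#' still carrying the full distance profile that separates genes sharing a
#' centroid.
#'
#' @param embeddings A gene x dimension numeric matrix with gene symbols as
#'   row names.
#' @param M Number of macrogenes (at most the number of genes).
#' @param seed Integer seed (k-means initialization).
#' @param bandwidth Optional distance scale `h`.
#' @return An `M` x genes non-negative weight matrix with gene columns.
#' @export
init_macrogene_weights <- function(embeddings, M, seed = 1L, bandwidth = NULL) {
  embeddings <- as.matrix(embeddings)
  G <- nrow(embeddings)
  assert_that(M <= G, "M cannot exceed the number of genes",
              class = "xenosig_config_error")
  set.seed(seed)
  centers <- if (M == G) embeddings else
    stats::kmeans(embeddings, centers = M, nstart = 5L, iter.max = 100L)$centers
  # gene x centroid Euclidean distances
  cross <- embeddings %*% t(centers)
  d2 <- outer(rowSums(embeddings^2), rowSums(centers^2), "+") - 2 * cross
  d <- sqrt(pmax(d2, 0))
  h <- bandwidth %||% (stats::median(d) / 8)
  if (h <= 0) h <- 1
  W <- t(softplus(-d / h))
  # normalize columns and floor the entries: cosine structure is preserved
  # while every coordinate keeps a usable softplus gradient during training
  W <- sweep(W, 2, pmax(sqrt(colSums(W^2)), 1e-300), "/")
  W <- pmax(W, 0.05)
  rownames(W) <- NULL
  colnames(W) <- rownames(embeddings)
  W
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' The reconstruction loss of the macrogene autoencoder: a mixture of a point
#' mass at zero (weight `pi`) and a negative binomial with mean `mean` and
#' size `theta`, summed over entries.
#'
#' @param x Non-negative counts.
#' @param mean Positive NB means (recycled).
#' @param theta Positive NB size (recycled).
#' @param pi Structural-zero probability in `[0, 1)` (recycled).
#' @return The summed negative log-likelihood (finite, non-negative).
#' @export
zinb_nll <- function(x, mean, theta, pi = 0) {
  assert_that(all(x >= 0), "counts must be non-negative", class = "xenosig_domain_error")
  assert_that(all(mean > 0), "mean must be positive", class = "xenosig_domain_error")
  assert_that(all(theta > 0), "theta must be positive", class = "xenosig_domain_error")
  assert_that(all(pi >= 0 & pi < 1), "pi must lie in [0, 1)",
              class = "xenosig_domain_error")
  n <- length(x)
  mean <- rep_len(mean, n); theta <- rep_len(theta, n); pi <- rep_len(pi, n)
  ll <- numeric(n)
  nz <- x > 0
  if (any(nz))
    ll[nz] <- log1p(-pi[nz]) +
      stats::dnbinom(x[nz], size = theta[nz], mu = mean[nz], log = TRUE)
  if (any(!nz)) {
    lp0 <- theta[!nz] * (log(theta[!nz]) - log(theta[!nz] + mean[!nz]))
    b <- log1p(-pi[!nz]) + lp0
    ll[!nz] <- ifelse(pi[!nz] > 0,
                      pmax(log(pi[!nz]), b) + log1p(exp(-abs(log(pi[!nz]) - b))),
                      b)
  }
  -sum(ll)
}

#' Pairwise cross-species cosine similarity of macrogene weight columns
#'
#' @param model A [pretrain_macrogenes()] result.
#' @return A mouse-genes x human-genes matrix of cosine similarities between
#'   weight columns.
#' @export
cross_species_similarity <- function(model) {
  stopifnot(inherits(model, "macrogene_model"))
  W <- model$W
  mi <- model$genes$species == "mouse"
  hi <- model$genes$species == "human"
  nrm <- sqrt(colSums(W^2))
  Wn <- sweep(W, 2, pmax(nrm, 1e-300), "/")
  S <- crossprod(Wn[, mi, drop = FALSE], Wn[, hi, drop = FALSE])
  dimnames(S) <- list(model$genes$symbol[mi], model$genes$symbol[hi])
  S
}

#' Cross-species gene pairs by weight-column cosine similarity
#'
#' Returns every (mouse, human) gene pair whose macrogene weight columns have
#' cosine similarity strictly above `threshold` (the published cutoff is
#' 0.85), sorted by similarity, descending.
#'
#' @param model A [pretrain_macrogenes()] result.
#' @param threshold Strict lower bound on similarity.
#' @return A tibble with `mouse`, `human`, `similarity`.
#' @export
pair_genes <- function(model, threshold = 0.85) {
  S <- cross_species_similarity(model)
  hit <- which(S > threshold, arr.ind = TRUE)
  out <- tibble::tibble(mouse = rownames(S)[hit[, 1]],
                        human = colnames(S)[hit[, 2]],
                        similarity = S[hit])
  dplyr::arrange(out, dplyr::desc(.data$similarity))
}
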