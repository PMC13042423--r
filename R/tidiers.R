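#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DEG signature into its per-gene table
#'
#' @param x A [call_degs()] result.
#' @param ... Unused.
#' @return The per-gene tibble (`gene`, `log2fc`, `p`, `q`, `call`, ...).
#' @method tidy deg_signature
#' @export
tidy.deg_signature <- function(x, ...) x$table

#' One-row summary of a DEG signature
#'
#' @param x A [call_degs()] result.
#' @param ... Unused.
#' @return A tibble with `n_tested`, `n_up`, `n_down`, `lfc_threshold`,
#'   `alpha`.
#' @method glance deg_signature
#' @export
glance.deg_signature <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x$table), n_up = length(x$up),
                 n_down = length(x$down),
                 lfc_threshold = x$lfc_threshold, alpha = x$alpha)
}

#' Tidy GSVA scores into long format
#'
#' @param x A [gsva_scores()] result.
#' @param ... Unused.
#' @return A tibble with `set`, `barcode`, `score`.
#' @method tidy gsva_result
#' @export
tidy.gsva_result <- function(x, ...) {
  tibble::tibble(set = rep(rownames(x$scores), ncol(x$scores)),
                 barcode = rep(colnames(x$scores), each = nrow(x$scores)),
                 score = as.vector(x$scores))
}

#' Tidy per-cell Tom scores
#'
#' @param x A [compute_tom_scores()] result.
#' @param ... Unused.
#' @return The per-cell tibble (`barcode`, `gsva_up`, `gsva_down`, `tom`,
#'   `group`).
#' @method tidy tom_result
#' @export
tidy.tom_result <- function(x, ...) x$cells

#' One-row summary of a Tom-score result
#'
#' @param x A [compute_tom_scores()] result.
#' @param ... Unused.
#' @return A tibble with `n_cells`, `mean_tom`, `cor_updown`, `method`.
#' @method glance tom_result
#' @export
glance.tom_result <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells), mean_tom = mean(x$cells$tom),
                 cor_updown = x$cor_updown, method = x$method)
}

#' Tidy the training trace of a macrogene model
#'
#' @param x A [pretrain_macrogenes()] result.
#' @param ... Unused.
#' @return The per-step loss tibble (`step`, `l_rc`, `l_s`, `total`).
#' @method tidy macrogene_model
#' @export
tidy.macrogene_model <- function(x, ...) x$trace

#' One-row summary of a macrogene model
#'
#' @param x A [pretrain_macrogenes()] result.
#' @param ... Unused.
#' @return A tibble with model size, step count, and initial/final losses.
#' @method glance macrogene_model
#' @export
glance.macrogene_model <- function(x, ...) {
  tibble::tibble(n_macrogenes = nrow(x$W), n_genes = ncol(x$W),
                 steps = x$config$steps,
                 initial_loss = x$initial$total,
                 final_loss = utils::tail(x$trace$total, 1))
}
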