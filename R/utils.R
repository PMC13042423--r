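# internal numerical helpers

softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

inv_softplus <- function(y) {
  # inverse of softplus for y > 0
  ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg, class = "xenosig_error") {
  if (!isTRUE(ok)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

#' Cosine similarity between two vectors
#'
#' Computes \eqn{\cos(w_i, w_j) = w_i \cdot w_j / (\lVert w_i\rVert \lVert
#' w_j\rVert)}, the statistic used to decide whether a mouse gene and a human
#' gene share a macrogene weight profile.
#'
#' @param w_i,w_j Numeric vectors of equal length; neither may be all zero.
#' @return A single number in \eqn{[-1, 1]}.
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))
#' @export
cosine_similarity <- function(w_i, w_j) {
  assert_that(is.numeric(w_i) && is.numeric(w_j) && length(w_i) == length(w_j),
              "w_i and w_j must be numeric vectors of equal length")
  ni <- sqrt(sum(w_i^2))
  nj <- sqrt(sum(w_j^2))
  assert_that(ni > 0 && nj > 0, "cosine similarity is undefined for a zero vector",
              class = "xenosig_domain_error")
  sum(w_i * w_j) / (ni * nj)
}

# area under the ROC curve for a score that should rank `positive` cases high;
# equivalent to the rank-sum statistic scaled to [0, 1]
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  stopifnot(n1 > 0, n0 > 0)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
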