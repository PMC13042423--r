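#' GSVA parameters
#'
#' @param kcdf Kernel for the per-gene cumulative density estimate:
#'   `"gaussian"` (bandwidth sd/4, for log-scale input; the default),
#'   `"poisson"` (rate x + 0.5, for raw counts), or `"ecdf"` (empirical CDF;
#'   rank-invariant).
#' @param tau Exponent on the rank statistic in the random walk (default 1).
#' @param score_mode `"max_diff"` (default): enrichment score is the maximum
#'   positive plus the maximum negative deviation of the walk;
#'   `"two_sided_max"`: the single deviation of largest magnitude, signed.
#' @param min_set_size,max_set_size Bounds on set size after intersection
#'   with the expression panel.
#' @return A list of class `gsva_params`.
#' @export
gsva_params <- function(kcdf = c("gaussian", "poisson", "ecdf"), tau = 1,
                        score_mode = c("max_diff", "two_sided_max"),
                        min_set_size = 5L, max_set_size = 500L) {
  kcdf <- match.arg(kcdf)
  score_mode <- match.arg(score_mode)
  assert_that(tau > 0, "tau must be positive", class = "xenosig_config_error")
  assert_that(min_set_size <= max_set_size, "min_set_size must be <= max_set_size",
              class = "xenosig_config_error")
  structure(list(kcdf = kcdf, tau = tau, score_mode = score_mode,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size)),
            class = "gsva_params")
}

#' Kernel-CDF relative-expression statistic
#'
#' For each gene, estimates each cell's position in that gene's cross-cell
#' expression distribution: the kernel-smoothed cumulative density
#' `z_cg = (1/n) * sum_k K((x_cg - x_kg) / h_g)` with a Gaussian kernel of
#' bandwidth `h_g = sd_g / 4` (log-scale input), a shifted-Poisson kernel for
#' counts, or the empirical CDF. Constant genes map to 0.5 for every cell.
#'
#' @param expr A cells x genes numeric matrix (at least 2 cells).
#' @param kcdf One of `"gaussian"`, `"poisson"`, `"ecdf"`.
#' @return A dense cells x genes matrix with entries in (0, 1).
#' @export
kcdf_transform <- function(expr, kcdf = c("gaussian", "poisson", "ecdf")) {
  kcdf <- match.arg(kcdf)
  expr <- as.matrix(expr)
  assert_that(nrow(expr) >= 2, "kernel CDF needs at least 2 cells",
              class = "xenosig_domain_error")
  n <- nrow(expr)
  z <- matrix(NA_real_, n, ncol(expr), dimnames = dimnames(expr))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    if (kcdf == "gaussian") {
      h <- stats::sd(x) / 4
      z[, j] <- if (h == 0) 0.5 else
        rowMeans(stats::pnorm(outer(x, x, "-") / h))
    } else if (kcdf == "poisson") {
      if (stats::sd(x) == 0) { z[, j] <- 0.5; next }
      lam <- x + 0.5
      z[, j] <- rowMeans(outer(x, lam, function(q, l) stats::ppois(q, l)))
    } else {
      if (stats::sd(x) == 0) { z[, j] <- 0.5; next }
      z[, j] <- vapply(x, function(v) mean(x <= v), numeric(1))
    }
  }
  z
}

# single-cell, single-set enrichment walk over genes ordered by decreasing z;
# rstat is |p/2 - rank| for the cell, in_set a logical over genes
walk_score <- function(ord, rstat, in_set, tau, score_mode) {
  p <- length(ord)
  inc <- rstat[ord]^tau * in_set[ord]
  denom_in <- sum(inc)
  m <- sum(in_set)
  steps <- ifelse(in_set[ord], if (denom_in > 0) inc / denom_in else 0,
                  -1 / (p - m))
  v <- cumsum(steps)
  vmax <- max(0, max(v))
  vmin <- min(0, min(v))
  if (score_mode == "max_diff") vmax + vmin
  else if (vmax > -vmin) vmax else vmin
}

#' Gene set variation analysis scores
#'
#' Implements the published per-sample enrichment algorithm: each gene's
#' expression is converted to a relative-expression statistic across cells
#' ([kcdf_transform()]); within each cell genes are ranked by that statistic
#' (decreasing, ties broken by panel order) and a weighted Kolmogorov-Smirnov
#' random walk is run, with inside-set increments proportional to
#' `|p/2 - rank|^tau` and uniform outside-set decrements. The enrichment
#' score combines the maximum positive and negative deviations according to
#' `params$score_mode`; scores always lie in `[-1, 1]`.
#'
#' Sets are intersected with the panel first; genes absent from the panel are
#' dropped (counted in the result). A set that is empty, equal to the whole
#' panel, or outside the configured size bounds after intersection is skipped
#' with a warning; if no set survives, an error is raised.
#'
#' @param expr A cells x genes matrix of (log-normalized) expression.
#' @param sets A named list of gene-symbol vectors.
#' @param params A [gsva_params()].
#' @return An object of class `gsva_result`: `scores` (sets x cells matrix),
#'   `params`, and `set_info` (tibble: set, n_genes, n_used, status).
#' @export
gsva_scores <- function(expr, sets, params = gsva_params()) {
  stopifnot(inherits(params, "gsva_params"))
  assert_that(length(sets) > 0 && !is.null(names(sets)) && !anyDuplicated(names(sets)),
              "sets must be a uniquely named list")
  expr <- as.matrix(expr)
  p <- ncol(expr)
  used <- lapply(sets, function(s) intersect(unique(s), colnames(expr)))
  status <- vapply(names(sets), function(nm) {
    k <- length(used[[nm]])
    if (k == 0) "empty_after_intersection"
    else if (k == p) "equals_whole_panel"
    else if (k < params$min_set_size) "below_min_size"
    else if (k > params$max_set_size) "above_max_size"
    else "ok"
  }, character(1))
  set_info <- tibble::tibble(set = names(sets),
                             n_genes = lengths(lapply(sets, unique)),
                             n_used = lengths(used), status = status)
  bad <- set_info$set[set_info$status != "ok"]
  if (length(bad) > 0)
    rlang::warn(sprintf("skipping sets: %s",
                        paste(sprintf("%s (%s)", bad,
                                      set_info$status[set_info$status != "ok"]),
                              collapse = ", ")))
  keep <- set_info$set[set_info$status == "ok"]
  assert_that(length(keep) > 0, "no gene set is scorable against this panel",
              class = "xenosig_empty_error")

  z <- kcdf_transform(expr, params$kcdf)
  n <- nrow(expr)
  scores <- matrix(NA_real_, length(keep), n,
                   dimnames = list(keep, rownames(expr)))
  in_set <- lapply(keep, function(nm) colnames(expr) %in% used[[nm]])
  for (c_i in seq_len(n)) {
    ord <- order(z[c_i, ], decreasing = TRUE)
    rnk <- integer(p); rnk[ord] <- seq_len(p)
    rstat <- abs(p / 2 - rnk)
    for (s_i in seq_along(keep)) {
      scores[s_i, c_i] <- walk_score(ord, rstat, in_set[[s_i]],
                                     params$tau, params$score_mode)
    }
  }
  structure(list(scores = scores, params = params, set_info = set_info),
            class = "gsva_result")
}

#' @export
print.gsva_result <- function(x, ...) {
  cat(sprintf("<gsva_result> %d sets x %d cells (kcdf=%s, mode=%s)\n",
              nrow(x$scores), ncol(x$scores), x$params$kcdf, x$params$score_mode))
  invisible(x)
}

#' Compare GSVA scores between two cell groups
#'
#' Two-sided Welch t-test per gene set, BH-adjusted across sets. Degenerate
#' sets with zero variance in both groups give `t = 0, p = 1` when the group
#' means are equal.
#'
#' @param result A [gsva_scores()] result (or a sets x cells score matrix).
#' @param group Logical or two-level vector over cells.
#' @return A tibble with `set`, `mean_a`, `mean_b`, `t`, `p`, `q`.
#' @export
compare_scores <- function(result, group) {
  scores <- if (inherits(result, "gsva_result")) result$scores else as.matrix(result)
  if (!is.logical(group)) {
    lv <- unique(group)
    assert_that(length(lv) == 2, "group must be logical or have exactly two levels")
    group <- group == lv[1]
  }
  assert_that(length(group) == ncol(scores), "group must have one entry per cell")
  assert_that(sum(group) >= 2 && sum(!group) >= 2,
              "each group needs at least 2 cells", class = "xenosig_empty_error")
  res <- purrr::map_dfr(rownames(scores), function(nm) {
    a <- scores[nm, group]; b <- scores[nm, !group]
    se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
    if (se2 == 0) {
      tt <- if (mean(a) == mean(b)) list(statistic = 0, p.value = 1) else
        list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
    } else {
      ht <- stats::t.test(a, b)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    tibble::tibble(set = nm, mean_a = mean(a), mean_b = mean(b),
                   t = tt$statistic, p = tt$p.value)
  })
  res$q <- bh_adjust(res$p)
  res
}

#' Read a GMT gene-set file
#'
#' @param path Path to a tab-separated GMT file (set name, description, then
#'   genes).
#' @return A named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets A named list of gene vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "xenosig") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
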