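# Independent brute-force oracles used to check the package implementations.
# These deliberately use naive loop-based code paths.

# naive GSVA: per-gene kernel CDF and per-cell random walk, all double loops
oracle_gsva <- function(expr, sets, kcdf = "gaussian", tau = 1,
                        mode = "max_diff") {
  expr <- as.matrix(expr)
  n <- nrow(expr); p <- ncol(expr)
  z <- matrix(0, n, p)
  for (j in seq_len(p)) {
    x <- expr[, j]
    h <- stats::sd(x) / 4
    for (ci in seq_len(n)) {
      z[ci, j] <- if (kcdf == "gaussian") {
        if (h == 0) 0.5 else mean(stats::pnorm((x[ci] - x) / h))
      } else if (kcdf == "ecdf") {
        if (stats::sd(x) == 0) 0.5 else mean(x <= x[ci])
      } else {
        if (stats::sd(x) == 0) 0.5 else mean(stats::ppois(x[ci], x + 0.5))
      }
    }
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), rownames(expr)))
  for (si in seq_along(sets)) {
    inset <- colnames(expr) %in% sets[[si]]
    m <- sum(inset)
    for (ci in seq_len(n)) {
      ord <- order(z[ci, ], decreasing = TRUE)
      rnk <- integer(p); rnk[ord] <- seq_len(p)
      rs <- abs(p / 2 - rnk)
      denom <- sum(rs[inset]^tau)
      v <- 0; vmax <- 0; vmin <- 0
      for (g in ord) {
        v <- v + if (inset[g]) rs[g]^tau / denom else -1 / (p - m)
        if (v > vmax) vmax <- v
        if (v < vmin) vmin <- v
      }
      out[si, ci] <- if (mode == "max_diff") vmax + vmin
        else if (vmax > -vmin) vmax else vmin
    }
  }
  out
}

# brute-force BH: q_i = min_{j : p_(j) >= p_(i)} p_(j) * m / rank(j), by the
# step-up definition evaluated directly
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(o == i)  # rank of p[i]
    cand <- vapply(ri:m, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# exact two-sided rank-sum p-value by explicit subset enumeration over index
# masks (independent of the combn-based path in the implementation)
oracle_rank_sum_exact <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); n <- length(r)
  w <- sum(r[seq_len(na)])
  idx <- seq_len(n)
  subsets <- utils::combn(idx, na, simplify = FALSE)
  ws <- vapply(subsets, function(s) sum(r[s]), numeric(1))
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# dense per-cell QC recomputation with plain loops
oracle_cell_qc <- function(counts_dense, mito_flag) {
  n <- nrow(counts_dense)
  out <- data.frame(detected_genes = integer(n), total_umi = numeric(n),
                    mito_fraction = numeric(n))
  for (i in seq_len(n)) {
    x <- counts_dense[i, ]
    out$detected_genes[i] <- sum(x > 0)
    out$total_umi[i] <- sum(x)
    out$mito_fraction[i] <- if (sum(x) > 0) sum(x[mito_flag]) / sum(x) else 0
  }
  out
}

# direct ZINB mixture density
oracle_zinb_nll <- function(x, mu, theta, pi) {
  dens <- ifelse(x == 0,
                 pi + (1 - pi) * stats::dnbinom(0, size = theta, mu = mu),
                 (1 - pi) * stats::dnbinom(x, size = theta, mu = mu))
  -sum(log(dens))
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# rank-based AUROC for a score against binary truth
oracle_auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
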