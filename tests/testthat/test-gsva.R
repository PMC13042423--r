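test_that("kcdf_transform handles constants, monotonicity, and quadrature", {
  x <- matrix(c(rep(2, 6), 1:6), 6, 2, dimnames = list(NULL, c("const", "inc")))
  z <- kcdf_transform(x, "gaussian")
  expect_true(all(z[, "const"] == 0.5))
  expect_true(all(diff(z[, "inc"]) > 0))
  expect_true(all(z > 0 & z < 1))
  expect_error(kcdf_transform(x[1, , drop = FALSE]),
               class = "xenosig_domain_error")

  # Gaussian kernel CDF equals direct numerical integration of the kernel
  set.seed(2)
  v <- rnorm(10)
  h <- sd(v) / 4
  direct <- vapply(v, function(q)
    mean(vapply(v, function(xk)
      integrate(function(t) dnorm(t, xk, h), -Inf, q)$value, numeric(1))),
    numeric(1))
  got <- kcdf_transform(matrix(v, 10, 1), "gaussian")[, 1]
  expect_equal(got, direct, tolerance = 1e-6)
})

test_that("gsva_scores matches the naive walk oracle on random instances", {
  set.seed(12)
  for (r in 1:8) {
    expr <- rand_expr(12, 30, seed = 100 + r)
    sets <- list(A = sample(colnames(expr), 8), B = sample(colnames(expr), 12))
    for (mode in c("max_diff", "two_sided_max")) {
      got <- gsva_scores(expr, sets,
                         gsva_params(score_mode = mode, min_set_size = 2))$scores
      want <- oracle_gsva(expr, sets, mode = mode)
      expect_equal(got, want, tolerance = 1e-9)
      expect_true(all(abs(got) <= 1))
    }
  }
})

test_that("a set occupying the top ranks of a cell maximizes that cell's score", {
  g <- sprintf("g%02d", 1:20)
  expr <- rand_expr(10, 20, seed = 55)
  colnames(expr) <- g
  set_genes <- g[1:5]
  # in cell 1, set genes get by far the largest values
  expr[1, set_genes] <- max(expr) + 5 + seq(5, 1)
  sc <- gsva_scores(expr, list(S = set_genes),
                    gsva_params(min_set_size = 2))$scores
  expect_equal(unname(which.max(sc["S", ])), 1L)
})

test_that("duplicate cells score identically; degenerate sets error", {
  expr <- rand_expr(8, 15, seed = 3)
  expr[2, ] <- expr[1, ]
  sc <- gsva_scores(expr, list(A = colnames(expr)[1:6]),
                    gsva_params(min_set_size = 2))$scores
  expect_equal(sc[, 1], sc[, 2])

  expect_error(suppressWarnings(
    gsva_scores(expr, list(Everything = colnames(expr)))),
    class = "xenosig_empty_error")
  expect_warning(
    sc2 <- gsva_scores(expr, list(A = colnames(expr)[1:6],
                                  Bad = c("zz1", "zz2")),
                       gsva_params(min_set_size = 2)),
    "skipping")
  expect_equal(rownames(sc2$scores), "A")
})

test_that("scores are invariant to gene and cell permutations", {
  expr <- rand_expr(10, 25, seed = 9)
  sets <- list(A = colnames(expr)[3:10])
  p <- gsva_params(min_set_size = 2)
  base <- gsva_scores(expr, sets, p)$scores
  set.seed(10)
  gp <- sample(ncol(expr)); cp <- sample(nrow(expr))
  perm <- gsva_scores(expr[cp, gp], sets, p)$scores
  expect_equal(perm[, colnames(base), drop = FALSE], base)
})

test_that("ecdf mode is rank-invariant under monotone transforms", {
  expr <- rand_expr(10, 25, seed = 21)
  sets <- list(A = colnames(expr)[1:7])
  p <- gsva_params(kcdf = "ecdf", min_set_size = 2)
  s1 <- gsva_scores(expr, sets, p)$scores
  s2 <- gsva_scores(exp(expr), sets, p)$scores
  s3 <- gsva_scores(expr^3, sets, p)$scores
  expect_equal(s1, s2)
  expect_equal(s1, s3)
})

test_that("compare_scores: identical groups, single set, planted shift", {
  scores <- matrix(rep(c(0.2, 0.2, 0.2, 0.2), 2), 2, 4, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), sprintf("c%d", 1:4)))
  out <- compare_scores(scores, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$t, c(0, 0))
  expect_equal(out$p, c(1, 1))

  single <- matrix(rnorm(20), 1, 20, dimnames = list("only", sprintf("c%d", 1:20)))
  out1 <- compare_scores(single, rep(c(TRUE, FALSE), 10))
  expect_equal(out1$q, out1$p)

  # power at a 1-sd shift, n = 100 per group
  set.seed(77)
  hits <- replicate(200, {
    sc <- matrix(c(rnorm(100, 1), rnorm(100)), 1, 200,
                 dimnames = list("s", sprintf("c%d", 1:200)))
    compare_scores(sc, rep(c(TRUE, FALSE), each = 100))$q < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})
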