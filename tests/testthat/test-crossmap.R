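test_that("convert_symbols_mgi resolves 1:1, many-to-many, and unmapped", {
  tab <- tibble::tibble(
    mouse_symbol = c("Glul", "Sds", "Twin1", "Twin2", "Lonely"),
    human_symbol = c("GLUL", "SDS", "TWIN", "TWIN", NA),
    class_key = c("K1", "K2", "K3", "K3", "K4"))
  conv <- convert_symbols_mgi(c("Glul"), tab)
  expect_equal(conv$converted, "GLUL")
  # both members of a 2-mouse:1-human group give the human symbol once
  conv2 <- convert_symbols_mgi(c("Twin1", "Twin2"), tab)
  expect_equal(conv2$converted, "TWIN")
  conv3 <- convert_symbols_mgi(c("Nope", "Lonely", "Sds"), tab)
  expect_equal(conv3$converted, "SDS")
  expect_setequal(conv3$unmapped, c("Nope", "Lonely"))
})

test_that("convert_symbols_mgi equals a brute-force class-key join", {
  b <- small_bundle()
  gt <- b$truth$genes
  genes <- gt$symbol[gt$species == "mouse"][seq(1, 100, by = 3)]
  conv <- convert_symbols_mgi(genes, b$homology)
  tab <- b$homology[!is.na(b$homology$human_symbol), ]
  keys <- tab$class_key[tab$mouse_symbol %in% genes]
  want <- unique(tab$human_symbol[tab$class_key %in% keys])
  expect_setequal(conv$converted, want)
})

test_that("init_macrogene_weights reflects embedding geometry", {
  # identical embeddings -> identical weight columns
  emb <- matrix(rnorm(60), 6, 10,
                dimnames = list(sprintf("g%d", 1:6), NULL))
  emb[2, ] <- emb[1, ]
  W <- init_macrogene_weights(emb, 3, seed = 2)
  expect_equal(W[, 1], W[, 2], ignore_attr = TRUE)

  # M = number of genes with distinct embeddings: biggest weight on own centroid
  emb2 <- matrix(rnorm(50, sd = 3), 5, 10,
                 dimnames = list(sprintf("h%d", 1:5), NULL))
  W2 <- init_macrogene_weights(emb2, 5, seed = 3)
  # each gene's top macrogene is unique to it
  expect_equal(unname(apply(W2, 2, which.max)), 1:5)

  # orthogonal clusters: within-cluster columns more similar than between
  base <- diag(3) * 10
  emb3 <- base[rep(1:3, each = 4), ] + matrix(rnorm(12 * 3, sd = 0.1), 12, 3)
  rownames(emb3) <- sprintf("q%02d", 1:12)
  W3 <- init_macrogene_weights(emb3, 3, seed = 4)
  cl <- rep(1:3, each = 4)
  cs <- function(i, j) cosine_similarity(W3[, i], W3[, j])
  within <- c(); between <- c()
  for (i in 1:11) for (j in (i + 1):12) {
    if (cl[i] == cl[j]) within <- c(within, cs(i, j)) else between <- c(between, cs(i, j))
  }
  expect_gt(min(within), max(between))

  expect_error(init_macrogene_weights(emb2, 9, seed = 1),
               class = "xenosig_config_error")
})

test_that("zinb_nll matches the direct mixture density and its limits", {
  set.seed(41)
  x <- rpois(50, 3)
  mu <- runif(50, 0.5, 6); th <- runif(50, 0.5, 4); pi <- runif(50, 0, 0.6)
  expect_equal(zinb_nll(x, mu, th, pi), oracle_zinb_nll(x, mu, th, pi),
               tolerance = 1e-10)
  # pi = 0 reduces to plain NB
  expect_equal(zinb_nll(x, mu, th, 0),
               -sum(dnbinom(x, size = th, mu = mu, log = TRUE)),
               tolerance = 1e-10)
  # x = 0 with pi -> 1: per-entry NLL -> 0
  expect_lt(zinb_nll(0, 2, 1, 1 - 1e-12), 1e-10)
  expect_error(zinb_nll(c(1, 2), c(1, -1), 1, 0), class = "xenosig_domain_error")
  expect_error(zinb_nll(1, 1, 1, 1), class = "xenosig_domain_error")
})

test_that("zinb_nll is minimized in mean at the empirical mean (pi = 0)", {
  set.seed(51)
  x <- rnbinom(200, size = 2, mu = 4)
  grid <- seq(0.5, 10, by = 0.01)
  nll <- vapply(grid, function(m) zinb_nll(x, m, 2, 0), numeric(1))
  expect_lt(abs(grid[which.min(nll)] - mean(x)), 0.02)
})

test_that("cosine_similarity matches direct arithmetic and its properties", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)), 32 / sqrt(14 * 77),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "xenosig_domain_error")
  set.seed(10)
  for (r in 1:200) {
    v <- rnorm(6); w <- rnorm(6); a <- runif(1, 0.1, 5)
    want <- sum(v * w) / sqrt(sum(v^2) * sum(w^2))
    expect_equal(cosine_similarity(v, w), want, tolerance = 1e-12)
    expect_equal(cosine_similarity(w, v), cosine_similarity(v, w))
    expect_equal(cosine_similarity(a * v, w), cosine_similarity(v, w),
                 tolerance = 1e-12)
  }
})

test_that("pair_genes respects strict thresholds and permutation invariance", {
  b <- cached("tiny_model", {
    bb <- small_bundle()
    pretrain_macrogenes(bb$mouse, bb$human, bb$embeddings, M = 15L,
                        steps = 60L, seed = 5L)
  })
  n_mouse <- sum(b$genes$species == "mouse")
  n_human <- sum(b$genes$species == "human")
  all_pairs <- pair_genes(b, threshold = -1)
  expect_equal(nrow(all_pairs), n_mouse * n_human)
  expect_true(all(diff(all_pairs$similarity) <= 0))
  none <- pair_genes(b, threshold = 1)
  expect_equal(nrow(none), 0)
  # default threshold is strict: a pair exactly at 0.85 would be excluded
  some <- pair_genes(b, threshold = 0.85)
  expect_true(all(some$similarity > 0.85))
})

test_that("convert_symbols_saturn maps via pairs with dedup and reporting", {
  pairs <- tibble::tibble(mouse = c("Glul", "Glul", "Sds"),
                          human = c("GLUL", "GLUL2", "SDS"),
                          similarity = c(0.99, 0.92, 0.97))
  conv <- convert_symbols_saturn(c("Glul", "Hamp", "Sds"), pairs)
  expect_equal(conv$converted, c("GLUL", "GLUL2", "SDS"))
  expect_equal(conv$unmapped, "Hamp")
})
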