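# trainer checks at miniature scale; the full desk-scale run lives in the
# acceptance suite

mini_bundle <- function() cached("mini_bundle", {
  simulate_bundle(sim_config(seed = 33, n_cells_per_species = 120L,
                             n_genes_per_species = 90L, n_ortholog_pairs = 70L,
                             n_up_genes = 8L, n_down_genes = 8L,
                             mito_gene_count = 4L, n_outlier_cells = 0L,
                             n_contaminant_cells = 0L))
})

test_that("analytic gradients agree with finite differences", {
  b <- mini_bundle()
  X <- as.matrix(b$mouse$counts); X <- X[, colSums(X) > 0]
  N <- as.matrix(normalize_log(X)); tot <- rowSums(X)
  sp <- list(X = X, N = N, lib = tot / mean(tot), cols = seq_len(ncol(X)))
  M <- 6L; G <- ncol(X); L <- 4L
  set.seed(3)
  par <- list(V = matrix(rnorm(M * G), M, G),
              E = matrix(rnorm(L * M, sd = 0.1), L, M),
              e_b = rnorm(L, sd = 0.1),
              D = matrix(rnorm(G * L, sd = 0.1), G, L),
              d_b = log(colMeans(X)),
              log_theta = rnorm(G, sd = 0.2),
              pi_logit = rep(-1.5, G))
  rows <- seq_len(nrow(X))
  fw <- xenosig:::zinb_forward(par, sp, rows, want_grad = TRUE)
  eps <- 1e-6
  pick <- function(nm) fw$g[[nm]]
  set.seed(4)
  for (nm in names(par)) {
    for (k in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
      p2 <- par; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- par; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (xenosig:::zinb_forward(p2, sp, rows, FALSE)$loss -
                xenosig:::zinb_forward(p3, sp, rows, FALSE)$loss) / (2 * eps)
      ana <- pick(nm)[k]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-4)
    }
  }
  # similarity-loss gradient (with a repeated gene index)
  i <- c(1L, 3L, 1L); j <- c(2L, 4L, 5L); tgt <- c(0.2, -0.1, 0.5)
  ls <- xenosig:::ls_forward(par, i, j, tgt, want_grad = TRUE)
  set.seed(5)
  for (k in sample(length(par$V), 6)) {
    p2 <- par; p2$V[k] <- p2$V[k] + eps
    p3 <- par; p3$V[k] <- p3$V[k] - eps
    num <- (xenosig:::ls_forward(p2, i, j, tgt, FALSE)$loss -
              xenosig:::ls_forward(p3, i, j, tgt, FALSE)$loss) / (2 * eps)
    expect_lt(abs(num - ls$g_V[k]) / max(abs(num) + abs(ls$g_V[k]), 1e-8), 1e-5)
  }
})

test_that("pretraining is reproducible and structurally sound", {
  b <- mini_bundle()
  m1 <- pretrain_macrogenes(b$mouse, b$human, b$embeddings, M = 12L,
                            steps = 50L, seed = 21L)
  m2 <- pretrain_macrogenes(b$mouse, b$human, b$embeddings, M = 12L,
                            steps = 50L, seed = 21L)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$trace, m2$trace)
  expect_equal(nrow(m1$trace), 50L)
  expect_true(all(is.finite(m1$W)) && all(m1$W >= 0))
  expect_equal(ncol(m1$W), nrow(m1$genes))
  expect_lt(tail(m1$trace$total, 1), m1$initial$total)
})

test_that("with one species and lambda_s = 0 the L_s term is identically zero", {
  b <- mini_bundle()
  m <- pretrain_macrogenes(b$mouse, NULL, b$embeddings, M = 10L, steps = 30L,
                           lambda_s = 0, seed = 8L)
  # the objective carries no similarity term: total is the reconstruction loss
  expect_equal(m$trace$total, m$trace$l_rc)
  expect_equal(m$initial$total, m$initial$l_rc)
  expect_true(all(m$genes$species == "mouse"))
  expect_lt(tail(m$trace$l_rc, 1), m$initial$l_rc)
})

test_that("all-zero genes are excluded before training, with a message", {
  b <- mini_bundle()
  X <- as.matrix(b$mouse$counts)
  X[, 10] <- 0L
  expect_message(
    m <- pretrain_macrogenes(X, NULL, b$embeddings, M = 8L, steps = 10L,
                             lambda_s = 0, seed = 2L),
    "all-zero")
  expect_equal(m$dropped_genes, colnames(X)[10])
  expect_false(colnames(X)[10] %in% m$genes$symbol)
})

test_that("overlapping panels and oversized M are rejected", {
  b <- mini_bundle()
  expect_error(pretrain_macrogenes(b$mouse, b$mouse, b$embeddings, M = 5L,
                                   steps = 5L, seed = 1L),
               "share gene symbols")
  expect_error(pretrain_macrogenes(b$mouse, b$human, b$embeddings,
                                   M = 10000L, steps = 5L, seed = 1L),
               class = "xenosig_config_error")
})

test_that("macrogene_expression projects cells through the weights", {
  b <- mini_bundle()
  m <- cached("mini_model", pretrain_macrogenes(b$mouse, b$human, b$embeddings,
                                                M = 12L, steps = 30L, seed = 9L))
  me <- macrogene_expression(m, b$mouse)
  expect_equal(dim(me), c(nrow(b$mouse$counts), 12L))
  common <- intersect(colnames(b$mouse$counts), m$genes$symbol)
  N <- normalize_log(b$mouse$counts[, common])
  W <- m$W[, match(common, m$genes$symbol)]
  expect_equal(me, as.matrix(N %*% t(W)), tolerance = 1e-12, ignore_attr = TRUE)
})
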