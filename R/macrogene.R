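# Macrogene autoencoder: counts -> macrogene expression (gene-to-macrogene
# weights W = softplus(V)) -> linear encoder to a latent space -> linear
# decoder to per-gene ZINB parameters. Trained by Adam on minibatches with
# loss L_rc (ZINB reconstruction NLL) + lambda_s * L_s (weight-column cosine
# similarities pulled toward protein-embedding cosine similarities).

new_adam_state <- function(par) {
  lapply(par, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, lr_mult = NULL) {
  for (nm in names(grad)) {
    g <- grad[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    mult <- if (!is.null(lr_mult) && nm %in% names(lr_mult)) lr_mult[[nm]] else 1
    par[[nm]] <- par[[nm]] - lr * mult * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(par = par, state = state)
}

# forward pass + ZINB NLL (and optionally gradients) for a batch of one
# species; the per-entry likelihood work happens in compiled code
zinb_forward <- function(par, sp, rows, want_grad = TRUE) {
  X <- sp$X[rows, , drop = FALSE]
  N <- sp$N[rows, , drop = FALSE]
  lib <- sp$lib[rows]
  cols <- sp$cols
  Vs <- par$V[, cols, drop = FALSE]
  Ws <- softplus(Vs)
  m <- N %*% t(Ws)
  z <- sweep(m %*% t(par$E), 2, par$e_b, "+")
  Ds <- par$D[cols, , drop = FALSE]
  eta <- sweep(z %*% t(Ds), 2, par$d_b[cols], "+")
  st <- .zinb_stats_cpp(X, eta, lib, par$log_theta[cols], par$pi_logit[cols],
                        want_grad)
  if (!want_grad) return(list(loss = st$loss))
  deta <- st$deta
  g_D <- crossprod(deta, z)                  # Gs x L
  g_d_b <- colSums(deta)
  dz <- deta %*% Ds                          # B x L
  g_E <- crossprod(dz, m)                    # L x M
  g_e_b <- colSums(dz)
  dm <- dz %*% par$E                         # B x M
  g_W <- crossprod(dm, N)                    # M x Gs
  g_V <- g_W * sigmoid(Vs)
  list(loss = st$loss, cols = cols,
       g = list(V = g_V, E = g_E, e_b = g_e_b, D = g_D, d_b = g_d_b,
                log_theta = st$g_log_theta, pi_logit = st$g_pi_logit))
}

# L_s: mean squared gap between weight-column cosine similarity and embedding
# cosine similarity over a set of gene pairs (repeated gene indices allowed;
# gradients are aggregated per gene)
ls_forward <- function(par, pi_idx, pj_idx, tgt, want_grad = TRUE) {
  W <- softplus(par$V)
  U <- W[, pi_idx, drop = FALSE]
  Vv <- W[, pj_idx, drop = FALSE]
  nu <- sqrt(colSums(U^2)); nv <- sqrt(colSums(Vv^2))
  cs <- colSums(U * Vv) / (nu * nv)
  diffc <- cs - tgt
  loss <- mean(diffc^2)
  if (!want_grad) return(list(loss = loss))
  P <- length(tgt)
  coef <- 2 * diffc / P
  dU <- sweep(sweep(Vv, 2, nu * nv, "/") - sweep(U, 2, cs / nu^2, "*"), 2, coef, "*")
  dV2 <- sweep(sweep(U, 2, nu * nv, "/") - sweep(Vv, 2, cs / nv^2, "*"), 2, coef, "*")
  agg <- rowsum(rbind(t(dU), t(dV2)), c(pi_idx, pj_idx))
  g_V <- par$V * 0
  cols <- as.integer(rownames(agg))
  g_V[, cols] <- t(agg) * sigmoid(par$V[, cols, drop = FALSE])
  list(loss = loss, g_V = g_V)
}

#' Pretrain the macrogene autoencoder
#'
#' Jointly learns non-negative gene-to-macrogene weights for both species'
#' genes by minimizing a ZINB reconstruction loss `L_rc` plus `lambda_s`
#' times a supplementary loss `L_s` that pulls the cosine similarity of two
#' genes' weight columns toward the cosine similarity of their protein
#' embeddings. Per gradient step each species contributes a minibatch of
#' cells; gene pairs for `L_s` mix random pairs with pairs anchored at high
#' embedding similarity. The per-step loss trace is evaluated on the full
#' data (and a fixed evaluation pair set), so it reflects the optimization
#' objective, not minibatch noise. Fully reproducible from `seed`.
#'
#' @param counts_mouse,counts_human [count_matrix()] objects (or plain cells
#'   x genes count matrices with dimnames); gene symbols must not overlap
#'   between species. `counts_human` may be `NULL` for a single-species
#'   autoencoder (then `L_s` uses within-species pairs only).
#' @param embeddings Gene x dimension matrix with row names covering every
#'   gene of both panels.
#' @param M Number of macrogenes.
#' @param W_init Optional initial weight matrix (`M` x genes, columns in
#'   mouse-then-human panel order); defaults to
#'   [init_macrogene_weights()] on `embeddings`.
#' @param steps Number of gradient steps (the published pretraining uses
#'   2000).
#' @param lambda_s Weight of the embedding-similarity loss.
#' @param lr Adam learning rate (linearly decayed to a tenth over training).
#' @param batch_size Cells per species per step (capped at the dataset size).
#' @param latent_dim Dimension of the encoder latent space.
#' @param n_pairs Gene pairs per step for `L_s` (mixed anchor/hard-negative/
#'   random sampling; repeated genes allowed).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `macrogene_model`: `W` (M x genes, softplus of
#'   the learned `V`), `genes` (tibble: symbol, species), encoder/decoder
#'   parameters, `trace` (tibble with one row per step: `step`, `l_rc`,
#'   `l_s`, `total`), `initial` (losses before training), and `config`.
#' @export
pretrain_macrogenes <- function(counts_mouse, counts_human, embeddings,
                                M = 50L, W_init = NULL, steps = 2000L,
                                lambda_s = 1, lr = 1e-3, batch_size = 128L,
                                latent_dim = 32L, n_pairs = 500L, seed = 1L) {
  as_dense <- function(cm) {
    m <- if (inherits(cm, "count_matrix")) cm$counts else cm
    as.matrix(m)
  }
  species_list <- list(mouse = as_dense(counts_mouse))
  if (!is.null(counts_human)) species_list$human <- as_dense(counts_human)
  all_sym <- unlist(lapply(species_list, colnames), use.names = FALSE)
  assert_that(!anyDuplicated(all_sym),
              "mouse and human panels must not share gene symbols")
  assert_that(all(all_sym %in% rownames(embeddings)),
              "embeddings must cover every gene of both panels")

  set.seed(seed)
  sp <- list()
  offset <- 0L
  dropped <- character(0)
  for (s in names(species_list)) {
    X <- species_list[[s]]
    zero <- colSums(X) == 0
    if (any(zero)) {
      dropped <- c(dropped, colnames(X)[zero])
      X <- X[, !zero, drop = FALSE]
    }
    N <- as.matrix(normalize_log(X))
    tot <- rowSums(X)
    sp[[s]] <- list(X = X, N = N, lib = tot / mean(tot),
                    cols = offset + seq_len(ncol(X)), symbols = colnames(X))
    offset <- offset + ncol(X)
  }
  if (length(dropped) > 0)
    rlang::inform(sprintf("excluded %d all-zero gene(s) before training", length(dropped)))
  genes <- tibble::tibble(
    symbol = unlist(lapply(sp, `[[`, "symbols"), use.names = FALSE),
    species = rep(names(sp), vapply(sp, function(x) length(x$cols), integer(1))))
  G <- nrow(genes)
  emb <- as.matrix(embeddings)[genes$symbol, , drop = FALSE]

  if (is.null(W_init)) W_init <- init_macrogene_weights(emb, M, seed = seed)
  assert_that(nrow(W_init) == M && ncol(W_init) == G,
              "W_init must be M x (total genes)", class = "xenosig_config_error")

  L <- as.integer(latent_dim)
  par <- list(V = inv_softplus(pmax(W_init, 1e-6)),
              E = matrix(stats::rnorm(L * M, sd = 0.01), L, M),
              e_b = numeric(L),
              D = matrix(stats::rnorm(G * L, sd = 0.01), G, L),
              d_b = log(unlist(lapply(sp, function(x) colMeans(x$X)), use.names = FALSE)),
              log_theta = numeric(G),
              pi_logit = rep(-2, G))

  # normalized embeddings for similarity targets
  en <- emb / pmax(sqrt(rowSums(emb^2)), 1e-300)
  # anchor pairs: cross-species (or any, if one species) pairs with high
  # embedding cosine similarity
  if (length(sp) == 2) {
    cs <- en[sp$mouse$cols, , drop = FALSE] %*% t(en[sp$human$cols, , drop = FALSE])
    hi <- which(cs > 0.8, arr.ind = TRUE)
    anchors <- cbind(sp$mouse$cols[hi[, 1]], sp$human$cols[hi[, 2]])
  } else {
    cs <- en %*% t(en); diag(cs) <- 0
    hi <- which(cs > 0.8 & upper.tri(cs), arr.ind = TRUE)
    anchors <- cbind(hi[, 1], hi[, 2])
  }
  if (nrow(anchors) > 5000) anchors <- anchors[sample(nrow(anchors), 5000), , drop = FALSE]
  # hard negatives: pairs whose current weight columns are similar (they share
  # macrogenes) but whose embeddings are not; L_s must push these apart. The
  # pool is re-mined from the evolving weights every `neg_refresh` steps.
  emb_cos <- if (length(sp) == 2)
    en[sp$mouse$cols, , drop = FALSE] %*% t(en[sp$human$cols, , drop = FALSE])
  else en %*% t(en)
  mine_negatives <- function(W, cap = 8000L) {
    Wn <- sweep(W, 2, pmax(sqrt(colSums(W^2)), 1e-300), "/")
    if (length(sp) == 2) {
      cw <- crossprod(Wn[, sp$mouse$cols, drop = FALSE],
                      Wn[, sp$human$cols, drop = FALSE])
      hi <- which(cw > 0.7 & emb_cos < 0.5, arr.ind = TRUE)
      neg <- cbind(sp$mouse$cols[hi[, 1]], sp$human$cols[hi[, 2]])
    } else {
      cw <- crossprod(Wn)
      hi <- which(cw > 0.7 & emb_cos < 0.5 & upper.tri(cw), arr.ind = TRUE)
      neg <- cbind(hi[, 1], hi[, 2])
    }
    if (nrow(neg) > cap) neg <- neg[sample(nrow(neg), cap), , drop = FALSE]
    neg
  }
  neg_refresh <- 50L
  negatives <- mine_negatives(softplus(inv_softplus(pmax(W_init, 1e-6))))

  pair_target <- function(i, j) rowSums(en[i, , drop = FALSE] * en[j, , drop = FALSE])
  draw_from <- function(pool, k) {
    if (nrow(pool) == 0 || k == 0) return(matrix(integer(0), 0, 2))
    pool[sample(nrow(pool), min(k, nrow(pool))), , drop = FALSE]
  }
  sample_pairs <- function() {
    # every anchor and mined negative, every step (consistent pressure is what
    # moves the weight geometry), plus n_pairs random pairs for coverage
    ri <- cbind(sample(G, n_pairs, replace = TRUE), sample(G, n_pairs, replace = TRUE))
    ri <- ri[ri[, 1] != ri[, 2], , drop = FALSE]
    idx <- rbind(anchors, negatives, ri)
    list(i = idx[, 1], j = idx[, 2], t = pair_target(idx[, 1], idx[, 2]))
  }
  # fixed evaluation pair set for the loss trace
  eval_pairs <- local({
    ai <- rbind(anchors[seq_len(min(1500, nrow(anchors))), , drop = FALSE],
                negatives[seq_len(min(1500, nrow(negatives))), , drop = FALSE])
    ri <- matrix(sample(G, 2 * min(2000, floor(G / 2))), ncol = 2)
    idx <- rbind(ai, ri)
    list(i = idx[, 1], j = idx[, 2], t = pair_target(idx[, 1], idx[, 2]))
  })

  full_loss <- function(par) {
    l_rc <- sum(vapply(sp, function(s)
      zinb_forward(par, s, seq_len(nrow(s$X)), want_grad = FALSE)$loss, numeric(1)))
    l_s <- ls_forward(par, eval_pairs$i, eval_pairs$j, eval_pairs$t,
                      want_grad = FALSE)$loss
    c(l_rc = l_rc, l_s = l_s)
  }

  initial <- full_loss(par)
  state <- new_adam_state(par)
  trace <- matrix(NA_real_, steps, 3, dimnames = list(NULL, c("l_rc", "l_s", "total")))
  for (t in seq_len(steps)) {
    grad <- lapply(par, function(p) p * 0)
    for (s in names(sp)) {
      n_s <- nrow(sp[[s]]$X)
      rows <- if (n_s <= batch_size) seq_len(n_s) else sample(n_s, batch_size)
      fw <- zinb_forward(par, sp[[s]], rows, want_grad = TRUE)
      grad$V[, fw$cols] <- grad$V[, fw$cols, drop = FALSE] + fw$g$V
      grad$E <- grad$E + fw$g$E
      grad$e_b <- grad$e_b + fw$g$e_b
      grad$D[fw$cols, ] <- grad$D[fw$cols, , drop = FALSE] + fw$g$D
      grad$d_b[fw$cols] <- grad$d_b[fw$cols] + fw$g$d_b
      grad$log_theta[fw$cols] <- grad$log_theta[fw$cols] + fw$g$log_theta
      grad$pi_logit[fw$cols] <- grad$pi_logit[fw$cols] + fw$g$pi_logit
    }
    if (lambda_s > 0) {
      if (t %% neg_refresh == 0) negatives <- mine_negatives(softplus(par$V))
      pr <- sample_pairs()
      lsf <- ls_forward(par, pr$i, pr$j, pr$t, want_grad = TRUE)
      grad$V <- grad$V + lambda_s * lsf$g_V
    }
    lr_t <- lr * (1 - 0.9 * (t - 1) / max(steps - 1, 1))
    # the weight matrix carries both losses and needs larger moves than the
    # encoder/decoder to reshape column geometry within the step budget
    upd <- adam_update(par, grad, state, lr_t, t, lr_mult = list(V = 3))
    par <- upd$par; state <- upd$state
    fl <- full_loss(par)
    trace[t, ] <- c(fl["l_rc"], fl["l_s"], fl["l_rc"] + lambda_s * fl["l_s"])
    if (!is.finite(trace[t, "total"]))
      rlang::abort(sprintf("training diverged at step %d (non-finite loss)", t),
                   class = "xenosig_divergence_error")
  }

  structure(list(
    W = softplus(par$V),
    V = par$V,
    genes = genes,
    encoder = list(E = par$E, b = par$e_b),
    decoder = list(D = par$D, b = par$d_b,
                   theta = exp(par$log_theta), pi = sigmoid(par$pi_logit)),
    trace = tibble::tibble(step = seq_len(steps),
                           l_rc = trace[, "l_rc"], l_s = trace[, "l_s"],
                           total = trace[, "total"]),
    initial = list(l_rc = unname(initial["l_rc"]), l_s = unname(initial["l_s"]),
                   total = unname(initial["l_rc"] + lambda_s * initial["l_s"])),
    dropped_genes = dropped,
    config = list(M = M, steps = steps, lambda_s = lambda_s, lr = lr,
                  batch_size = batch_size, latent_dim = latent_dim,
                  n_pairs = n_pairs, seed = seed)),
    class = "macrogene_model")
}

#' @export
print.macrogene_model <- function(x, ...) {
  cat(sprintf("<macrogene_model> %d macrogenes x %d genes (%s); %d steps, final loss %.4f (initial %.4f)\n",
              nrow(x$W), ncol(x$W), paste(unique(x$genes$species), collapse = "+"),
              x$config$steps, utils::tail(x$trace$total, 1), x$initial$total))
  invisible(x)
}

#' Macrogene expression of cells under a trained model
#'
#' @param model A [pretrain_macrogenes()] result.
#' @param counts A [count_matrix()] or cells x genes count matrix of one
#'   species covered by the model.
#' @return A cells x macrogenes matrix (`normalize_log(counts) %*% t(W)`
#'   restricted to that species' gene columns).
#' @export
macrogene_expression <- function(model, counts) {
  stopifnot(inherits(model, "macrogene_model"))
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  common <- intersect(colnames(m), model$genes$symbol)
  assert_that(length(common) > 0, "no gene of the matrix is in the model",
              class = "xenosig_empty_error")
  N <- normalize_log(m[, common, drop = FALSE])
  W <- model$W[, match(common, model$genes$symbol), drop = FALSE]
  out <- as.matrix(N %*% t(W))
  rownames(out) <- rownames(m)
  out
}

#' Save or load a macrogene model checkpoint
#'
#' Serializes the full model (weights, encoder/decoder parameters, loss
#' trace, configuration and seed) to a single file.
#'
#' @param model A [pretrain_macrogenes()] result.
#' @param path Checkpoint file path.
#' @return `path` invisibly (`write_macrogene_model`); the restored
#'   `macrogene_model` (`read_macrogene_model`).
#' @export
write_macrogene_model <- function(model, path) {
  stopifnot(inherits(model, "macrogene_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_macrogene_model
#' @export
read_macrogene_model <- function(path) {
  model <- readRDS(path)
  assert_that(inherits(model, "macrogene_model"),
              "file does not contain a macrogene model",
              class = "xenosig_format_error")
  model
}
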