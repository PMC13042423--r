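test_that("sample_zinb matches NB moments and degenerate limits", {
  expect_identical(sample_zinb(5, 2, 1, 20, seed = 1), rep(0L, 20))
  expect_identical(sample_zinb(5, 2, 0.3, 0, seed = 1), integer(0))
  expect_error(sample_zinb(-1, 2, 0, 5), class = "xenosig_domain_error")
  expect_error(sample_zinb(5, 0, 0, 5), class = "xenosig_domain_error")
  expect_error(sample_zinb(5, 2, 1.2, 5), class = "xenosig_domain_error")

  # NB moments: mean 5, variance 5 + 25/2 = 17.5
  x <- sample_zinb(5, 2, 0, 50000, seed = 42)
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 5), 3 * se_mean)
  m4 <- mean((x - mean(x))^4)
  se_var <- sqrt((m4 - var(x)^2) / length(x))
  expect_lt(abs(var(x) - 17.5), 3 * se_var)

  # Poisson limit at huge dispersion: variance/mean ratio ~ 1
  y <- sample_zinb(4, 1e6, 0, 10000, seed = 43)
  expect_lt(abs(var(y) / mean(y) - 1), 0.05)

  # reproducible from seed
  expect_identical(sample_zinb(3, 1, 0.2, 100, seed = 9),
                   sample_zinb(3, 1, 0.2, 100, seed = 9))
})

test_that("simulate_bundle is deterministic and validates its config", {
  cfg <- sim_config(seed = 5, n_cells_per_species = 120, n_genes_per_species = 80,
                    n_ortholog_pairs = 60, n_up_genes = 8, n_down_genes = 8,
                    mito_gene_count = 4, n_outlier_cells = 6,
                    n_contaminant_cells = 10)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$mouse$counts, b2$mouse$counts)
  expect_identical(b1$human$counts, b2$human$counts)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$embeddings, b2$embeddings)

  expect_error(sim_config(seed = 1, n_ortholog_pairs = 500,
                          n_genes_per_species = 400),
               class = "xenosig_config_error")
  expect_error(sim_config(seed = 1, zone_fractions = c(0.5, 0.5, 0.5)),
               class = "xenosig_config_error")
})

test_that("zinb_dropout = 1 yields all-zero count matrices", {
  b <- simulate_bundle(sim_config(seed = 2, n_cells_per_species = 60,
                                  n_genes_per_species = 60, n_ortholog_pairs = 40,
                                  n_up_genes = 5, n_down_genes = 5,
                                  mito_gene_count = 3, zinb_dropout = 1,
                                  n_outlier_cells = 0, n_contaminant_cells = 0))
  expect_equal(sum(b$mouse$counts), 0)
  expect_equal(sum(b$human$counts), 0)
})

test_that("planted up-genes carry the configured fold change in expectation", {
  b <- default_bundle()
  tr <- b$truth$cells[b$truth$cells$species == "mouse", ]
  gt <- b$truth$genes[b$truth$genes$species == "mouse", ]
  counts <- as.matrix(b$mouse$counts)
  hep <- !tr$outlier & !tr$contaminant
  up <- gt$role == "up"
  # compare library-size-adjusted means between signature and background cells
  lib <- rowSums(counts)
  cpm <- counts / lib
  ratio <- colMeans(cpm[hep & tr$signature, up]) /
    colMeans(cpm[hep & !tr$signature, up])
  lfc <- b$config$signature_log2fc
  expect_lt(abs(median(log2(ratio)) - lfc), 0.15)
})

test_that("ortholog embedding pairs dominate random non-pairs", {
  b <- small_bundle()
  emb <- b$embeddings
  en <- emb / sqrt(rowSums(emb^2))
  gt <- b$truth$genes
  mg <- gt[gt$species == "mouse" & !is.na(gt$ortholog), ]
  pair_cos <- vapply(seq_len(nrow(mg)), function(i)
    sum(en[mg$symbol[i], ] * en[mg$ortholog[i], ]), numeric(1))
  set.seed(1)
  rnd <- replicate(500, {
    i <- sample(rownames(en), 2)
    sum(en[i[1], ] * en[i[2], ])
  })
  expect_gt(median(pair_cos) - median(rnd), 0.5)
})

test_that("make_homology_table emulates 1:1, many-to-many and mouse-only rows", {
  # hand-built truth: 10 planted 1:1 pairs
  genes <- tibble::tibble(
    symbol = c(sprintf("m%02d", 1:12), sprintf("H%02d", 1:10)),
    species = rep(c("mouse", "human"), c(12, 10)),
    role = "null",
    ortholog = c(sprintf("H%02d", 1:10), NA, NA, sprintf("m%02d", 1:10)),
    mito = FALSE)
  tab <- make_homology_table(list(genes = genes), frac_many_to_many = 0,
                             n_mouse_only = 0)
  expect_equal(nrow(tab), 10)
  expect_equal(length(unique(tab$class_key)), 10)

  tab2 <- make_homology_table(list(genes = genes), frac_many_to_many = 0.2,
                              n_mouse_only = 2)
  expect_equal(length(unique(tab2$class_key[!is.na(tab2$human_symbol)])), 8)
  expect_equal(sum(is.na(tab2$human_symbol)), 2)

  # a constructed 2-mouse : 1-human group shares one key
  grp <- tibble::tibble(mouse_symbol = c("mA", "mB"), human_symbol = "HX",
                        class_key = "K1")
  conv <- convert_symbols_mgi(c("mA", "mB"), grp)
  expect_equal(conv$converted, "HX")

  # round trip: mouse -> key -> human -> key -> mouse recovers 1:1 partners
  fwd <- merge(data.frame(mouse_symbol = tab$mouse_symbol), tab)
  back <- merge(data.frame(human_symbol = fwd$human_symbol), tab)
  expect_setequal(back$mouse_symbol, tab$mouse_symbol)
})

test_that("planted outliers violate exactly one threshold of their preset", {
  b <- default_bundle()
  preset <- b$config$qc
  for (s in c("mouse", "human")) {
    tr <- b$truth$cells[b$truth$cells$species == s, ]
    qc <- apply_qc_filter(compute_cell_qc(b[[s]]), preset)
    out_reasons <- qc$reason[tr$outlier]
    expect_true(all(nchar(out_reasons) > 0))
    expect_false(any(grepl(",", out_reasons, fixed = TRUE)))
    expect_true(all(qc$reason[!tr$outlier] == ""))
  }
})

test_that("write_bundle produces a readable on-disk layout", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  m <- read_counts(file.path(dir, "mouse"))
  expect_equal(as.matrix(m$counts), as.matrix(b$mouse$counts),
               ignore_attr = FALSE)
  hom <- read.delim(file.path(dir, "shared", "homology.tsv"))
  expect_equal(nrow(hom), nrow(b$homology))
  emb <- read.delim(file.path(dir, "shared", "embeddings.tsv"))
  expect_equal(nrow(emb), nrow(b$embeddings))
})
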