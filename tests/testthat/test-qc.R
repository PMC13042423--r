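test_that("compute_cell_qc handles the arithmetic and degenerate cases", {
  cm <- count_matrix(matrix(c(3, 0, 2,
                              0, 0, 0), 2, 3, byrow = TRUE),
                     cell_meta = data.frame(barcode = c("a", "b")),
                     gene_meta = data.frame(symbol = c("g1", "g2", "g3"),
                                            mito = c(FALSE, FALSE, TRUE)))
  qc <- compute_cell_qc(cm)
  expect_equal(qc$detected_genes, c(2L, 0L))
  expect_equal(qc$total_umi, c(5, 0))
  expect_equal(qc$mito_fraction, c(0.4, 0))
})

test_that("compute_cell_qc equals a dense loop-based recomputation", {
  b <- default_bundle()
  qc <- compute_cell_qc(b$mouse)
  want <- oracle_cell_qc(as.matrix(b$mouse$counts), b$mouse$gene_meta$mito)
  expect_equal(qc$detected_genes, want$detected_genes)
  expect_equal(qc$total_umi, want$total_umi)
  expect_equal(qc$mito_fraction, want$mito_fraction)
})

test_that("QC presets carry the published thresholds", {
  p <- qc_preset("mouse_hepatocyte")
  expect_equal(p$max_mito_fraction, 0.05)
  expect_equal(p$min_genes, 2000L)
  expect_equal(p$max_genes, 10000L)
  expect_equal(p$max_umi, 100000L)
  p <- qc_preset("mouse_hsc")
  expect_equal(c(p$min_genes, p$max_genes, p$max_umi), c(2000L, 7000L, 50000L))
  p <- qc_preset("human_hepatocyte")
  expect_equal(c(p$min_genes, p$max_genes, p$max_umi), c(1500L, 6000L, 40000L))
  expect_error(qc_preset("whole_blood"), class = "xenosig_config_error")
  expect_error(qc_preset("mouse_hsc", min_genes = 8000),
               class = "xenosig_config_error")
})

test_that("threshold boundaries are kept (strict published wording)", {
  qc <- tibble::tibble(barcode = c("over_mito", "at_mito", "boundary_human"),
                       detected_genes = c(3000L, 3000L, 1500L),
                       total_umi = c(10000, 10000, 40000),
                       mito_fraction = c(0.06, 0.05, 0.05))
  out_m <- apply_qc_filter(qc, qc_preset("mouse_hepatocyte"))
  expect_false(out_m$keep[1])   # 0.06 exceeds 0.05
  expect_equal(out_m$reason[1], "mito")
  expect_true(out_m$keep[2])    # exactly 0.05 is kept
  out_h <- apply_qc_filter(qc[3, ], qc_preset("human_hepatocyte"))
  expect_true(out_h$keep)       # all three metrics exactly at the boundary
})

test_that("apply_qc_filter agrees exactly with per-cell brute force", {
  set.seed(31)
  n <- 10000
  qc <- tibble::tibble(barcode = sprintf("c%05d", 1:n),
                       detected_genes = sample(0:12000, n, replace = TRUE),
                       total_umi = runif(n, 0, 150000),
                       mito_fraction = runif(n))
  for (preset_name in c("mouse_hepatocyte", "mouse_hsc", "human_hepatocyte")) {
    p <- qc_preset(preset_name)
    got <- apply_qc_filter(qc, p)$keep
    want <- vapply(seq_len(n), function(i) {
      qc$mito_fraction[i] <= p$max_mito_fraction &&
        qc$detected_genes[i] >= p$min_genes &&
        qc$detected_genes[i] <= p$max_genes &&
        qc$total_umi[i] <= p$max_umi
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("normalize_log matches its closed form and dense recomputation", {
  # single count in a 10,000-UMI cell -> log(2)
  m <- matrix(0, 1, 3)
  m[1, 1] <- 1; m[1, 2] <- 9999
  cm <- matrix(m, 1, 3, dimnames = list("c1", c("g1", "g2", "g3")))
  out <- normalize_log(cm)
  expect_equal(out[1, 1], log(2), tolerance = 1e-12)

  set.seed(5)
  x <- matrix(rpois(50 * 20, 3), 50, 20,
              dimnames = list(sprintf("c%d", 1:50), sprintf("g%d", 1:20)))
  got <- as.matrix(normalize_log(x))
  tot <- rowSums(x)
  want <- log1p(x / tot * 1e4)
  expect_equal(got, want, tolerance = 1e-12)

  # scale invariance per cell
  expect_equal(as.matrix(normalize_log(x * 7L)), want, tolerance = 1e-12)

  # all-zero cells give all-zero rows
  x[3, ] <- 0
  expect_true(all(as.matrix(normalize_log(x))[3, ] == 0))
})

test_that("QC filtering and contaminant exclusion compose", {
  b <- small_bundle()
  qc <- apply_qc_filter(compute_cell_qc(b$mouse), b$config$qc)
  norm_all <- normalize_log(b$mouse)
  # exclusion computed on the filtered subset
  kept <- subset_cells(b$mouse, cells = qc$keep)
  norm_kept <- normalize_log(kept)
  labs <- cluster_cells(norm_kept, n_clusters = 4, seed = 3)
  det <- compute_cell_qc(kept)$detected_genes
  mask <- exclude_contaminant_clusters(norm_kept, labs, detected_genes = det)
  # identical to filtering first then excluding, by construction of the API;
  # check the composed mask against truth
  tr <- b$truth$cells[b$truth$cells$species == "mouse", ][qc$keep, ]
  expect_true(all(!mask[tr$contaminant]))
})
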