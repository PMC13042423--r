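#' Configuration for the two-species synthetic data generator
#'
#' Builds the parameter set for [simulate_bundle()]. Defaults describe a
#' desk-scale pair of hepatocyte datasets: ~1,000 cells and 400 genes per
#' species, 300 planted 1:1 ortholog pairs, a 10% "p16-high-like" signature
#' subpopulation confined to zone 3 carrying a correlated up/down program in
#' both species, three liver zones with marker-gene programs, mitochondrial
#' genes, threshold-violating outlier cells, and a small non-hepatocyte
#' (Ptprc/Dcn/Pecam1-expressing) contaminant population.
#'
#' @param seed Integer seed; the bundle is fully reproducible from it.
#' @param n_cells_per_species Total cells per species, including outliers and
#'   contaminants.
#' @param n_genes_per_species Genes per species.
#' @param n_ortholog_pairs Number of planted 1:1 ortholog pairs (the first
#'   `n_ortholog_pairs` panel positions, which include the marker genes).
#' @param frac_signature_cells Fraction of cells carrying the planted
#'   signature program (placed in zone 3).
#' @param n_up_genes,n_down_genes Sizes of the planted up/down programs; drawn
#'   from ortholog-paired genes so the program exists in both species.
#' @param signature_log2fc Planted effect size in log2 units: up genes are
#'   scaled by `2^signature_log2fc` in signature cells, down genes by the
#'   reciprocal.
#' @param zone_fractions Length-3 vector of hepatocyte zone proportions,
#'   summing to 1.
#' @param mito_gene_count Number of mitochondrial genes (named `mt-*`/`MT-*`
#'   and flagged in gene metadata).
#' @param mito_target_fraction Expected mitochondrial UMI fraction in healthy
#'   cells; kept well below the 0.05 QC threshold so only planted outliers
#'   violate it.
#' @param zinb_dispersion Negative binomial size parameter theta (variance =
#'   mu + mu^2/theta).
#' @param zinb_dropout Structural zero-inflation probability.
#' @param zone_effect Multiplicative boost of a zone's marker genes in cells
#'   of that zone.
#' @param marker_base_mean Baseline mean count of zone marker genes.
#' @param libsize_sdlog Log-sd of the per-cell lognormal library-size factor.
#' @param embedding_dim Dimension of the synthetic protein embeddings.
#' @param embedding_noise_sd Per-coordinate noise added independently to each
#'   member of an ortholog pair around a shared base vector.
#' @param n_outlier_cells Cells per species planted to violate exactly one QC
#'   threshold of `qc` (cycling over high-UMI, high-mito and low-gene types).
#' @param n_contaminant_cells Non-hepatocyte cells per species expressing the
#'   contaminant markers.
#' @param qc A [qc_preset()] the outliers are planted against; defaults to
#'   the synthetic-scale preset (the published thresholds assume whole-
#'   transcriptome panels far larger than this generator's).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_species = 1000L,
                       n_genes_per_species = 400L,
                       n_ortholog_pairs = 300L,
                       frac_signature_cells = 0.1,
                       n_up_genes = 40L,
                       n_down_genes = 40L,
                       signature_log2fc = 1.5,
                       zone_fractions = c(1, 1, 1) / 3,
                       mito_gene_count = 10L,
                       mito_target_fraction = 0.015,
                       zinb_dispersion = 2,
                       zinb_dropout = 0.1,
                       zone_effect = 8,
                       marker_base_mean = 10,
                       libsize_sdlog = 0.3,
                       embedding_dim = 32L,
                       embedding_noise_sd = 0.05,
                       n_outlier_cells = 30L,
                       n_contaminant_cells = 60L,
                       qc = qc_preset("synthetic_hepatocyte")) {
  cfg <- list(seed = as.integer(seed),
              n_cells_per_species = as.integer(n_cells_per_species),
              n_genes_per_species = as.integer(n_genes_per_species),
              n_ortholog_pairs = as.integer(n_ortholog_pairs),
              frac_signature_cells = frac_signature_cells,
              n_up_genes = as.integer(n_up_genes),
              n_down_genes = as.integer(n_down_genes),
              signature_log2fc = signature_log2fc,
              zone_fractions = zone_fractions,
              mito_gene_count = as.integer(mito_gene_count),
              mito_target_fraction = mito_target_fraction,
              zinb_dispersion = zinb_dispersion,
              zinb_dropout = zinb_dropout,
              zone_effect = zone_effect,
              marker_base_mean = marker_base_mean,
              libsize_sdlog = libsize_sdlog,
              embedding_dim = as.integer(embedding_dim),
              embedding_noise_sd = embedding_noise_sd,
              n_outlier_cells = as.integer(n_outlier_cells),
              n_contaminant_cells = as.integer(n_contaminant_cells),
              qc = qc)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    assert_that(n_cells_per_species > 0 && n_genes_per_species > 0,
                "cell and gene counts must be positive", class = "xenosig_config_error")
    assert_that(n_ortholog_pairs <= n_genes_per_species,
                "n_ortholog_pairs cannot exceed n_genes_per_species",
                class = "xenosig_config_error")
    assert_that(frac_signature_cells >= 0 && frac_signature_cells <= 1,
                "frac_signature_cells must lie in [0, 1]", class = "xenosig_config_error")
    assert_that(zinb_dropout >= 0 && zinb_dropout <= 1,
                "zinb_dropout must lie in [0, 1]", class = "xenosig_config_error")
    assert_that(zinb_dispersion > 0, "zinb_dispersion must be positive",
                class = "xenosig_config_error")
    assert_that(length(zone_fractions) == 3 && abs(sum(zone_fractions) - 1) < 1e-12,
                "zone_fractions must be a 3-vector summing to 1",
                class = "xenosig_config_error")
    assert_that(embedding_noise_sd >= 0, "embedding_noise_sd must be non-negative",
                class = "xenosig_config_error")
    n_markers <- 6L + 3L
    assert_that(n_up_genes + n_down_genes + n_markers + mito_gene_count <= n_ortholog_pairs,
                "not enough ortholog pairs to host markers, mito genes and the up/down programs",
                class = "xenosig_config_error")
    assert_that(n_outlier_cells + n_contaminant_cells < n_cells_per_species,
                "outliers plus contaminants must leave room for hepatocytes",
                class = "xenosig_config_error")
  })
  invisible(cfg)
}

#' Draw from a zero-inflated negative binomial
#'
#' With probability `dropout` an observation is a structural zero; otherwise
#' it is negative binomial with mean `mean` and size (dispersion) `dispersion`
#' (variance `mean + mean^2/dispersion`). This is the sampling counterpart of
#' the ZINB likelihood used by [zinb_nll()] and the macrogene autoencoder.
#'
#' @param mean Positive mean (recycled to length `n`).
#' @param dispersion Positive NB size parameter (recycled).
#' @param dropout Structural zero probability in `[0, 1]`.
#' @param n Number of draws.
#' @param seed Optional integer seed for a self-contained reproducible draw.
#' @return An integer vector of length `n`.
#' @examples
#' sample_zinb(5, 2, 0.1, 10, seed = 1)
#' @export
sample_zinb <- function(mean, dispersion, dropout, n, seed = NULL) {
  assert_that(all(mean > 0), "mean must be positive", class = "xenosig_domain_error")
  assert_that(all(dispersion > 0), "dispersion must be positive",
              class = "xenosig_domain_error")
  assert_that(dropout >= 0 && dropout <= 1, "dropout must lie in [0, 1]",
              class = "xenosig_domain_error")
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(integer(0))
  x <- stats::rnbinom(n, size = dispersion, mu = mean)
  if (dropout > 0) x[stats::runif(n) < dropout] <- 0L
  as.integer(x)
}

# matrix-shaped ZINB draws; mu is an n x g matrix of means
rzinb_matrix <- function(mu, size, dropout) {
  x <- stats::rnbinom(length(mu), size = size, mu = as.vector(mu))
  if (dropout > 0) x[stats::runif(length(x)) < dropout] <- 0L
  matrix(as.integer(x), nrow = nrow(mu))
}

# panel layout shared by both species: zone markers, contaminant markers,
# mito genes, then generic genes; the first n_ortholog_pairs positions are the
# planted 1:1 orthologs
panel_symbols <- function(cfg, species) {
  zone_markers <- c("Sds", "Cyp2f2", "Hamp", "Igfbp2", "Glul", "Cyp2e1")
  contam_markers <- c("Ptprc", "Dcn", "Pecam1")
  mito <- paste0("mt-Sim", seq_len(cfg$mito_gene_count))
  n_named <- length(zone_markers) + length(contam_markers) + cfg$mito_gene_count
  generic <- sprintf("Gene%04d", seq_len(cfg$n_genes_per_species - n_named))
  sym <- c(zone_markers, contam_markers, mito, generic)
  if (species == "human") sym <- toupper(sym)
  sym
}

#' Generate a paired two-species synthetic dataset with ground truth
#'
#' Draws mouse and human hepatocyte count matrices from a gene-wise ZINB model
#' with lognormal baseline means shared across ortholog pairs, multiplicative
#' zone-marker effects, a planted signature subpopulation in zone 3 of both
#' species, per-cell lognormal library-size factors, planted QC outliers,
#' contaminant cells, a homology table, and protein-style embeddings in which
#' ortholog pairs share a base vector up to additive noise.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle`: `mouse` and `human`
#'   ([count_matrix()]s), `homology` (tibble: mouse_symbol, human_symbol,
#'   class_key), `embeddings` (gene x dim matrix spanning both species, with
#'   a `species` attribute), `truth` (`$cells` and `$genes` tibbles), and the
#'   `config`.
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  # shared baseline means for ortholog pairs, independent for species-specific
  base_shared <- stats::rlnorm(cfg$n_ortholog_pairs, meanlog = 0, sdlog = 1)
  species_data <- list()
  gene_truth <- list()
  for (species in c("mouse", "human")) {
    sym <- panel_symbols(cfg, species)
    G <- cfg$n_genes_per_species
    base <- stats::rlnorm(G, meanlog = 0, sdlog = 1)
    base[seq_len(cfg$n_ortholog_pairs)] <- base_shared
    zone_idx <- lapply(1:3, function(z) c(2 * z - 1, 2 * z))  # marker columns per zone
    base[1:6] <- cfg$marker_base_mean
    contam_idx <- 7:9
    base[contam_idx] <- 0.2
    mito_idx <- 9L + seq_len(cfg$mito_gene_count)
    # calibrate mito means to the target fraction of the expected library
    base[mito_idx] <- cfg$mito_target_fraction / (1 - cfg$mito_target_fraction) *
      sum(base[-mito_idx]) / cfg$mito_gene_count

    first_free <- 10L + cfg$mito_gene_count
    up_idx <- first_free - 1L + seq_len(cfg$n_up_genes)
    down_idx <- first_free - 1L + cfg$n_up_genes + seq_len(cfg$n_down_genes)
    contam_prog_idx <- (cfg$n_ortholog_pairs + 1L):G  # species-specific tail hosts the
    contam_prog_idx <- utils::head(contam_prog_idx, 30L)  # contaminant program

    n <- cfg$n_cells_per_species
    n_out <- cfg$n_outlier_cells
    n_con <- cfg$n_contaminant_cells
    n_hep <- n - n_out - n_con
    # cell layout: hepatocytes (zones, signature inside zone 3), outliers
    # (ordinary zone cells later perturbed), contaminants
    zone <- c(sample(1:3, n_hep + n_out, replace = TRUE, prob = cfg$zone_fractions),
              rep(NA_integer_, n_con))
    is_outlier <- c(rep(FALSE, n_hep), rep(TRUE, n_out), rep(FALSE, n_con))
    is_contam <- c(rep(FALSE, n_hep + n_out), rep(TRUE, n_con))
    n_sig <- round(cfg$frac_signature_cells * n)
    z3 <- which(zone == 3 & !is_outlier)
    assert_that(length(z3) >= n_sig, "not enough zone-3 cells to host the signature",
                class = "xenosig_config_error")
    sig_cells <- z3[seq_len(n_sig)]
    is_sig <- rep(FALSE, n); is_sig[sig_cells] <- TRUE

    lib <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$libsize_sdlog)
    mu <- outer(lib, base)
    for (z in 1:3) {
      in_z <- !is.na(zone) & zone == z
      # zone markers are boosted in their home zone and suppressed elsewhere,
      # mirroring the strong zone restriction of the real marker genes
      mu[in_z, zone_idx[[z]]] <- mu[in_z, zone_idx[[z]]] * cfg$zone_effect
      for (zo in setdiff(1:3, z))
        mu[in_z, zone_idx[[zo]]] <- mu[in_z, zone_idx[[zo]]] / cfg$zone_effect
    }
    mu[is_sig, up_idx] <- mu[is_sig, up_idx] * 2^cfg$signature_log2fc
    mu[is_sig, down_idx] <- mu[is_sig, down_idx] * 2^(-cfg$signature_log2fc)
    if (n_con > 0) {
      mu[is_contam, ] <- mu[is_contam, ] * 0.5
      mu[is_contam, contam_idx] <- mu[is_contam, contam_idx] * 100
      mu[is_contam, contam_prog_idx] <- mu[is_contam, contam_prog_idx] * 8
    }

    counts <- rzinb_matrix(mu, cfg$zinb_dispersion, cfg$zinb_dropout)

    # plant outliers: each violates exactly one threshold of cfg$qc
    outlier_type <- rep(NA_character_, n)
    out_cells <- which(is_outlier)
    types <- rep(c("high_umi", "high_mito", "low_genes"), length.out = n_out)
    for (k in seq_along(out_cells)) {
      i <- out_cells[k]
      outlier_type[i] <- types[k]
      if (types[k] == "high_umi") {
        tot <- sum(counts[i, ])
        counts[i, ] <- counts[i, ] * ceiling(1.5 * cfg$qc$max_umi / max(tot, 1))
      } else if (types[k] == "high_mito") {
        tot <- sum(counts[i, ])
        add <- ceiling(0.3 * max(tot, 100) / cfg$mito_gene_count)
        counts[i, mito_idx] <- counts[i, mito_idx] + add
      } else {
        keep <- sample(setdiff(seq_len(G), mito_idx), floor(cfg$qc$min_genes / 2))
        dropped <- setdiff(seq_len(G), keep)
        counts[i, dropped] <- 0L
        counts[i, keep] <- pmax(counts[i, keep], 1L)
      }
    }

    role <- rep("null", G)
    role[1:6] <- rep(c("zone1_marker", "zone2_marker", "zone3_marker"), each = 2)
    role[contam_idx] <- "contam_marker"
    role[up_idx] <- "up"
    role[down_idx] <- "down"
    role[contam_prog_idx] <- "contam_program"
    mito_flag <- seq_len(G) %in% mito_idx

    other <- if (species == "mouse") "human" else "mouse"
    partner <- rep(NA_character_, G)
    partner[seq_len(cfg$n_ortholog_pairs)] <-
      panel_symbols(cfg, other)[seq_len(cfg$n_ortholog_pairs)]

    barcodes <- sprintf("%s_cell_%04d", species, seq_len(n))
    cm <- count_matrix(counts,
                       cell_meta = tibble::tibble(barcode = barcodes, species = species),
                       gene_meta = tibble::tibble(symbol = sym, mito = mito_flag))
    species_data[[species]] <- list(
      cm = cm,
      cells = tibble::tibble(barcode = barcodes, species = species,
                             zone = ifelse(is.na(zone), NA_character_,
                                           paste0("zone", zone)),
                             signature = is_sig, outlier = is_outlier,
                             outlier_type = outlier_type, contaminant = is_contam))
    gene_truth[[species]] <- tibble::tibble(symbol = sym, species = species,
                                            role = role, ortholog = partner,
                                            mito = mito_flag)
  }

  genes <- dplyr::bind_rows(gene_truth)
  cells <- dplyr::bind_rows(lapply(species_data, `[[`, "cells"))
  truth <- list(cells = cells, genes = genes)
  homology <- make_homology_table(truth)

  # embeddings: ortholog pairs share a base vector up to additive noise
  d <- cfg$embedding_dim
  msym <- panel_symbols(cfg, "mouse"); hsym <- panel_symbols(cfg, "human")
  G <- cfg$n_genes_per_species
  emb_m <- matrix(stats::rnorm(G * d), G, d)
  emb_h <- matrix(stats::rnorm(G * d), G, d)
  np <- cfg$n_ortholog_pairs
  base_emb <- matrix(stats::rnorm(np * d), np, d)
  emb_m[seq_len(np), ] <- base_emb + matrix(stats::rnorm(np * d, sd = cfg$embedding_noise_sd), np, d)
  emb_h[seq_len(np), ] <- base_emb + matrix(stats::rnorm(np * d, sd = cfg$embedding_noise_sd), np, d)
  embeddings <- rbind(emb_m, emb_h)
  rownames(embeddings) <- c(msym, hsym)
  attr(embeddings, "species") <- rep(c("mouse", "human"), each = G)

  structure(list(mouse = species_data$mouse$cm, human = species_data$human$cm,
                 homology = homology, embeddings = embeddings,
                 truth = truth, config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> seed %d: mouse %d x %d, human %d x %d, %d homology rows\n",
              x$config$seed, nrow(x$mouse$counts), ncol(x$mouse$counts),
              nrow(x$human$counts), ncol(x$human$counts), nrow(x$homology)))
  invisible(x)
}

#' Build a homology table from planted gene truth
#'
#' Emulates an MGI-style vertebrate homology table: mouse and human symbols
#' sharing a class key are homologs. Each planted 1:1 pair receives its own
#' key; a configurable fraction of adjacent pairs is merged into shared keys
#' (many-to-many groups) and a few mouse-only rows without a human partner
#' are appended.
#'
#' @param truth The `truth` element of a [simulate_bundle()] result (or any
#'   list with a `$genes` tibble holding `symbol`, `species`, `ortholog`).
#' @param frac_many_to_many Fraction of ortholog pairs merged pairwise into
#'   shared (2 mouse : 2 human) class keys.
#' @param n_mouse_only Number of unpaired mouse genes given a key with no
#'   human member.
#' @return A tibble with columns `mouse_symbol`, `human_symbol`, `class_key`.
#' @export
make_homology_table <- function(truth, frac_many_to_many = 0.02, n_mouse_only = 2L) {
  g <- truth$genes
  pairs <- g[g$species == "mouse" & !is.na(g$ortholog), c("symbol", "ortholog")]
  assert_that(nrow(pairs) > 0, "truth contains no ortholog partners")
  names(pairs) <- c("mouse_symbol", "human_symbol")
  key <- sprintf("KEY%05d", seq_len(nrow(pairs)))
  n_merge <- floor(frac_many_to_many * nrow(pairs))
  if (n_merge > 0) {
    # merge the last 2*n_merge pairs two-by-two into shared keys
    tail_idx <- nrow(pairs) - seq_len(2 * n_merge) + 1L
    for (j in seq_len(n_merge)) {
      a <- tail_idx[2 * j - 1]; b <- tail_idx[2 * j]
      key[b] <- key[a]
    }
  }
  tab <- tibble::tibble(mouse_symbol = pairs$mouse_symbol,
                        human_symbol = pairs$human_symbol,
                        class_key = key)
  unpaired <- g$symbol[g$species == "mouse" & is.na(g$ortholog)]
  n_mouse_only <- min(n_mouse_only, length(unpaired))
  if (n_mouse_only > 0) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      mouse_symbol = utils::tail(unpaired, n_mouse_only),
      human_symbol = NA_character_,
      class_key = sprintf("KEYM%04d", seq_len(n_mouse_only))))
  }
  tab
}

#' Write a simulated bundle to disk
#'
#' Writes both species' count matrices ([write_counts()] layout), the
#' homology table and embeddings as TSV, and the truth tables as TSV plus a
#' JSON config echo, under `mouse/`, `human/` and `shared/` subdirectories.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(file.path(path, "shared"), recursive = TRUE, showWarnings = FALSE)
  write_counts(bundle$mouse, file.path(path, "mouse"))
  write_counts(bundle$human, file.path(path, "human"))
  utils::write.table(bundle$homology, file.path(path, "shared", "homology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emb <- data.frame(symbol = rownames(bundle$embeddings),
                    species = attr(bundle$embeddings, "species"),
                    unclass(as.data.frame(bundle$embeddings)), check.names = FALSE)
  utils::write.table(emb, file.path(path, "shared", "embeddings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$cells, file.path(path, "shared", "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$genes, file.path(path, "shared", "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg$qc <- unclass(cfg$qc)
  jsonlite::write_json(unclass(cfg), file.path(path, "shared", "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
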