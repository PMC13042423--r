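#' Configuration for the end-to-end pipeline
#'
#' Assembles and validates the parameters of every stage before any stage
#' runs. Stage seeds are derived from the global seed by small fixed offsets
#' so that one integer reproduces the whole run. Unknown stage parameters are
#' rejected.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory; each stage writes to its own
#'   subdirectory.
#' @param sim A [sim_config()]; defaults to a 600-cell-per-species bundle
#'   (the desk scale used throughout the package).
#' @param qc Name of the [qc_preset()] applied to both species.
#' @param cluster List: `n_clusters`, `n_hvg`, `n_pcs`.
#' @param deg List: `lfc_threshold`, `alpha`, `min_pct`.
#' @param gsva A [gsva_params()].
#' @param saturn List: `M`, `steps`, `lambda_s`, `lr`, `batch_size`,
#'   `latent_dim`, `threshold`.
#' @param tomscore List: `cut_mode`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("xenosig_run_"),
                            sim = NULL,
                            qc = "synthetic_hepatocyte",
                            cluster = list(),
                            deg = list(),
                            gsva = gsva_params(),
                            saturn = list(),
                            tomscore = list()) {
  seed <- as.integer(seed)
  sim <- sim %||% sim_config(seed = seed, n_cells_per_species = 600L)
  stopifnot(inherits(sim, "sim_config"), inherits(gsva, "gsva_params"))
  merge_stage <- function(user, defaults, stage) {
    unknown <- setdiff(names(user), names(defaults))
    assert_that(length(unknown) == 0,
                sprintf("unknown %s parameter(s): %s", stage,
                        paste(unknown, collapse = ", ")),
                class = "xenosig_config_error")
    utils::modifyList(defaults, user)
  }
  cluster <- merge_stage(cluster, list(n_clusters = 5L, n_hvg = 2000L, n_pcs = 10L),
                         "cluster")
  deg <- merge_stage(deg, list(lfc_threshold = 0.3, alpha = 0.05, min_pct = 0.10),
                     "deg")
  saturn <- merge_stage(saturn, list(M = 50L, steps = 2000L, lambda_s = 1,
                                     lr = 1e-3, batch_size = 128L,
                                     latent_dim = 32L, threshold = 0.85),
                        "saturn")
  tomscore <- merge_stage(tomscore, list(cut_mode = "tertile"), "tomscore")
  preset <- qc_preset(qc)  # validates the name
  assert_that(cluster$n_pcs < min(sim$n_cells_per_species, sim$n_genes_per_species),
              "n_pcs must be below min(cells, genes)", class = "xenosig_config_error")
  assert_that(saturn$M <= 2L * sim$n_genes_per_species,
              "more macrogenes than genes", class = "xenosig_config_error")
  structure(list(seed = seed, outdir = outdir, sim = sim, qc = preset,
                 cluster = cluster, deg = deg, gsva = gsva, saturn = saturn,
                 tomscore = tomscore),
            class = "pipeline_config")
}

checksum_dir <- function(path) {
  files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- substring(names(sums), nchar(path) + 2)
  as.list(sums)
}

#' Run the full synthetic-benchmark pipeline
#'
#' Executes simulate, QC, clustering with contaminant exclusion, zonation,
#' differential expression (the distinctive zone-3 subcluster against the
#' remaining zone-3 cells), both gene-conversion routes (homology table and
#' macrogene pairing), and Tom scoring of the human cells, writing each
#' stage's tables under `config$outdir` and returning a machine-readable run
#' report. Identical configurations (including the seed) yield identical
#' output checksums.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`: per-stage cell/gene counts,
#'   parameter echo, output checksums, warnings, and wall time. Also written
#'   as `report.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(), warnings = character(0))
  note <- function(w) report$warnings <<- c(report$warnings, conditionMessage(w))

  withCallingHandlers({
    ## simulate --------------------------------------------------------------
    bundle <- simulate_bundle(config$sim)
    write_bundle(bundle, file.path(out, "simulate"))
    report$stages$simulate <- list(
      status = "ok",
      n_cells = stats::setNames(as.list(c(nrow(bundle$mouse$counts), nrow(bundle$human$counts))),
                                c("mouse", "human")),
      n_genes = ncol(bundle$mouse$counts))

    ## qc --------------------------------------------------------------------
    dir.create(file.path(out, "qc"), showWarnings = FALSE)
    kept <- list(); qc_n <- list()
    for (s in c("mouse", "human")) {
      qc <- apply_qc_filter(compute_cell_qc(bundle[[s]]), config$qc)
      utils::write.table(qc, file.path(out, "qc", paste0(s, "_qc.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      kept[[s]] <- subset_cells(bundle[[s]], cells = qc$keep)
      qc_n[[s]] <- list(before = nrow(qc), after = sum(qc$keep),
                        excluded = sum(!qc$keep))
    }
    report$stages$qc <- c(list(status = "ok", preset = config$qc$name), qc_n)

    ## cluster + contaminant exclusion + zones --------------------------------
    dir.create(file.path(out, "zones"), showWarnings = FALSE)
    norm <- list(); labels <- list(); hep <- list()
    for (s in c("mouse", "human")) {
      norm[[s]] <- normalize_log(kept[[s]])
      labels[[s]] <- cluster_cells(norm[[s]], n_clusters = config$cluster$n_clusters,
                                   n_hvg = config$cluster$n_hvg,
                                   n_pcs = config$cluster$n_pcs,
                                   seed = config$seed + 11L)
      markers <- if (s == "mouse") c("Ptprc", "Dcn", "Pecam1") else
        c("PTPRC", "DCN", "PECAM1")
      qc_tab <- compute_cell_qc(kept[[s]])
      mask <- exclude_contaminant_clusters(norm[[s]], labels[[s]], markers,
                                           detected_genes = qc_tab$detected_genes)
      hep[[s]] <- subset_cells(kept[[s]], cells = mask)
      norm[[s]] <- norm[[s]][mask, , drop = FALSE]
      labels[[s]] <- labels[[s]][mask]
    }
    zones <- assign_zones(norm$mouse, zonation_markers("mouse"))
    utils::write.table(zones, file.path(out, "zones", "mouse_zones.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$zones <- list(
      status = "ok",
      n_hepatocytes = stats::setNames(lapply(hep, function(x) nrow(x$counts)),
                                      names(hep)),
      zone_counts = as.list(table(zones$zone)))

    ## deg: distinctive zone-3 subcluster vs remaining zone-3 cells -----------
    dir.create(file.path(out, "deg"), showWarnings = FALSE)
    z3 <- zones$zone == "zone3"
    assert_that(sum(z3) >= 10, "too few zone-3 cells for the DEG contrast",
                class = "xenosig_empty_error")
    n3 <- norm$mouse[z3, , drop = FALSE]
    sub <- cluster_cells(n3, n_clusters = 2L, n_hvg = config$cluster$n_hvg,
                         n_pcs = min(config$cluster$n_pcs, nrow(n3) - 1L),
                         seed = config$seed + 23L)
    minority <- as.integer(names(which.min(table(sub))))
    degs <- call_degs(deg_test(n3, sub == minority, min_pct = config$deg$min_pct),
                      lfc_threshold = config$deg$lfc_threshold,
                      alpha = config$deg$alpha)
    utils::write.table(tidy(degs), file.path(out, "deg", "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(list(signature_up = degs$up, signature_down = degs$down),
              file.path(out, "deg", "signature.gmt"))
    report$stages$deg <- list(status = "ok", n_cells = sum(z3),
                              n_up = length(degs$up), n_down = length(degs$down))

    ## crossmap ---------------------------------------------------------------
    dir.create(file.path(out, "crossmap"), showWarnings = FALSE)
    model <- pretrain_macrogenes(hep$mouse, hep$human, bundle$embeddings,
                                 M = config$saturn$M, steps = config$saturn$steps,
                                 lambda_s = config$saturn$lambda_s,
                                 lr = config$saturn$lr,
                                 batch_size = config$saturn$batch_size,
                                 latent_dim = config$saturn$latent_dim,
                                 seed = config$seed + 37L)
    pairs <- pair_genes(model, threshold = config$saturn$threshold)
    utils::write.table(pairs, file.path(out, "crossmap", "gene_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$crossmap <- list(
      status = "ok", n_pairs = nrow(pairs),
      initial_loss = model$initial$total,
      final_loss = utils::tail(model$trace$total, 1))

    ## tomscore ---------------------------------------------------------------
    dir.create(file.path(out, "tomscore"), showWarnings = FALSE)
    tom <- list()
    for (m in c("mgi", "saturn")) {
      sig <- transfer_signature(degs, m, table = bundle$homology, pairs = pairs)
      tom[[m]] <- compute_tom_scores(norm$human, sig, params = config$gsva,
                                     cut_mode = config$tomscore$cut_mode)
      per_cell <- dplyr::mutate(tom[[m]]$cells, cluster = labels$human)
      utils::write.table(per_cell,
                         file.path(out, "tomscore", paste0("tom_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summarize_by_cluster(tom[[m]], labels$human),
                         file.path(out, "tomscore", paste0("tom_", m, "_by_cluster.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$stages$tomscore <- list(
      status = "ok",
      cor_updown = stats::setNames(lapply(tom, `[[`, "cor_updown"), names(tom)),
      mean_tom = stats::setNames(lapply(tom, function(x) mean(x$cells$tom)),
                                 names(tom)))
  }, warning = function(w) { note(w); rlang::cnd_muffle(w) })

  report$checksums <- checksum_dir(out)
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$config_echo <- utils::capture.output(utils::str(unclass(config), give.attr = FALSE))
  class(report) <- "run_report"
  json <- file.path(out, "report.json")
  jsonlite::write_json(unclass(report[setdiff(names(report), "config_echo")]),
                       json, auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, %d stages ok, %.1f s, %d warnings\n",
              x$seed, length(x$stages), x$wall_time_s, length(x$warnings)))
  invisible(x)
}
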