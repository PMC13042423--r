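# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small bundle for unit tests (fast to generate)
small_bundle <- function() cached("small_bundle", {
  simulate_bundle(sim_config(seed = 7, n_cells_per_species = 300L,
                             n_genes_per_species = 150L,
                             n_ortholog_pairs = 110L,
                             n_up_genes = 15L, n_down_genes = 15L,
                             mito_gene_count = 5L,
                             n_outlier_cells = 9L, n_contaminant_cells = 30L))
})

# full-size bundle at the generator defaults (QC exactness, zonation)
default_bundle <- function() cached("default_bundle", {
  simulate_bundle(sim_config(seed = 11))
})

# desk-scale bundle for the macrogene training criteria
desk_bundle <- function() cached("desk_bundle", {
  simulate_bundle(sim_config(seed = 101, n_cells_per_species = 600L))
})

# the trained desk-scale model, shared across acceptance checks
desk_model <- function() cached("desk_model", {
  b <- desk_bundle()
  pretrain_macrogenes(b$mouse, b$human, b$embeddings, M = 50L, steps = 2000L,
                      seed = 101L)
})

# random expression matrix with named dims
rand_expr <- function(n_cells, n_genes, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n_cells * n_genes), n_cells, n_genes,
         dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                         sprintf("g%03d", seq_len(n_genes))))
}
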