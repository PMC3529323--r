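# Shared fixtures built in code.

# Small hand-constructed single-experiment tables for targeted
# presence/fold-change checks. `present` is a genes x samples logical
# matrix aligned with `values`.
make_experiment <- function(values, present = NULL, experiment = "exp1",
                            n_control = ncol(values) / 2) {
  n_samples <- ncol(values)
  genes <- rownames(values) %||% sprintf("g%02d", seq_len(nrow(values)))
  condition <- rep(c("control", "treatment"),
                   c(n_control, n_samples - n_control))
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    experiment = experiment,
    class = "mito",
    condition = condition,
    replicate = stats::ave(seq_len(n_samples), condition, FUN = seq_along)
  )
  if (is.null(present)) present <- matrix(TRUE, nrow(values), n_samples)
  colnames(values) <- samples$sample_id
  colnames(present) <- samples$sample_id
  list(
    expression = dplyr::bind_cols(tibble::tibble(gene_id = genes),
                                  tibble::as_tibble(values)),
    presence = dplyr::bind_cols(tibble::tibble(gene_id = genes),
                                tibble::as_tibble(present)),
    samples = samples
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# The benchmark compendium used by the recovery tests: 14 mitochondrial +
# 13 chloroplast perturbations plus a small mixed (general-stress) group,
# 2000 genes, 3 replicates, planted |log2 FC| = 2, replicate noise 0.25,
# respond probability 0.7. Generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

acceptance_config <- function() {
  retrosig::synthetic_config(
    n_genes = 2000, n_mito = 14, n_chloro = 13, n_other = 5,
    n_replicates = 3, effect_size_log2 = 2, noise_sd_log2 = 0.25,
    respond_prob = 0.7, seed = 101L
  )
}

acceptance_compendium <- function() {
  if (is.null(.fixture_cache$comp)) {
    .fixture_cache$comp <- retrosig::simulate_compendium(acceptance_config())
  }
  .fixture_cache$comp
}

acceptance_de <- function() {
  if (is.null(.fixture_cache$de)) {
    comp <- acceptance_compendium()
    .fixture_cache$de <- retrosig::call_differential(
      comp$expression, comp$presence, comp$samples)
  }
  .fixture_cache$de
}
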