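# small fixtures built in code

make_samples <- function(n, platform = "array", age = "P2", layer = "LII") {
  tibble::tibble(sample_id = paste0("s", seq_len(n)),
                 age = rep_len(age, n),
                 layer = rep_len(layer, n),
                 animal_id = paste0("an", seq_len(n)),
                 platform = platform)
}

make_eset <- function(values, scale = "log2", samples = NULL, mask = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  }
  samples <- samples %||% make_samples(ncol(values))
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  expr_set(values, samples, scale = scale, mask = mask)
}

# paired two-cell design (one age, both layers) for simple DE tests
make_paired_samples <- function(n_animals, age = "P2") {
  tibble::tibble(
    sample_id = paste0(age, "_a", rep(seq_len(n_animals), each = 2),
                       "_", rep(c("LII", "LDeep"), n_animals)),
    age = age,
    layer = rep(c("LII", "LDeep"), n_animals),
    animal_id = paste0(age, "_a", rep(seq_len(n_animals), each = 2)),
    platform = "array")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast small simulation config for tests
test_config <- function(...) {
  simulation_config(n_mirna = 80, n_mrna = 150, n_terms = 12, ...)
}

# config for the single-strong-target recovery scenario: two mirrored
# modules responsive in both the age and the pooled layer contrast, and no
# free DE genes, so planted regulation is the only mRNA structure
recovery_config <- function(seed) {
  shapes <- rbind(both_up = c(0, 0, 2, 2, -2, -2, 0, 0) / 2,
                  both_down = -c(0, 0, 2, 2, -2, -2, 0, 0) / 2)
  colnames(shapes) <- colnames(default_module_shapes())
  simulation_config(n_mirna = 40, n_mrna = 150, n_modules = 2,
                    module_shapes = shapes, module_fraction = 0.8,
                    mrna_de_fraction = 0, seed = seed)
}
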