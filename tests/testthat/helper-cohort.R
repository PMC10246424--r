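# small configs used throughout; generation stays in code, nothing on disk
tiny_config <- function(...) {
  args <- modifyList(
    list(n_subgroups = 4L, n_marker_genes_per_subgroup = 3L,
         n_background_genes = 20L, n_cells_per_subgroup = 25L,
         n_bulk_samples = 40L, n_mutation_background_genes = 40L,
         seed = 101L),
    list(...))
  do.call(simulation_config, args)
}

# diversity table straight from a fraction matrix with rownames
dt_of <- function(fractions) diversity_table(fractions)
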