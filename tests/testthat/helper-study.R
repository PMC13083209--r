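# shared fixture: a small synthetic study, generated in code
small_study <- function(seed = 7, n_asv = 12, n_families = 8,
                        n_genotypes = 28, ramets = 3, depth = 1500) {
  simulate_study(
    n_families = n_families, n_genotypes = n_genotypes,
    ramets_per_genotype = ramets,
    params = asv_sim_params(n_asv = n_asv, depth = depth),
    seed = seed)
}

# metadata aligned to the rows of a count/residual matrix
aligned_md <- function(study, mat) {
  study$metadata[match(rownames(mat), study$metadata$tree), ]
}
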