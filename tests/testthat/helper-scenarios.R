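# Shared simulation scenarios. A "cell" is one organ-stage combination of the
# full factorial design: 5 genotypes x 4 trials x 3 replicates = 60 plots.

cell_design <- function(n_genotypes = 5, n_trials = 4, n_replicates = 3) {
  build_design(n_genotypes, n_trials, n_replicates,
               organs = "flag_leaf", stages = "anthesis")
}

# plain-noise scenario: no factor shifts, optional sparse yield effects
sim_cell <- function(seed, n_effects = 10, n_metabolites = 80, block_rho = 0,
                     target_r2 = 0.7, ...) {
  d <- cell_design()
  sim <- simulate_metabolome(
    d, n_metabolites = n_metabolites, n_blocks = max(1, n_metabolites %/% 10),
    block_rho = block_rho, seed = seed, n_effects = n_effects,
    target_r2 = target_r2, condition_shift = 0,
    effect_sds = list(organ = 0, stage = 0, condition = 0, genotype = 0), ...)
  traits <- simulate_traits(sim$matrix, sim$truth, seed = seed)
  list(matrix = sim$matrix, truth = sim$truth, traits = traits,
       y = traits$GY,
       true_features = names(which(sim$truth$true_beta != 0)))
}

# small, fast stability configuration for unit tests
fast_cfg <- list(n_grid = 50, eps = 1e-2)
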