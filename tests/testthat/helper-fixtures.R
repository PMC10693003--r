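# Shared fixtures: tiny graphs and parameter sets built in code.

single_node_graph <- function(capacity = 3L) {
  metapop_graph(data.frame(id = "P1", capacity = as.integer(capacity),
                           role = "plain", stringsAsFactors = FALSE))
}

two_node_graph <- function(capacity = 2L) {
  build_well_mixed(2, capacity)
}

neutral_params <- function(antibiotic = 0.3, founders = 10L,
                           founder_mutants = 5L, migration_prob = 0, ...) {
  sim_params(antibiotic = antibiotic, migration_prob = migration_prob,
             mutant = type_params(1, 1), wild = type_params(1, 1),
             founders = founders, founder_mutants = founder_mutants,
             intro_node = "P1", ...)
}

selective_params <- function(antibiotic = 0.3, wild_kill = 1.5,
                             migration_prob = 0, founders = 3L,
                             founder_mutants = 1L, ...) {
  sim_params(antibiotic = antibiotic, migration_prob = migration_prob,
             mutant = type_params(1, 1), wild = type_params(1, wild_kill),
             founders = founders, founder_mutants = founder_mutants,
             intro_node = "P1", ...)
}

# A hand-built trajectory for observable tests: `fractions` is the
# metapopulation mutant fraction per step on a single node of capacity
# 1000 (fraction resolution 1e-3).
fake_trajectory <- function(fractions, capacity = 1000L) {
  n <- length(fractions)
  mut <- as.integer(round(fractions * capacity))
  structure(list(step = 0:(n - 1),
                 wild = matrix(capacity - mut, ncol = 1,
                               dimnames = list(NULL, "P1")),
                 mutant = matrix(mut, ncol = 1, dimnames = list(NULL, "P1")),
                 node_ids = "P1",
                 capacity = c(P1 = capacity),
                 params = NULL, seed = NA_integer_),
            class = "sim_trajectory")
}

# Multi-node trajectory from per-node mutant-fraction matrices (full
# occupancy), used for spread-order tests.
fake_multinode_trajectory <- function(frac_matrix, capacity = 100L) {
  ids <- colnames(frac_matrix)
  mut <- matrix(as.integer(round(frac_matrix * capacity)),
                nrow = nrow(frac_matrix), dimnames = list(NULL, ids))
  structure(list(step = 0:(nrow(mut) - 1),
                 wild = matrix(capacity, nrow(mut), length(ids),
                               dimnames = list(NULL, ids)) - mut,
                 mutant = mut,
                 node_ids = ids,
                 capacity = stats::setNames(rep(capacity, length(ids)), ids),
                 params = NULL, seed = NA_integer_),
            class = "sim_trajectory")
}
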