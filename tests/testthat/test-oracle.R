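test_that("state enumeration counts and indexes every feasible configuration", {
  expect_equal(nrow(enumerate_states(single_node_graph(1))$W), 3)
  expect_equal(nrow(enumerate_states(single_node_graph(2))$W), 6)
  sp <- enumerate_states(two_node_graph(2))
  expect_equal(nrow(sp$W), 36)
  # bijectivity: every row maps back to its own index
  for (s in seq_len(nrow(sp$W))) {
    expect_equal(state_index(sp, sp$W[s, ], sp$U[s, ]), s)
  }
  expect_error(enumerate_states(build_well_mixed(4, 1600)),
               class = "metamp_too_large")
  expect_error(state_index(sp, c(3L, 0L), c(0L, 0L)),
               class = "metamp_invalid_parameter")
})

test_that("phase kernels are row-stochastic and reduce to identities in degenerate cases", {
  g <- two_node_graph(2L)
  p <- selective_params(antibiotic = 0.3, wild_kill = 1.5, migration_prob = 0.2)
  sp <- enumerate_states(g)
  for (phase in c("death", "birth", "migration", "growth", "step")) {
    K <- phase_kernel(sp, phase, g, p)
    expect_lt(max(abs(rowSums(K) - 1)), 1e-12)
  }

  # death kernel with no antibiotic is the identity
  p0 <- neutral_params(antibiotic = 0)
  D0 <- phase_kernel(sp, "death", g, p0)
  expect_lt(max(abs(D0 - diag(nrow(sp$W)))), 1e-12)

  # birth kernel row for a full node is an identity row
  g1 <- single_node_graph(2L)
  sp1 <- enumerate_states(g1)
  B <- phase_kernel(sp1, "birth", g1, p)
  full <- state_index(sp1, 1L, 1L)
  expect_equal(unname(B[full, full]), 1)

  # death kernel row for 1 wild at Z*A = 0.3 is Binomial(1, 0.7)
  D <- phase_kernel(sp1, "death", g1,
                    sim_params(antibiotic = 0.3, mutant = type_params(1, 1),
                               wild = type_params(1, 1)))
  one_w <- state_index(sp1, 1L, 0L)
  none <- state_index(sp1, 0L, 0L)
  expect_equal(unname(D[one_w, none]), 0.3)
  expect_equal(unname(D[one_w, one_w]), 0.7)

  expect_error(phase_kernel(sp, "step", g, p, max_states = 10),
               class = "metamp_too_large")
})

test_that("with no antibiotic the step kernel equals birth then migration", {
  g <- two_node_graph(2L)
  p <- neutral_params(antibiotic = 0, migration_prob = 0.3)
  sp <- enumerate_states(g)
  step_k <- phase_kernel(sp, "step", g, p)
  composed <- phase_kernel(sp, "death", g, p) %*%
    phase_kernel(sp, "birth", g, p) %*%
    phase_kernel(sp, "migration", g, p)
  expect_lt(max(abs(step_k - composed)), 1e-12)
})

test_that("absorption probabilities sum to one and honor symmetry", {
  g <- single_node_graph(2L)
  p <- neutral_params(antibiotic = 0.3)
  ft <- fixation_table(g, p)
  tot <- ft$p_mutant_fix + ft$p_wild_fix + ft$p_extinct
  expect_lt(max(abs(tot - 1)), 1e-10)

  # all-mutant start fixes with probability 1
  expect_equal(ft$p_mutant_fix[ft$w_P1 == 0 & ft$m_P1 == 2], 1)

  # neutral symmetry: (1 wild, 1 mutant) is exchangeable
  mixed <- ft[ft$w_P1 == 1 & ft$m_P1 == 1, ]
  expect_equal(mixed$p_mutant_fix, mixed$p_wild_fix, tolerance = 1e-12)

  # label swap leaves the mirrored state's fixation unchanged
  g3 <- single_node_graph(3L)
  p_sel <- selective_params(antibiotic = 0.3, wild_kill = 1.5)
  ft3 <- fixation_table(g3, p_sel)
  p_swap <- sim_params(antibiotic = 0.3, migration_prob = 0,
                       mutant = type_params(1, 1.5), wild = type_params(1, 1),
                       founders = 3L, founder_mutants = 1L, intro_node = "P1")
  ft3s <- fixation_table(g3, p_swap)
  a <- ft3$p_mutant_fix[ft3$w_P1 == 2 & ft3$m_P1 == 1]
  b <- ft3s$p_wild_fix[ft3s$w_P1 == 1 & ft3s$m_P1 == 2]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the linear solve matches brute-force forward iteration of the kernel", {
  g <- two_node_graph(2L)
  p <- selective_params(antibiotic = 0.3, wild_kill = 1.5, migration_prob = 0.2)
  sp <- enumerate_states(g)
  kern <- phase_kernel(sp, "step", g, p)
  ft <- fixation_probabilities(sp, kern)
  idx <- state_index(sp, c(1L, 1L), c(1L, 0L))
  iter <- metamp:::.absorption_by_iteration(sp, kern, idx)
  expect_equal(unname(iter["mutant"]), ft$p_mutant_fix[idx], tolerance = 1e-8)
  expect_equal(unname(iter["wild"]), ft$p_wild_fix[idx], tolerance = 1e-8)
  expect_equal(unname(iter["extinct"]), ft$p_extinct[idx], tolerance = 1e-8)
})

test_that("simulator fixation frequencies agree with the exact oracle on a tiny instance", {
  g <- single_node_graph(3L)
  p <- selective_params(antibiotic = 0.3, wild_kill = 1.5)
  chk <- check_oracle(g, p, init = list(wild = 2L, mutant = 1L),
                      n_runs = 2000, base_seed = 77)
  expect_true(attr(chk, "pass"))
})

test_that("the comparison verdict flags a corrupted probability (negative control)", {
  exact <- c(mutant = 0.4, wild = 0.45, extinct = 0.15)
  counts <- round(exact * 2000)
  ok <- metamp:::.fixation_compare(exact, counts, 2000)
  expect_true(attr(ok, "pass"))
  corrupted <- c(mutant = 0.55, wild = 0.30, extinct = 0.15)
  bad <- metamp:::.fixation_compare(corrupted, counts, 2000)
  expect_false(attr(bad, "pass"))
})
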