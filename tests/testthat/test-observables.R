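test_that("metapopulation fraction is mutants over agents and undefined when empty", {
  g <- build_star(3, 1600)
  st <- make_state(g, wild = c(333L, 333L, 333L, 0L), mutant = c(0L, 0L, 1L, 0L))
  expect_equal(metapop_fraction(st), 0.001)
  st_all <- make_state(g, wild = 0L, mutant = c(10L, 10L, 10L, 10L))
  expect_equal(metapop_fraction(st_all), 1)
  st_half <- make_state(g, wild = c(5L, 5L, 5L, 5L), mutant = c(5L, 5L, 5L, 5L))
  expect_equal(metapop_fraction(st_half), 0.5)
  st_empty <- make_state(g, wild = 0L, mutant = 0L)
  expect_error(metapop_fraction(st_empty), class = "metamp_undefined_fraction")
})

test_that("time to majority scans the trajectory for the first crossing", {
  expect_equal(time_to_majority(fake_trajectory(c(0.6, 0.7, 0.8))), 0L)
  f <- c(seq(0.01, 0.45, length.out = 37), 0.52, 0.6)
  expect_equal(time_to_majority(fake_trajectory(f)), 37L)
  expect_true(is.na(time_to_majority(fake_trajectory(rep(0.4, 50)))))
  # threshold is a parameter
  expect_equal(time_to_majority(fake_trajectory(c(0.1, 0.35, 0.9)),
                                threshold = 0.3), 1L)
})

test_that("fixation outcome classifies mutant, wild, extinct, and none", {
  expect_equal(fixation_outcome(fake_trajectory(c(0.2, 0.6, 1)))$outcome, "mutant")
  expect_equal(fixation_outcome(fake_trajectory(c(0.2, 0.1, 0)))$outcome, "wild")
  expect_equal(fixation_outcome(fake_trajectory(c(0.2, 0.4)))$outcome, "none")
  tr_ext <- fake_trajectory(c(0.5, 0.5))
  tr_ext$wild[2, ] <- 0L
  tr_ext$mutant[2, ] <- 0L
  out <- fixation_outcome(tr_ext)
  expect_equal(out$outcome, "extinct")
  expect_equal(out$step, 1L)
})

test_that("ensemble averages pool fractions with SE and reject mixed lengths", {
  tr <- fake_trajectory(c(0.1, 0.2, 0.3))
  one <- ensemble_average(list(tr))
  expect_equal(one$mean_fraction, c(0.1, 0.2, 0.3))
  expect_equal(one$se, c(0, 0, 0))

  # mirrored pair averages to one half everywhere
  pair <- ensemble_average(list(fake_trajectory(c(0.1, 0.3, 0.8)),
                                fake_trajectory(c(0.9, 0.7, 0.2))))
  expect_true(all(abs(pair$mean_fraction - 0.5) < 1e-12))

  expect_error(
    ensemble_average(list(fake_trajectory(c(0.1, 0.2)),
                          fake_trajectory(c(0.1, 0.2, 0.3)))),
    class = "metamp_invalid_input")

  # extinct replicates leave the average from the extinction step on
  tr_ext <- fake_trajectory(c(0.5, 0.5, 0.5))
  tr_ext$wild[3, ] <- 0L
  tr_ext$mutant[3, ] <- 0L
  mix <- ensemble_average(list(tr_ext, fake_trajectory(c(0.1, 0.1, 0.1))))
  expect_equal(mix$n_alive, c(2L, 2L, 1L))
  expect_equal(mix$mean_fraction[3], 0.1)
  expect_equal(attr(mix, "extinct"), 1L)
})

test_that("neutral ensembles drift around the founder share (martingale property)", {
  g <- single_node_graph(50L)
  p <- neutral_params(antibiotic = 0.3, founders = 20L, founder_mutants = 10L,
                      n_steps = 30)
  ens <- run_ensemble(g, p, n_reps = 100, base_seed = 2500)
  summ <- ensemble_average(ens)
  mid <- c(11, 21, 31)  # steps 10, 20, 30
  for (i in mid) {
    expect_lt(abs(summ$mean_fraction[i] - 0.5), 3 * summ$se[i])
  }
})

test_that("expected migrants follow m*K*(1 - A/rho) with threshold at rho", {
  expect_equal(expected_migrants(0, 1600, 0.2, 1), 0)
  expect_equal(expected_migrants(0.01, 1600, 1, 1), 0)
  expect_equal(expected_migrants(1 / 1280, 1600, 0.2, 1), 1)
  # linear in m and K, non-increasing in A
  expect_equal(expected_migrants(0.02, 1600, 0.2, 1),
               2 * expected_migrants(0.01, 1600, 0.2, 1))
  expect_equal(expected_migrants(0.01, 3200, 0.2, 1),
               2 * expected_migrants(0.01, 1600, 0.2, 1))
  a_grid <- seq(0, 1.5, by = 0.25)
  em <- expected_migrants(0.01, 1600, a_grid, 1)
  expect_true(all(diff(em) <= 0))
  expect_error(expected_migrants(0.01, 1600, 0.2, 0),
               class = "metamp_invalid_parameter")
  # inverse mapping used by the presets
  m <- migration_for_em(1, capacity = 1600, antibiotic = 0.25)
  expect_equal(expected_migrants(m, 1600, 0.25, 1), 1)
})

test_that("dilution head-counts convert migration percentages to individuals", {
  expect_equal(migrants_from_dilution(0.001, 1e7), 100)
  expect_equal(migrants_from_dilution(1, 1e7), 1e5)
  expect_equal(migrants_from_dilution(0, 1e7), 0)
  expect_error(migrants_from_dilution(-1), class = "metamp_invalid_parameter")
})

test_that("amplification curves difference two summaries on a shared grid", {
  a <- ensemble_average(list(fake_trajectory(c(0.1, 0.2, 0.3)),
                             fake_trajectory(c(0.2, 0.3, 0.4))))
  expect_true(all(abs(amplification_curve(a, a)$diff) < 1e-12))
  b <- ensemble_average(list(fake_trajectory(c(0.1, 0.2, 0.3) + 0.1),
                             fake_trajectory(c(0.2, 0.3, 0.4) + 0.1)))
  expect_true(all(abs(amplification_curve(b, a)$diff - 0.1) < 1e-12))
  short <- ensemble_average(list(fake_trajectory(c(0.1, 0.2))))
  expect_error(amplification_curve(a, short), class = "metamp_invalid_input")
})

test_that("spread order ranks nodes by first crossing with ties on id", {
  fr <- cbind(P1 = c(0, 0, 0, 0.2, 0.6),
              P2 = c(0, 0.2, 0.6, 0.9, 1),
              P3 = c(0.6, 0.9, 1, 1, 1),
              P4 = c(0, 0, 0, 0, 0.2))
  tr <- fake_multinode_trajectory(fr)
  so <- per_node_spread_order(tr, 0.5)
  expect_equal(so$node_id, c("P3", "P2", "P1", "P4"))
  expect_equal(so$cross_step, c(0L, 2L, 4L, NA_integer_))
  expect_equal(so$reached, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(per_node_spread_order(tr, 0), class = "metamp_invalid_parameter")

  # no migration: only the introduction node is ever taken over
  g <- build_star(3, 60)
  p <- sim_params(migration_prob = 0, n_steps = 60, founders = 40L,
                  founder_mutants = 4L, intro_node = "P3", seed = 31,
                  wild = type_params(1, 1.4))
  so2 <- per_node_spread_order(sim_run(g, p), 0.5)
  reached <- so2$node_id[so2$reached]
  expect_true(all(reached %in% "P3"))
})
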