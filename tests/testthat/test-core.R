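test_that("day/step conversion follows the doubling-time formula", {
  expect_identical(steps_for_days(5, 30), 240L)
  expect_identical(steps_for_days(1, 30), 48L)
  expect_identical(steps_for_days(5, 60), 120L)
  expect_error(steps_for_days(0, 30), class = "metamp_invalid_parameter")
  expect_error(steps_for_days(5, 0), class = "metamp_invalid_parameter")
})

test_that("effective carrying capacity matches (1 - Z*A/R)*K with a floor at 0", {
  expect_equal(effective_carrying_capacity(0, 5, 1, 1600), 1600)
  expect_equal(effective_carrying_capacity(1, 0, 1, 1600), 1600)
  expect_equal(effective_carrying_capacity(1, 1, 1, 1600), 0)
  expect_equal(effective_carrying_capacity(2, 1, 1, 1600), 0)  # past threshold
  expect_equal(effective_carrying_capacity(1, 0.25, 1, 1600), 1200)
  expect_error(effective_carrying_capacity(1, 0.25, 0, 1600),
               class = "metamp_invalid_parameter")
})

test_that("wild-type calibration places the invasion advantage at the resident equilibrium", {
  w <- calibrate_wild_kill(0.1, type_params(1, 1), 0.25)
  expect_equal(w$kill_rate, 1.4)
  # invasion growth factor of the mutant at the wild equilibrium:
  # empty fraction = Zw*A/R, so g = 1 - Zm*A + R*(Zw*A/R) = 1 + advantage
  g <- 1 - 1 * 0.25 + 1 * (w$kill_rate * 0.25 / 1)
  expect_equal(g, 1.1)
  expect_error(calibrate_wild_kill(10, type_params(1, 1), 0.25),
               class = "metamp_invalid_parameter")
  expect_error(calibrate_wild_kill(0.1, type_params(1, 1), 0),
               class = "metamp_invalid_parameter")
})

test_that("seeding places founders uniformly and mutants in the non-hub intro node", {
  g <- build_star(3, 1600)
  p <- sim_params(founders = 1000L, founder_mutants = 1L, intro_node = "P3")
  set.seed(1)
  st <- seed_state(g, p)
  expect_equal(sum(st$wild) + sum(st$mutant), 1000)
  expect_equal(sum(st$mutant), 1)
  expect_equal(unname(st$mutant["P3"]), 1)
  expect_equal(unname(st$mutant["P2"]), 0)

  # founders spread over all nodes (multivariate hypergeometric, n large)
  expect_true(all(st$wild > 0))

  # saturation fills every space
  p_full <- sim_params(founders = 6400L, founder_mutants = 0L)
  st_full <- seed_state(g, p_full)
  expect_true(all(st_full$wild + st_full$mutant == st_full$capacity))

  # empty founding
  p0 <- sim_params(founders = 0L, founder_mutants = 0L)
  st0 <- seed_state(g, p0)
  expect_equal(sum(st0$wild) + sum(st0$mutant), 0)

  expect_error(seed_state(g, sim_params(founders = 6401L)),
               class = "metamp_invalid_parameter")
  expect_error(seed_state(g, sim_params(intro_node = "P2")),
               class = "metamp_invalid_parameter")
})

test_that("death phase is binomial thinning with certain death past the threshold", {
  g <- single_node_graph(20000L)
  st <- make_state(g, wild = 10000L, mutant = 5000L)

  # no antibiotic: identity
  p0 <- neutral_params(antibiotic = 0)
  set.seed(1)
  expect_equal(death_phase(st, p0)$wild, st$wild)
  expect_equal(death_phase(st, p0)$mutant, st$mutant)

  # Z*A >= 1 kills everything of that type
  p_kill <- sim_params(antibiotic = 1, mutant = type_params(1, 0.2),
                       wild = type_params(1, 1.5))
  set.seed(1)
  stk <- death_phase(st, p_kill)
  expect_equal(sum(stk$wild), 0)
  expect_true(sum(stk$mutant) > 0)

  # binomial mean: survivors of 10000 at p_death 0.3 ~ 7000
  p3 <- sim_params(antibiotic = 0.3, mutant = type_params(1, 1),
                   wild = type_params(1, 1))
  set.seed(42)
  survivors <- replicate(200, sum(death_phase(st, p3)$wild))
  se <- sqrt(10000 * 0.7 * 0.3 / 200)
  expect_lt(abs(mean(survivors) - 7000), 3 * se)
})

test_that("birth phase respects crowding, zero rates, and the capacity trim", {
  g <- single_node_graph(100L)
  p <- neutral_params(antibiotic = 0)

  # full node: no births
  st_full <- make_state(g, wild = 60L, mutant = 40L)
  set.seed(1)
  expect_equal(birth_phase(st_full, p)$wild, st_full$wild)

  # zero birth rate: no births of that type
  p0 <- sim_params(antibiotic = 0, mutant = type_params(0, 1),
                   wild = type_params(1, 1))
  st <- make_state(g, wild = 30L, mutant = 30L)
  set.seed(1)
  stb <- birth_phase(st, p0)
  expect_equal(unname(stb$mutant["P1"]), 30L)
  expect_gte(unname(stb$wild["P1"]), 30L)

  # overflow: proposals forced above free space still respect capacity
  # (parents from a crowded start, tiny free space)
  st_tight <- make_state(g, wild = 49L, mutant = 49L)
  for (seed in 1:20) {
    set.seed(seed)
    out <- birth_phase(st_tight, p)
    expect_lte(out$wild + out$mutant, 100L)
    expect_gte(out$wild, st_tight$wild)
    expect_gte(out$mutant, st_tight$mutant)
  }
})

test_that("migration conserves agents, aborts into full nodes, and follows edge weights", {
  # m = 0: identity
  g <- two_node_graph(5L)
  st <- make_state(g, wild = c(3L, 1L), mutant = c(1L, 0L))
  p0 <- neutral_params(migration_prob = 0)
  expect_equal(migration_phase(st, g, p0)$wild, st$wild)

  # m = 1 with room: forced move A -> B
  gAB <- metapop_graph(
    nodes = data.frame(id = c("A", "B"), capacity = 10L, role = "plain"),
    edges = data.frame(src = "A", dst = "B", weight = 1))
  stAB <- make_state(gAB, wild = c(4L, 0L), mutant = c(2L, 0L))
  p1 <- neutral_params(migration_prob = 1)
  set.seed(3)
  moved <- migration_phase(stAB, gAB, p1)
  expect_equal(unname(moved$wild["B"]), 4L)
  expect_equal(unname(moved$mutant["B"]), 2L)

  # destination full: everyone stays
  stFull <- make_state(gAB, wild = c(4L, 10L), mutant = c(2L, 0L))
  set.seed(3)
  stayed <- migration_phase(stFull, gAB, p1)
  expect_equal(stayed$wild, stFull$wild)

  # conservation under random states on a star, many seeds
  gs <- build_star(3, 8)
  pm <- neutral_params(migration_prob = 0.5)
  for (seed in 1:25) {
    set.seed(seed)
    wild <- as.integer(sample(0:4, 4, replace = TRUE))
    mutant <- as.integer(sample(0:3, 4, replace = TRUE))
    st0 <- make_state(gs, wild, mutant)
    st1 <- migration_phase(st0, gs, pm)
    expect_equal(sum(st1$wild), sum(wild))
    expect_equal(sum(st1$mutant), sum(mutant))
    expect_true(all(st1$wild + st1$mutant <= st1$capacity))
  }

  # hub destinations empirically uniform over the three leaves
  set.seed(99)
  gs_big <- build_star(3, 40000)
  st_hub <- make_state(gs_big, wild = c(0L, 30000L, 0L, 0L), mutant = 0L)
  p_all <- neutral_params(migration_prob = 1)
  out <- migration_phase(st_hub, gs_big, p_all)
  counts <- out$wild[c("P1", "P3", "P4")]
  se <- sqrt(30000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 10000) < 3 * se))
})

test_that("bottleneck thins binomially and validates its fraction", {
  g <- single_node_graph(5000L)
  st <- make_state(g, wild = 2000L, mutant = 2000L)
  expect_equal(bottleneck(st, 1)$wild, st$wild)
  expect_error(bottleneck(st, 0), class = "metamp_invalid_parameter")
  expect_error(bottleneck(st, 1.2), class = "metamp_invalid_parameter")
  set.seed(7)
  thinned <- replicate(200, sum(bottleneck(st, 0.5)$mutant))
  se <- sqrt(2000 * 0.25 / 200)
  expect_lt(abs(mean(thinned) - 1000), 3 * se)
})

test_that("a full step is inert when all phases are inert and preserves invariants", {
  g <- build_star(3, 10)
  p_inert <- sim_params(antibiotic = 0, migration_prob = 0,
                        mutant = type_params(0, 1), wild = type_params(0, 1))
  st <- make_state(g, wild = c(2L, 3L, 1L, 0L), mutant = c(1L, 0L, 2L, 0L))
  set.seed(1)
  out <- sim_step(st, g, p_inert)
  expect_equal(out$wild, st$wild)
  expect_equal(out$mutant, st$mutant)
  expect_equal(out$step, st$step + 1L)

  # empty state is absorbing
  st_empty <- make_state(g, wild = 0L, mutant = 0L)
  out_e <- sim_step(st_empty, g, neutral_params(migration_prob = 0.3))
  expect_equal(sum(out_e$wild) + sum(out_e$mutant), 0)

  # invariants hold across random steps
  p <- selective_params(migration_prob = 0.3)
  for (seed in 1:20) {
    set.seed(seed)
    sti <- make_state(g, as.integer(sample(0:5, 4, TRUE)),
                      as.integer(sample(0:5, 4, TRUE)))
    for (k in 1:5) {
      sti <- sim_step(sti, g, p)
      expect_true(all(sti$wild >= 0) && all(sti$mutant >= 0))
      expect_true(all(sti$wild + sti$mutant <= sti$capacity))
    }
  }
})

test_that("runs are reproducible bit-for-bit and record the full trajectory", {
  g <- build_star(3, 100)
  p <- sim_params(migration_prob = 0.01, n_steps = 30, founders = 100L,
                  seed = 123)
  tr1 <- sim_run(g, p)
  tr2 <- sim_run(g, p)
  expect_identical(tr1$wild, tr2$wild)
  expect_identical(tr1$mutant, tr2$mutant)
  expect_equal(nrow(tr1$wild), 31)
  expect_equal(tr1$step, 0:30)

  # n_steps = 0: the seed state only
  p0 <- sim_params(n_steps = 0, founders = 100L, seed = 5)
  tr0 <- sim_run(g, p0)
  expect_equal(nrow(tr0$wild), 1)

  # tidy export has deterministic (replicate, step, node) order
  df <- as.data.frame(tr1, replicate = 2L)
  expect_equal(names(df), c("replicate", "step", "node_id", "wild", "mutant"))
  expect_equal(nrow(df), 31 * 4)
  expect_equal(df$step[1:8], rep(0:1, each = 4))

  # ensemble replicate i reproduces a single run at base_seed + i - 1
  ens <- run_ensemble(g, p, n_reps = 3, base_seed = 123)
  expect_identical(ens[[1]]$wild, tr1$wild)
})

test_that("single-type occupancy tracks the effective carrying capacity and falls with antibiotic", {
  g <- single_node_graph(400L)
  occupancy <- function(A) {
    p <- sim_params(antibiotic = A, migration_prob = 0, n_steps = 150,
                    mutant = type_params(1, 1), wild = type_params(1, 1),
                    founders = 200L, founder_mutants = 200L,
                    intro_node = "P1")
    occ <- vapply(1:30, function(i) {
      p$seed <- 700 + i
      tr <- sim_run(g, p)
      sum(tr$mutant[151, ])
    }, numeric(1))
    occ
  }
  occ25 <- occupancy(0.25)
  target <- effective_carrying_capacity(1, 0.25, 1, 400)
  expect_lt(abs(mean(occ25) - target), 3 * sd(occ25) / sqrt(30))
  occ50 <- occupancy(0.5)
  expect_lt(mean(occ50), mean(occ25))
})
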