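#' Simulation state
#'
#' Per-node counts of wild-type and mutant agents; remaining spaces are
#' empty.  Counts are integers and `wild + mutant <= capacity` in every
#' node at all times.
#'
#' @param graph a [metapop_graph()].
#' @param wild,mutant integer vectors of per-node counts, in the
#'   graph's node order (recycled scalars allowed).
#' @param step step index (0 = founding state).
#' @return an object of class `sim_state` with named elements `wild`,
#'   `mutant`, `capacity`, `step`.
#' @export
make_state <- function(graph, wild, mutant, step = 0L) {
  ids <- graph$nodes$id
  caps <- stats::setNames(as.integer(graph$nodes$capacity), ids)
  wild <- stats::setNames(as.integer(rep_len(wild, length(ids))), ids)
  mutant <- stats::setNames(as.integer(rep_len(mutant, length(ids))), ids)
  if (any(wild < 0) || any(mutant < 0) || any(wild + mutant > caps)) {
    metamp_abort("counts must be >= 0 and wild + mutant <= capacity in every node",
                 "metamp_invalid_parameter")
  }
  new_sim_state(wild, mutant, caps, step)
}

new_sim_state <- function(wild, mutant, capacity, step = 0L) {
  structure(list(wild = wild, mutant = mutant, capacity = capacity,
                 step = as.integer(step)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> step %d | wild %d, mutant %d / capacity %d\n",
              x$step, sum(x$wild), sum(x$mutant), sum(x$capacity)))
  print(data.frame(node = names(x$wild), wild = as.integer(x$wild),
                   mutant = as.integer(x$mutant),
                   capacity = as.integer(x$capacity), row.names = NULL))
  invisible(x)
}

# Default introduction node: "P3" when present and not the hub,
# otherwise the first non-hub node.
default_intro_node <- function(graph) {
  non_hub <- graph$nodes$id[graph$nodes$role != "hub"]
  if (length(non_hub) == 0) return(NA_character_)
  if ("P3" %in% non_hub) "P3" else non_hub[1]
}

#' Seed the founding state
#'
#' Places `founder_mutants` resistant mutants in the introduction node
#' (a designated non-hub patch, by default `"P3"`) and the remaining
#' `founders - founder_mutants` wild-type agents uniformly at random
#' over all remaining empty spaces of the metapopulation (multivariate
#' hypergeometric across nodes).  With the default 1000 founders and 1
#' mutant this reproduces the ~1:1000 resistant:wild founding ratio.
#'
#' Uses the current RNG state; [sim_run()] seeds the RNG beforehand.
#'
#' @param graph a [metapop_graph()].
#' @param params a [sim_params()].
#' @return a `sim_state` at step 0.
#' @export
seed_state <- function(graph, params) {
  ids <- graph$nodes$id
  caps <- stats::setNames(as.integer(graph$nodes$capacity), ids)
  founders <- params$founders
  fm <- params$founder_mutants
  if (founders > sum(caps)) {
    metamp_abort(sprintf("founders (%d) exceed total capacity (%d)",
                         founders, sum(caps)),
                 "metamp_invalid_parameter")
  }
  mutant <- stats::setNames(integer(length(ids)), ids)
  if (fm > 0) {
    intro <- params$intro_node %||% default_intro_node(graph)
    if (is.na(intro) || !intro %in% ids) {
      metamp_abort("no valid non-hub introduction node available",
                   "metamp_invalid_parameter")
    }
    if (graph$nodes$role[match(intro, ids)] == "hub") {
      metamp_abort("the mutant must be introduced in a non-hub node",
                   "metamp_invalid_parameter")
    }
    if (fm > caps[intro]) {
      metamp_abort("founder_mutants exceed the introduction node's capacity",
                   "metamp_invalid_parameter")
    }
    mutant[intro] <- fm
  }
  wild <- stats::setNames(integer(length(ids)), ids)
  n_wild <- founders - fm
  if (n_wild > 0) {
    avail <- caps - mutant
    pool <- rep(seq_along(ids), avail)
    picked <- if (length(pool) == 1) pool else sample(pool, n_wild)
    wild <- stats::setNames(tabulate(picked, nbins = length(ids)), ids)
  }
  new_sim_state(wild, mutant, caps, 0L)
}

#' Death phase
#'
#' Each agent of type `tau` is removed with probability `min(1,
#' kill_rate_tau * antibiotic)`; survivors are binomial per node and
#' type.  Counts never increase.
#'
#' @param state a `sim_state`.
#' @param params a [sim_params()].
#' @return the post-death `sim_state` (step index unchanged; phases are
#'   composed by [sim_step()]).
#' @export
death_phase <- function(state, params) {
  p_w <- min(1, params$wild$kill_rate * params$antibiotic)
  p_m <- min(1, params$mutant$kill_rate * params$antibiotic)
  n <- length(state$wild)
  wild <- state$wild
  mutant <- state$mutant
  if (p_w > 0) wild[] <- stats::rbinom(n, state$wild, 1 - p_w)
  if (p_m > 0) mutant[] <- stats::rbinom(n, state$mutant, 1 - p_m)
  new_sim_state(wild, mutant, state$capacity, state$step)
}

#' Birth phase
#'
#' Each parent of type `tau` produces one offspring with probability
#' `birth_rate_tau * empty / capacity` (offspring binomial per node and
#' type).  If the proposed offspring exceed the free spaces, exactly
#' `empty` offspring are retained by sampling without replacement from
#' the proposal pool (hypergeometric allocation between types), which is
#' unbiased between types.  Within a full generation ([sim_step()]) the
#' parent counts and the empty-space fraction are those of the
#' generation start, so that death and birth balance at the effective
#' carrying capacity `(1 - Z*A/R)*K`; called stand-alone, the state's
#' own counts are used.
#'
#' @param state a `sim_state` (post-death when called from
#'   [sim_step()]).
#' @param params a [sim_params()].
#' @param parents optional list with `wild` and `mutant` parent counts
#'   (defaults to the state's counts).
#' @param empty optional per-node empty-space counts used in the birth
#'   probability (defaults to the state's empty spaces).
#' @return the post-birth `sim_state`.
#' @export
birth_phase <- function(state, params, parents = NULL, empty = NULL) {
  K <- state$capacity
  n <- length(K)
  par_w <- parents$wild %||% state$wild
  par_m <- parents$mutant %||% state$mutant
  e0 <- empty %||% (K - state$wild - state$mutant)
  pb_w <- pmin(1, pmax(0, params$wild$birth_rate * e0 / K))
  pb_m <- pmin(1, pmax(0, params$mutant$birth_rate * e0 / K))
  b_w <- stats::rbinom(n, par_w, pb_w)
  b_m <- stats::rbinom(n, par_m, pb_m)
  avail <- K - state$wild - state$mutant
  over <- which(b_w + b_m > avail)
  for (i in over) {
    keep_w <- stats::rhyper(1, b_w[i], b_m[i], avail[i])
    b_w[i] <- keep_w
    b_m[i] <- avail[i] - keep_w
  }
  new_sim_state(state$wild + b_w, state$mutant + b_m, K, state$step)
}

#' Migration phase
#'
#' Each agent independently attempts to migrate with probability `m`;
#' the destination is drawn from the [outgoing_distribution()] of its
#' node.  Moves are resolved one at a time in a uniformly random global
#' order; a move into a node with no empty space at that moment is
#' aborted (the agent stays).  Agents in nodes with no outgoing edges
#' never move.  Total agent count is conserved exactly.
#'
#' @param state a `sim_state`.
#' @param graph the [metapop_graph()] the state lives on.
#' @param params a [sim_params()] (only `migration_prob` is used).
#' @return the post-migration `sim_state`.
#' @export
migration_phase <- function(state, graph, params) {
  .migrate(state, .graph_runtime(graph), params$migration_prob)
}

.migrate <- function(state, rt, m) {
  if (m <= 0 || length(rt$has_out) == 0) return(state)
  wild <- state$wild
  mutant <- state$mutant
  caps <- state$capacity
  src <- integer(0); typ <- integer(0); dst <- integer(0)
  for (i in rt$has_out) {
    k_w <- stats::rbinom(1, wild[i], m)
    k_m <- stats::rbinom(1, mutant[i], m)
    if (k_w + k_m == 0) next
    o <- rt$out[[i]]
    nd <- length(o$dst)
    if (k_w > 0) {
      d <- if (nd == 1) rep.int(o$dst, k_w) else
        o$dst[sample.int(nd, k_w, replace = TRUE, prob = o$prob)]
      src <- c(src, rep.int(i, k_w)); typ <- c(typ, rep.int(1L, k_w)); dst <- c(dst, d)
    }
    if (k_m > 0) {
      d <- if (nd == 1) rep.int(o$dst, k_m) else
        o$dst[sample.int(nd, k_m, replace = TRUE, prob = o$prob)]
      src <- c(src, rep.int(i, k_m)); typ <- c(typ, rep.int(2L, k_m)); dst <- c(dst, d)
    }
  }
  n_mv <- length(src)
  if (n_mv == 0) return(state)
  ord <- if (n_mv == 1) 1L else sample.int(n_mv)
  occ <- wild + mutant
  for (j in ord) {
    dd <- dst[j]
    if (occ[dd] < caps[dd]) {
      ss <- src[j]
      if (typ[j] == 1L) {
        wild[ss] <- wild[ss] - 1L; wild[dd] <- wild[dd] + 1L
      } else {
        mutant[ss] <- mutant[ss] - 1L; mutant[dd] <- mutant[dd] + 1L
      }
      occ[ss] <- occ[ss] - 1L; occ[dd] <- occ[dd] + 1L
    }
  }
  new_sim_state(wild, mutant, caps, state$step)
}

#' Bottleneck (serial-transfer dilution)
#'
#' Random thinning of every node: each agent survives independently
#' with probability `fraction` (binomial per node and type).  Mimics
#' the dilution bottleneck of daily serial transfer; smaller fractions
#' impose stronger drift.
#'
#' @param state a `sim_state`.
#' @param fraction survival probability in (0, 1\].
#' @return the thinned `sim_state`.
#' @export
bottleneck <- function(state, fraction) {
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 || fraction > 1) {
    metamp_abort("bottleneck fraction must be in (0, 1]",
                 "metamp_invalid_parameter")
  }
  if (fraction == 1) return(state)
  n <- length(state$wild)
  wild <- state$wild; mutant <- state$mutant
  wild[] <- stats::rbinom(n, state$wild, fraction)
  mutant[] <- stats::rbinom(n, state$mutant, fraction)
  new_sim_state(wild, mutant, state$capacity, state$step)
}

#' Advance the simulation by one generation
#'
#' Composition of the three phases — death, birth, migration — followed
#' by the bottleneck on scheduled steps.  Death and birth propensities
#' are both evaluated on the generation-start state (synchronous
#' update), which makes the single-patch equilibrium occupancy equal to
#' [effective_carrying_capacity()]; migration then acts on the
#' post-birth state.
#'
#' @param state a `sim_state`.
#' @param graph the [metapop_graph()].
#' @param params a [sim_params()].
#' @return the `sim_state` one step later (step index incremented).
#' @export
sim_step <- function(state, graph, params) {
  .sim_step(state, .graph_runtime(graph), params)
}

.sim_step <- function(state, rt, params) {
  par0 <- list(wild = state$wild, mutant = state$mutant)
  e0 <- state$capacity - state$wild - state$mutant
  st <- death_phase(state, params)
  st <- birth_phase(st, params, parents = par0, empty = e0)
  st <- .migrate(st, rt, params$migration_prob)
  new_step <- state$step + 1L
  if (!is.null(params$bottleneck_every) &&
      new_step %% params$bottleneck_every == 0) {
    st <- bottleneck(st, params$bottleneck_fraction)
  }
  st$step <- new_step
  st
}

#' Run a single simulation replicate
#'
#' Seeds the RNG from `params$seed` (if given), founds the population
#' with [seed_state()], and advances `n_steps` generations, recording
#' per-step per-node counts of both types.  Bit-for-bit reproducible
#' given the same graph, parameters, and seed.
#'
#' @param graph a [metapop_graph()].
#' @param params a [sim_params()].
#' @return an object of class `sim_trajectory`: list with `step`
#'   (0..n_steps), integer matrices `wild` and `mutant` (step by node),
#'   `node_ids`, `capacity`, `params`, `seed`.  Convert to a tidy data
#'   frame with [as.data.frame()].
#' @examples
#' g <- build_star(3, 100)
#' p <- sim_params(migration_prob = 0.01, n_steps = 20, founders = 60,
#'                 seed = 1)
#' tr <- sim_run(g, p)
#' @export
sim_run <- function(graph, params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  rt <- .graph_runtime(graph)
  st <- seed_state(graph, params)
  n_steps <- params$n_steps
  ids <- rt$ids
  W <- matrix(0L, n_steps + 1, length(ids), dimnames = list(NULL, ids))
  M <- W
  W[1, ] <- st$wild
  M[1, ] <- st$mutant
  if (n_steps > 0) {
    for (t in seq_len(n_steps)) {
      st <- .sim_step(st, rt, params)
      W[t + 1, ] <- st$wild
      M[t + 1, ] <- st$mutant
    }
  }
  structure(list(step = 0:n_steps, wild = W, mutant = M,
                 node_ids = ids, capacity = rt$caps,
                 params = params, seed = params$seed),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  tot <- sum(x$wild[nrow(x$wild), ]) + sum(x$mutant[nrow(x$mutant), ])
  frac <- if (tot > 0) sum(x$mutant[nrow(x$mutant), ]) / tot else NA_real_
  cat(sprintf("<sim_trajectory> %d nodes, %d steps, final mutant fraction %s\n",
              length(x$node_ids), max(x$step),
              ifelse(is.na(frac), "NA (extinct)", sprintf("%.4f", frac))))
  invisible(x)
}

#' Tidy a trajectory (or ensemble) into a data frame
#'
#' One row per (replicate,) step and node, columns `step`, `node_id`,
#' `wild`, `mutant` (plus `replicate` for ensembles); deterministic row
#' order (replicate, step, node).
#'
#' @param x a `sim_trajectory`.
#' @param row.names,optional ignored (base-generic signature).
#' @param replicate replicate index recorded in the output.
#' @param ... ignored.
#' @return a data frame.
#' @export
as.data.frame.sim_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                         replicate = 1L, ...) {
  n_node <- length(x$node_ids)
  n_step <- length(x$step)
  data.frame(
    replicate = as.integer(replicate),
    step = rep(x$step, each = n_node),
    node_id = rep(x$node_ids, times = n_step),
    wild = as.integer(t(x$wild)),
    mutant = as.integer(t(x$mutant)),
    stringsAsFactors = FALSE
  )
}

#' Run an ensemble of replicates
#'
#' Replicate `i` uses seed `base_seed + i - 1`, so replicate 1 equals a
#' single [sim_run()] at `base_seed` and the whole ensemble is
#' reproducible from one base seed.
#'
#' @param graph a [metapop_graph()].
#' @param params a [sim_params()].
#' @param n_reps number of replicates (>= 1).
#' @param base_seed base RNG seed; defaults to `params$seed` (or 1).
#' @return an object of class `sim_ensemble`: a list of
#'   `sim_trajectory` objects with attribute `base_seed`.
#' @export
run_ensemble <- function(graph, params, n_reps = 100L,
                         base_seed = params$seed %||% 1L) {
  if (length(n_reps) != 1 || is.na(n_reps) || n_reps < 1) {
    metamp_abort("n_reps must be >= 1", "metamp_invalid_parameter")
  }
  trajs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    params$seed <- as.integer(base_seed + i - 1)
    trajs[[i]] <- sim_run(graph, params)
  }
  structure(trajs, class = "sim_ensemble", base_seed = as.integer(base_seed))
}

#' @export
as.data.frame.sim_ensemble <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x), function(i) {
    as.data.frame(x[[i]], replicate = i)
  }))
}

#' Simulate runs to absorption and record fixation outcomes
#'
#' Runs replicates until one type is lost (mutant fixation: no wild
#' type left and at least one mutant; wild fixation: the reverse;
#' extinction: empty metapopulation) or `max_steps` is hit.  This is
#' the empirical counterpart of the exact absorption probabilities from
#' [fixation_table()].
#'
#' @param graph a [metapop_graph()].
#' @param params a [sim_params()] (its `n_steps` is ignored).
#' @param n_runs number of independent runs.
#' @param base_seed seed for run `i` is `base_seed + i - 1`.
#' @param max_steps safety cap on steps per run; runs still mixed at
#'   the cap get outcome `"none"`.
#' @param init optional list with per-node `wild` and `mutant` counts
#'   for the starting state; defaults to [seed_state()].
#' @return data frame with columns `replicate`, `outcome` (factor:
#'   mutant/wild/extinct/none), `steps`.
#' @export
simulate_fixation <- function(graph, params, n_runs = 1000L, base_seed = 1L,
                              max_steps = 10000L, init = NULL) {
  rt <- .graph_runtime(graph)
  outcomes <- character(n_runs)
  steps <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(as.integer(base_seed + r - 1))
    st <- if (is.null(init)) seed_state(graph, params)
          else make_state(graph, init$wild, init$mutant)
    t <- 0L
    repeat {
      wt <- sum(st$wild); mt <- sum(st$mutant)
      if (wt == 0L || mt == 0L || t >= max_steps) break
      st <- .sim_step(st, rt, params)
      t <- t + 1L
    }
    outcomes[r] <- if (wt == 0L && mt == 0L) "extinct"
      else if (wt == 0L) "mutant"
      else if (mt == 0L) "wild"
      else "none"
    steps[r] <- t
  }
  data.frame(replicate = seq_len(n_runs),
             outcome = factor(outcomes, levels = c("mutant", "wild", "extinct", "none")),
             steps = steps)
}
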