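#' Enumerate the full state space of a tiny metapopulation
#'
#' A state assigns each node a pair (wild, mutant) with `wild + mutant
#' <= capacity`; a node with capacity K has `(K+1)(K+2)/2` local
#' states, and the global space is their product.  Enumeration is only
#' feasible for tiny instances and is guarded by `limit`.
#'
#' @param graph a [metapop_graph()].
#' @param limit maximum admissible number of global states.
#' @return an object of class `state_space`: matrices `W` and `U`
#'   (state by node, wild and mutant counts), per-node sizes, mixed-radix
#'   bases, and local-id lookup tables.
#' @examples
#' sp <- enumerate_states(build_well_mixed(2, 2))
#' nrow(sp$W)  # 36
#' @export
enumerate_states <- function(graph, limit = 2e5) {
  caps <- as.integer(graph$nodes$capacity)
  ids <- graph$nodes$id
  sizes <- (caps + 1) * (caps + 2) / 2
  total <- prod(sizes)
  if (total > limit) {
    metamp_abort(sprintf(
      "state space has %g states, above the limit of %g", total, limit),
      "metamp_too_large")
  }
  total <- as.integer(total)
  local <- lapply(caps, function(K) {
    w <- unlist(lapply(0:K, function(x) rep.int(x, K - x + 1)))
    u <- unlist(lapply(0:K, function(x) 0:(K - x)))
    cbind(w = w, u = u)
  })
  lid <- lapply(seq_along(caps), function(i) {
    K <- caps[i]
    M <- matrix(NA_integer_, K + 1, K + 1)
    M[local[[i]] + 1L] <- seq_len(sizes[i])
    M
  })
  bases <- cumprod(c(1, sizes[-length(sizes)]))
  W <- matrix(0L, total, length(caps), dimnames = list(NULL, ids))
  U <- W
  for (i in seq_along(caps)) {
    lidx <- rep(rep(seq_len(sizes[i]), each = bases[i]), length.out = total)
    W[, i] <- local[[i]][lidx, "w"]
    U[, i] <- local[[i]][lidx, "u"]
  }
  structure(list(W = W, U = U, sizes = sizes, bases = bases, lid = lid,
                 local = local, caps = stats::setNames(caps, ids),
                 node_ids = ids),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d nodes, %d states\n",
              length(x$caps), nrow(x$W)))
  invisible(x)
}

#' Index of a state within a state space
#'
#' @param space a [enumerate_states()] object.
#' @param wild,mutant per-node counts.
#' @return the 1-based row index into `space$W` / `space$U`.
#' @export
state_index <- function(space, wild, mutant) {
  caps <- unname(space$caps)
  if (any(wild < 0) || any(mutant < 0) || any(wild > caps) ||
      any(mutant > caps) || any(wild + mutant > caps)) {
    metamp_abort("counts violate a node capacity", "metamp_invalid_parameter")
  }
  lids <- vapply(seq_along(space$caps), function(i) {
    space$lid[[i]][wild[i] + 1L, mutant[i] + 1L]
  }, integer(1))
  if (any(is.na(lids))) {
    metamp_abort("counts violate a node capacity", "metamp_invalid_parameter")
  }
  as.integer(1 + sum((lids - 1) * space$bases))
}

# ---- per-node exact phase distributions -------------------------------

# Death: independent binomial survival per type.
.node_death_matrix <- function(K, local, lid, p_w, p_m) {
  S <- nrow(local)
  P <- matrix(0, S, S)
  for (s in seq_len(S)) {
    w <- local[s, "w"]; u <- local[s, "u"]
    pw <- stats::dbinom(0:w, w, 1 - p_w)
    pu <- stats::dbinom(0:u, u, 1 - p_m)
    for (wi in 0:w) for (ui in 0:u) {
      P[s, lid[wi + 1L, ui + 1L]] <- P[s, lid[wi + 1L, ui + 1L]] + pw[wi + 1] * pu[ui + 1]
    }
  }
  P
}

# Offspring proposal + hypergeometric trim, shared by the stand-alone
# birth kernel and the joint growth kernel.  Accumulates the
# distribution over retained (birth_w, birth_m) given proposal
# distributions and available spaces.
.birth_allocation <- function(nw, nu, pb_w, pb_m, avail) {
  # returns matrix of (b_w, b_m, prob)
  acc <- list()
  pw <- stats::dbinom(0:nw, nw, pb_w)
  pu <- stats::dbinom(0:nu, nu, pb_m)
  for (bw in 0:nw) for (bu in 0:nu) {
    p <- pw[bw + 1] * pu[bu + 1]
    if (p == 0) next
    if (bw + bu <= avail) {
      acc[[length(acc) + 1]] <- c(bw, bu, p)
    } else {
      # retain exactly `avail` offspring without replacement
      for (kw in max(0, avail - bu):min(bw, avail)) {
        ph <- stats::dhyper(kw, bw, bu, avail)
        if (ph > 0) acc[[length(acc) + 1]] <- c(kw, avail - kw, p * ph)
      }
    }
  }
  do.call(rbind, acc)
}

# Stand-alone birth: parents and empty spaces from the current state.
.node_birth_matrix <- function(K, local, lid, R_w, R_m) {
  S <- nrow(local)
  P <- matrix(0, S, S)
  for (s in seq_len(S)) {
    w <- local[s, "w"]; u <- local[s, "u"]
    e <- K - w - u
    alloc <- .birth_allocation(w, u, min(1, max(0, R_w * e / K)),
                               min(1, max(0, R_m * e / K)), e)
    for (r in seq_len(nrow(alloc))) {
      tgt <- lid[w + alloc[r, 1] + 1L, u + alloc[r, 2] + 1L]
      P[s, tgt] <- P[s, tgt] + alloc[r, 3]
    }
  }
  P
}

# Joint death + birth of one generation: both propensities evaluated on
# the generation-start counts (synchronous update), deaths and birth
# proposals independent, then the trim against post-death free space.
.node_growth_matrix <- function(K, local, lid, p_w, p_m, R_w, R_m) {
  S <- nrow(local)
  P <- matrix(0, S, S)
  for (s in seq_len(S)) {
    w <- local[s, "w"]; u <- local[s, "u"]
    e0 <- K - w - u
    pb_w <- min(1, max(0, R_w * e0 / K))
    pb_m <- min(1, max(0, R_m * e0 / K))
    dw <- stats::dbinom(0:w, w, p_w)
    du <- stats::dbinom(0:u, u, p_m)
    for (Dw in 0:w) for (Du in 0:u) {
      pd <- dw[Dw + 1] * du[Du + 1]
      if (pd == 0) next
      sw <- w - Dw; su <- u - Du
      avail <- K - sw - su
      alloc <- .birth_allocation(w, u, pb_w, pb_m, avail)
      for (r in seq_len(nrow(alloc))) {
        tgt <- lid[sw + alloc[r, 1] + 1L, su + alloc[r, 2] + 1L]
        P[s, tgt] <- P[s, tgt] + pd * alloc[r, 3]
      }
    }
  }
  P
}

# Kronecker assembly of independent per-node kernels into the global
# kernel.  Node 1 is the fastest-varying index in the mixed-radix
# state id, so the product is taken in reverse node order.
.kron_nodes <- function(mats) {
  Reduce(function(a, b) kronecker(a, b), rev(mats))
}

# ---- exact migration kernel -------------------------------------------

# All non-negative integer vectors of length `parts` summing to `k`.
.compositions <- function(k, parts) {
  if (parts == 1) return(matrix(k, 1, 1))
  out <- list()
  for (first in 0:k) {
    rest <- .compositions(k - first, parts - 1)
    out[[length(out) + 1]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Average over uniformly random global move orders, with rejection of
# moves into full nodes.  `mv` is an integer matrix with columns
# src, dst, type (1 = wild, 2 = mutant), count.  Memoized on
# (counts, remaining moves).
.resolve_orders <- function(w, u, caps, mv, cache) {
  mv <- mv[mv[, 4] > 0, , drop = FALSE]
  if (nrow(mv) == 0) {
    out <- 1
    names(out) <- paste(c(w, u), collapse = ",")
    return(out)
  }
  key <- paste(c(w, u, t(mv)), collapse = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(mv[, 4])
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(mv))) {
    pr <- as.numeric(mv[r, 4]) / total
    w2 <- w; u2 <- u
    dd <- mv[r, 2]
    if (w2[dd] + u2[dd] < caps[dd]) {
      ss <- mv[r, 1]
      if (mv[r, 3] == 1L) { w2[ss] <- w2[ss] - 1L; w2[dd] <- w2[dd] + 1L }
      else { u2[ss] <- u2[ss] - 1L; u2[dd] <- u2[dd] + 1L }
    }
    mv2 <- mv
    mv2[r, 4] <- mv2[r, 4] - 1L
    sub <- .resolve_orders(w2, u2, caps, mv2, cache)
    for (nm in names(sub)) {
      acc[[nm]] <- (acc[[nm]] %||% 0) + pr * as.numeric(sub[[nm]])
    }
  }
  out <- unlist(as.list(acc))
  cache[[key]] <- out
  out
}

# Exact migration kernel: mixture over per-agent binomial migration
# decisions, multinomial destination choices, and uniformly random
# global move orders with full-node rejection.
.migration_matrix <- function(space, graph, m) {
  S <- nrow(space$W)
  P <- matrix(0, S, S)
  rt <- .graph_runtime(graph)
  caps <- space$caps
  n <- length(caps)
  if (m <= 0 || length(rt$has_out) == 0) {
    diag(P) <- 1
    return(P)
  }
  # units: one per (node with out-edges, type)
  units <- list()
  for (i in rt$has_out) {
    units[[length(units) + 1]] <- list(node = i, type = 1L)
    units[[length(units) + 1]] <- list(node = i, type = 2L)
  }
  cache <- new.env(parent = emptyenv())
  for (s in seq_len(S)) {
    w <- space$W[s, ]; u <- space$U[s, ]
    counts <- vapply(units, function(un) {
      if (un$type == 1L) w[un$node] else u[un$node]
    }, integer(1))
    # enumerate how many agents of each unit migrate
    grids <- lapply(counts, function(k) 0:k)
    combos <- as.matrix(expand.grid(grids))
    for (ci in seq_len(nrow(combos))) {
      ks <- combos[ci, ]
      p_mig <- prod(stats::dbinom(ks, counts, m))
      if (p_mig == 0) next
      # enumerate destination splits for each migrating unit
      split_opts <- vector("list", length(units))
      for (j in seq_along(units)) {
        k <- ks[j]
        o <- rt$out[[units[[j]]$node]]
        if (k == 0) {
          split_opts[[j]] <- list(list(mv = NULL, p = 1))
        } else {
          comps <- .compositions(k, length(o$dst))
          split_opts[[j]] <- lapply(seq_len(nrow(comps)), function(r) {
            cc <- comps[r, ]
            mv <- cbind(src = rep.int(units[[j]]$node, sum(cc > 0)),
                        dst = o$dst[cc > 0],
                        type = rep.int(units[[j]]$type, sum(cc > 0)),
                        count = cc[cc > 0])
            list(mv = mv, p = stats::dmultinom(cc, prob = o$prob))
          })
        }
      }
      # cartesian product over units
      partial <- list(list(mv = NULL, p = 1))
      for (j in seq_along(units)) {
        nxt <- list()
        for (a in partial) for (b in split_opts[[j]]) {
          nxt[[length(nxt) + 1]] <- list(mv = rbind(a$mv, b$mv), p = a$p * b$p)
        }
        partial <- nxt
      }
      for (a in partial) {
        mv <- a$mv
        if (is.null(mv)) {
          P[s, s] <- P[s, s] + p_mig * a$p
          next
        }
        res <- .resolve_orders(w, u, caps, mv, cache)
        for (nm in names(res)) {
          cnt <- as.integer(strsplit(nm, ",", fixed = TRUE)[[1]])
          tgt <- state_index(space, cnt[seq_len(n)], cnt[n + seq_len(n)])
          P[s, tgt] <- P[s, tgt] + p_mig * a$p * res[[nm]]
        }
      }
    }
  }
  P
}

#' Exact phase transition kernel on an enumerated state space
#'
#' Builds the row-stochastic transition matrix of one phase under
#' exactly the distributional rules of the simulator: binomial deaths,
#' binomial birth proposals with hypergeometric trimming against free
#' space, and migration as the exact mixture over per-agent binomial
#' migration decisions, multinomial destination choices, and uniformly
#' random global move orders with full-node rejection.
#'
#' Phases `"death"`, `"birth"`, and `"migration"` are the stand-alone
#' operators (propensities evaluated on the kernel's own input state).
#' `"growth"` is the exact joint death + birth of one generation, with
#' both propensities evaluated on the generation-start state as the
#' simulator does; `"step"` is `growth` followed by `migration` and is
#' the one-generation kernel used for absorption probabilities.  With
#' no antibiotic, `death` is the identity and `step` equals `birth`
#' composed with `migration`.
#'
#' @param space an [enumerate_states()] object.
#' @param phase one of `"death"`, `"birth"`, `"migration"`,
#'   `"growth"`, `"step"`.
#' @param graph the [metapop_graph()] (needed for migration).
#' @param params a [sim_params()].
#' @param max_states guard on the state-space size for dense kernels.
#' @return a dense row-stochastic matrix.
#' @export
phase_kernel <- function(space, phase, graph, params, max_states = 3000) {
  S <- nrow(space$W)
  if (S > max_states) {
    metamp_abort(sprintf("state space has %d states, above the kernel limit %d",
                         S, max_states),
                 "metamp_too_large")
  }
  phase <- match.arg(phase, c("death", "birth", "migration", "growth", "step"))
  p_w <- min(1, params$wild$kill_rate * params$antibiotic)
  p_m <- min(1, params$mutant$kill_rate * params$antibiotic)
  per_node <- function(fn) {
    mats <- lapply(seq_along(space$caps), function(i) {
      fn(space$caps[i], space$local[[i]], space$lid[[i]])
    })
    .kron_nodes(mats)
  }
  switch(phase,
    death = per_node(function(K, local, lid)
      .node_death_matrix(K, local, lid, p_w, p_m)),
    birth = per_node(function(K, local, lid)
      .node_birth_matrix(K, local, lid, params$wild$birth_rate,
                         params$mutant$birth_rate)),
    growth = per_node(function(K, local, lid)
      .node_growth_matrix(K, local, lid, p_w, p_m,
                          params$wild$birth_rate, params$mutant$birth_rate)),
    migration = .migration_matrix(space, graph, params$migration_prob),
    step = phase_kernel(space, "growth", graph, params, max_states) %*%
      .migration_matrix(space, graph, params$migration_prob)
  )
}

#' Exact absorption (fixation) probabilities
#'
#' Classifies every state as `mixed` (both types present), `mutant`
#' (no wild type, at least one mutant), `wild`, or `extinct`, and
#' solves the standard first-step linear system for the probability
#' that a chain started in each mixed state first leaves the mixed
#' class into each absorbing class, together with the expected number
#' of steps to absorption.  Mutant fixation means the wild type is gone
#' while the population itself may keep fluctuating.
#'
#' @param space an [enumerate_states()] object.
#' @param kernel the one-step kernel from `phase_kernel(space, "step",
#'   ...)`.
#' @return an object of class `fixation_table`: a data frame with the
#'   per-node counts (`w_<id>`, `m_<id>`), `class`, `p_mutant_fix`,
#'   `p_wild_fix`, `p_extinct`, `expected_steps`.
#' @export
fixation_probabilities <- function(space, kernel) {
  wt <- rowSums(space$W)
  mt <- rowSums(space$U)
  cls <- ifelse(wt > 0 & mt > 0, "mixed",
                ifelse(mt > 0, "mutant", ifelse(wt > 0, "wild", "extinct")))
  S <- nrow(space$W)
  p_mut <- as.numeric(cls == "mutant")
  p_wld <- as.numeric(cls == "wild")
  p_ext <- as.numeric(cls == "extinct")
  esteps <- numeric(S)
  mix <- which(cls == "mixed")
  if (length(mix)) {
    Q <- kernel[mix, mix, drop = FALSE]
    Rm <- rowSums(kernel[mix, cls == "mutant", drop = FALSE])
    Rw <- rowSums(kernel[mix, cls == "wild", drop = FALSE])
    Re <- rowSums(kernel[mix, cls == "extinct", drop = FALSE])
    A <- diag(length(mix)) - Q
    sol <- tryCatch(
      solve(A, cbind(Rm, Rw, Re, rep(1, length(mix)))),
      error = function(e) metamp_abort(
        sprintf("absorption system is singular: %s", conditionMessage(e)),
        "metamp_structural")
    )
    p_mut[mix] <- sol[, 1]
    p_wld[mix] <- sol[, 2]
    p_ext[mix] <- sol[, 3]
    esteps[mix] <- sol[, 4]
  }
  out <- data.frame(space$W, space$U, class = cls,
                    p_mutant_fix = p_mut, p_wild_fix = p_wld,
                    p_extinct = p_ext, expected_steps = esteps,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[seq_len(2 * length(space$caps))] <-
    c(paste0("w_", space$node_ids), paste0("m_", space$node_ids))
  structure(out, class = c("fixation_table", "data.frame"))
}

#' One-call exact fixation table for a tiny instance
#'
#' @param graph a [metapop_graph()].
#' @param params a [sim_params()].
#' @param limit state-space guard, see [enumerate_states()].
#' @return a `fixation_table`, see [fixation_probabilities()].
#' @export
fixation_table <- function(graph, params, limit = 2e5) {
  space <- enumerate_states(graph, limit)
  kernel <- phase_kernel(space, "step", graph, params)
  structure(fixation_probabilities(space, kernel), space = space)
}

# Brute-force cross-check: forward-iterate the stopped kernel (rows of
# non-mixed states replaced by identity) until the mass left on mixed
# states is below tol.  Used in tests against the linear solve.
.absorption_by_iteration <- function(space, kernel, start_idx,
                                     tol = 1e-12, max_iter = 100000) {
  wt <- rowSums(space$W)
  mt <- rowSums(space$U)
  mixed <- wt > 0 & mt > 0
  P <- kernel
  P[!mixed, ] <- 0
  diag(P)[!mixed] <- 1
  v <- numeric(nrow(P)); v[start_idx] <- 1
  it <- 0
  while (sum(v[mixed]) > tol && it < max_iter) {
    v <- as.numeric(v %*% P)
    it <- it + 1
  }
  c(mutant = sum(v[!mixed & mt > 0]),
    wild = sum(v[!mixed & mt == 0 & wt > 0]),
    extinct = sum(v[wt == 0 & mt == 0]))
}

#' Compare exact fixation probabilities with simulator frequencies
#'
#' Runs the simulator to absorption `n_runs` times from a given start
#' state and checks each empirical absorption frequency against the
#' exact value from the Markov-chain solve, passing when the deviation
#' is within 3 empirical standard errors.
#'
#' @param graph a tiny [metapop_graph()] (state space within limits).
#' @param params a [sim_params()].
#' @param init list with per-node `wild` and `mutant` start counts
#'   (a mixed state).
#' @param n_runs simulator replicates.
#' @param base_seed seed for the simulator runs.
#' @param max_steps cap per run.
#' @return data frame with one row per outcome: `outcome`, `exact`,
#'   `empirical`, `se`, `z`, `pass`; attribute `pass` is the overall
#'   verdict.
#' @export
check_oracle <- function(graph, params, init, n_runs = 10000L, base_seed = 1L,
                         max_steps = 10000L) {
  ft <- fixation_table(graph, params)
  space <- attr(ft, "space")
  idx <- state_index(space, init$wild, init$mutant)
  exact <- c(mutant = ft$p_mutant_fix[idx],
             wild = ft$p_wild_fix[idx],
             extinct = ft$p_extinct[idx])
  sim <- simulate_fixation(graph, params, n_runs = n_runs,
                           base_seed = base_seed, max_steps = max_steps,
                           init = init)
  counts <- table(sim$outcome)[c("mutant", "wild", "extinct")]
  .fixation_compare(exact, as.integer(counts), n_runs)
}

# Shared comparison core (also used as the negative-control hook in
# tests): counts are (mutant, wild, extinct) absorption tallies.
.fixation_compare <- function(exact, counts, n) {
  emp <- counts / n
  se <- sqrt(emp * (1 - emp) / n)
  z <- ifelse(se > 0, (emp - exact) / se, ifelse(emp == exact, 0, Inf))
  out <- data.frame(outcome = names(exact), exact = as.numeric(exact),
                    empirical = as.numeric(emp), se = as.numeric(se),
                    z = as.numeric(z),
                    pass = abs(as.numeric(z)) <= 3,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, pass = all(out$pass))
}
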