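#' Metapopulation mutant fraction
#'
#' Total mutants divided by total agents across all nodes.
#'
#' @param state a `sim_state`.
#' @return a value in \[0, 1\].  An empty metapopulation has no defined
#'   fraction and raises a `metamp_undefined_fraction` error; ensemble
#'   summaries report extinction separately instead.
#' @export
metapop_fraction <- function(state) {
  tot <- sum(state$wild) + sum(state$mutant)
  if (tot == 0) {
    metamp_abort("metapopulation is empty; the mutant fraction is undefined",
                 "metamp_undefined_fraction")
  }
  sum(state$mutant) / tot
}

#' Per-step metapopulation mutant fraction of a trajectory
#'
#' @param traj a `sim_trajectory`.
#' @return numeric vector over steps 0..n; `NA` at steps where the
#'   metapopulation is empty (extinct).
#' @export
traj_fractions <- function(traj) {
  mut <- rowSums(traj$mutant)
  tot <- rowSums(traj$wild) + mut
  ifelse(tot > 0, mut / tot, NA_real_)
}

#' Per-node mutant fractions of a trajectory
#'
#' @param traj a `sim_trajectory`.
#' @return matrix (step by node) of within-node mutant fractions, `NA`
#'   where a node is empty.
#' @export
node_fractions <- function(traj) {
  tot <- traj$wild + traj$mutant
  out <- traj$mutant / tot
  out[tot == 0] <- NA_real_
  out
}

#' Time to majority
#'
#' Smallest step at which the metapopulation mutant fraction reaches
#' `threshold` (default 50%), or `NA` if it never does.
#'
#' @param traj a `sim_trajectory`.
#' @param threshold majority threshold in (0, 1\].
#' @return integer step, or `NA_integer_`.
#' @export
time_to_majority <- function(traj, threshold = 0.5) {
  f <- traj_fractions(traj)
  hit <- which(!is.na(f) & f >= threshold)
  if (length(hit) == 0) NA_integer_ else as.integer(traj$step[hit[1]])
}

#' Fixation outcome of a trajectory
#'
#' First step at which one type is absent: `"mutant"` (no wild type
#' left, at least one mutant), `"wild"`, `"extinct"` (empty
#' metapopulation), or `"none"` if both types coexist to the end.
#'
#' @param traj a `sim_trajectory`.
#' @return list with `outcome` (character) and `step` (integer or NA).
#' @export
fixation_outcome <- function(traj) {
  wt <- rowSums(traj$wild)
  mt <- rowSums(traj$mutant)
  absorbed <- which(wt == 0L | mt == 0L)
  if (length(absorbed) == 0) return(list(outcome = "none", step = NA_integer_))
  i <- absorbed[1]
  out <- if (wt[i] == 0L && mt[i] == 0L) "extinct"
    else if (wt[i] == 0L) "mutant" else "wild"
  list(outcome = out, step = as.integer(traj$step[i]))
}

#' Ensemble summary of replicate trajectories
#'
#' Per-step mean and standard error of the metapopulation mutant
#' fraction over replicates, plus per-replicate times to majority and
#' fixation outcomes.  A replicate whose metapopulation goes extinct is
#' excluded from the mean from the extinction step onward (its fraction
#' is undefined) and counted in the `extinct` attribute; `n_alive`
#' records how many replicates contribute at each step.
#'
#' @param trajs a `sim_ensemble` or list of `sim_trajectory` objects of
#'   equal length.
#' @param threshold majority threshold passed to [time_to_majority()].
#' @return an object of class `ensemble_summary`: a data frame with
#'   columns `step`, `mean_fraction`, `se`, `n_alive`, and attributes
#'   `n_reps`, `majority` (data frame `replicate`, `time_to_majority`,
#'   `fixed`), `extinct`, `fractions` (replicate-by-step matrix).
#' @export
ensemble_average <- function(trajs, threshold = 0.5) {
  if (length(trajs) < 1) {
    metamp_abort("need at least one trajectory", "metamp_invalid_input")
  }
  lens <- vapply(trajs, function(tr) length(tr$step), integer(1))
  if (length(unique(lens)) != 1) {
    metamp_abort("trajectories have different lengths", "metamp_invalid_input")
  }
  fr <- do.call(rbind, lapply(trajs, traj_fractions))
  n_alive <- colSums(!is.na(fr))
  mean_f <- colMeans(fr, na.rm = TRUE)
  se <- apply(fr, 2, function(col) {
    k <- sum(!is.na(col))
    if (k > 1) stats::sd(col, na.rm = TRUE) / sqrt(k) else 0
  })
  mean_f[n_alive == 0] <- NA_real_
  ttm <- vapply(trajs, time_to_majority, integer(1), threshold = threshold)
  fix <- vapply(trajs, function(tr) fixation_outcome(tr)$outcome, character(1))
  out <- data.frame(step = trajs[[1]]$step, mean_fraction = mean_f,
                    se = se, n_alive = as.integer(n_alive), row.names = NULL)
  structure(out,
            class = c("ensemble_summary", "data.frame"),
            n_reps = length(trajs),
            majority = data.frame(replicate = seq_along(trajs),
                                  time_to_majority = ttm,
                                  fixed = fix == "mutant"),
            extinct = sum(fix == "extinct"),
            fractions = fr)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d replicates, steps 0..%d, %d extinct\n",
              attr(x, "n_reps"), max(x$step), attr(x, "extinct")))
  maj <- attr(x, "majority")
  cat(sprintf("  mutant fixed in %d replicates; median time to majority %s\n",
              sum(maj$fixed),
              stats::median(maj$time_to_majority[maj$fixed]) %||% NA))
  print.data.frame(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Expected mutant migrants per edge per step
#'
#' At the mutant effective carrying capacity, a patch sends `m * K * (1
#' - A / rho)` mutant migrants per step along an edge, where `rho = R /
#' Z` is the normalized resistance.  Transient amplification by star
#' topologies is expected when this quantity is on the order of one:
#' each colonized patch then seeds the next rarely enough that the
#' mutant first rises to high frequency locally, and spread proceeds
#' stepwise through the hub.
#'
#' @param migration_rate per-agent migration probability `m`.
#' @param spaces_per_node patch capacity `K`.
#' @param antibiotic antibiotic concentration `A`.
#' @param normalized_resistance `R / Z` (> 0).
#' @return expected migrants per edge per step (>= 0).
#' @examples
#' expected_migrants(1 / 1280, 1600, 0.2, 1)  # 1
#' @export
expected_migrants <- function(migration_rate, spaces_per_node, antibiotic,
                              normalized_resistance) {
  if (any(is.na(normalized_resistance)) || any(normalized_resistance <= 0)) {
    metamp_abort("normalized_resistance must be > 0", "metamp_invalid_parameter")
  }
  migration_rate * spaces_per_node *
    pmax(0, 1 - antibiotic / normalized_resistance)
}

#' Migration probability achieving a target expected-migrant count
#'
#' Inverse of [expected_migrants()]: the per-agent migration
#' probability at which a patch at mutant effective carrying capacity
#' sends `em_target` mutant migrants per edge per step.  Scenario
#' presets use targets 0.1 / 1 / 10 for low / intermediate / high
#' migration.
#'
#' @param em_target expected migrants per edge per step (> 0).
#' @param capacity patch capacity.
#' @param antibiotic antibiotic concentration.
#' @param mutant mutant [type_params()].
#' @return migration probability in (0, 1\].
#' @export
migration_for_em <- function(em_target, capacity = 1600, antibiotic = 0.25,
                             mutant = type_params(1, 1)) {
  keff <- effective_carrying_capacity(mutant$kill_rate, antibiotic,
                                      mutant$birth_rate, capacity)
  if (keff <= 0) {
    metamp_abort("effective carrying capacity is 0; no migration rate can reach the target",
                 "metamp_invalid_parameter")
  }
  m <- em_target / keff
  if (m > 1) {
    metamp_abort("target expected migrants requires migration probability > 1",
                 "metamp_invalid_parameter")
  }
  m
}

#' Migrant head-count implied by a dispersal dilution
#'
#' In the serial-transfer protocol, migration rate is set by diluting
#' the dispersal pool; a migration rate of `p` percent of a transfer
#' aliquot of `aliquot_cfu` colony-forming units corresponds to `p/100 *
#' aliquot_cfu` migrating individuals.  With the standard ~1e7 CFU
#' aliquot, 0.001% is ~100 individuals and 1% is ~1e5.
#'
#' @param migration_percent migration rate in percent.
#' @param aliquot_cfu transfer aliquot size in CFU.
#' @return number of migrating individuals.
#' @examples
#' migrants_from_dilution(0.001)  # 100
#' migrants_from_dilution(1)      # 1e5
#' @export
migrants_from_dilution <- function(migration_percent, aliquot_cfu = 1e7) {
  if (any(migration_percent < 0) || any(aliquot_cfu < 0)) {
    metamp_abort("migration_percent and aliquot_cfu must be >= 0",
                 "metamp_invalid_parameter")
  }
  migration_percent / 100 * aliquot_cfu
}

#' Amplification curve: star minus well-mixed mean fraction
#'
#' Per-step difference between the mean metapopulation mutant fractions
#' of two ensembles (conventionally star minus well-mixed) with the
#' pooled standard error.  Positive values at intermediate steps that
#' shrink toward late steps are the signature of transient
#' amplification.
#'
#' @param star,mixed `ensemble_summary` objects on the same step grid.
#' @return data frame with columns `step`, `diff`, `se`.
#' @export
amplification_curve <- function(star, mixed) {
  if (!isTRUE(all.equal(star$step, mixed$step))) {
    metamp_abort("the two summaries are on different step grids",
                 "metamp_invalid_input")
  }
  data.frame(step = star$step,
             diff = star$mean_fraction - mixed$mean_fraction,
             se = sqrt(star$se^2 + mixed$se^2))
}

#' Order in which nodes are taken over by the mutant
#'
#' Nodes sorted by the first step at which their within-node mutant
#' fraction reaches `threshold`; ties broken by node id; nodes that
#' never reach the threshold are listed last with `reached = FALSE`.
#'
#' @param traj a `sim_trajectory`.
#' @param threshold within-node fraction threshold, in (0, 1).
#' @return data frame with columns `node_id`, `cross_step` (NA if never
#'   crossed), `reached`, in spread order.
#' @export
per_node_spread_order <- function(traj, threshold = 0.5) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold >= 1) {
    metamp_abort("threshold must be in (0, 1)", "metamp_invalid_parameter")
  }
  nf <- node_fractions(traj)
  cross <- apply(nf, 2, function(col) {
    hit <- which(!is.na(col) & col >= threshold)
    if (length(hit)) traj$step[hit[1]] else NA_integer_
  })
  out <- data.frame(node_id = traj$node_ids,
                    cross_step = as.integer(cross),
                    reached = !is.na(cross),
                    stringsAsFactors = FALSE)
  out[order(!out$reached, out$cross_step, out$node_id), , drop = FALSE]
}
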