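# Scenario presets: the study conditions (4 patches of 1,600 spaces,
# 1,000 founders with a single resistant mutant introduced in leaf P3,
# 240 generations, 100 instantiations) combined with topology,
# migration level, dispersal asymmetry, and an optional bottleneck.
# Migration levels are calibrated through the expected-migrants
# diagnostic: low / intermediate / high correspond to ~0.1 / 1 / 10
# expected mutant migrants per edge per step at the mutant effective
# carrying capacity.

.preset_defaults <- list(
  capacity = 1600L,
  n_nodes = 4L,
  antibiotic = 0.25,
  advantage = 0.1,
  founders = 1000L,
  founder_mutants = 1L,
  n_steps = 240L,
  n_reps = 100L,
  asymmetry_ratio = 2,
  em_levels = c(low = 0.1, intermediate = 1, high = 10),
  bottleneck_every = 48L,   # once per experiment day (48 steps)
  bottleneck_fraction = 0.05
)

.preset_table <- function() {
  d <- .preset_defaults
  rows <- list(
    list(name = "star_low_m",            topology = "star",  em = "low",          asym = "balanced", bottleneck = FALSE),
    list(name = "star_intermediate_m",   topology = "star",  em = "intermediate", asym = "balanced", bottleneck = FALSE),
    list(name = "star_high_m",           topology = "star",  em = "high",         asym = "balanced", bottleneck = FALSE),
    list(name = "mixed_low_m",           topology = "mixed", em = "low",          asym = "balanced", bottleneck = FALSE),
    list(name = "mixed_intermediate_m",  topology = "mixed", em = "intermediate", asym = "balanced", bottleneck = FALSE),
    list(name = "mixed_high_m",          topology = "mixed", em = "high",         asym = "balanced", bottleneck = FALSE),
    list(name = "star_in_gt_out_low_m",  topology = "star",  em = "low",          asym = "in_gt_out", bottleneck = FALSE),
    list(name = "star_out_gt_in_low_m",  topology = "star",  em = "low",          asym = "out_gt_in", bottleneck = FALSE),
    list(name = "star_in_gt_out_high_m", topology = "star",  em = "high",         asym = "in_gt_out", bottleneck = FALSE),
    list(name = "star_out_gt_in_high_m", topology = "star",  em = "high",         asym = "out_gt_in", bottleneck = FALSE),
    list(name = "bottleneck_star_in_low_m", topology = "star",  em = "low", asym = "in_gt_out", bottleneck = TRUE),
    list(name = "bottleneck_mixed_low_m",   topology = "mixed", em = "low", asym = "balanced",  bottleneck = TRUE)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r$name, topology = r$topology, migration_level = r$em,
               asymmetry = r$asym, bottleneck = r$bottleneck,
               expected_migrants = unname(d$em_levels[r$em]),
               stringsAsFactors = FALSE)
  }))
}

#' List the built-in scenario presets
#'
#' Each preset resolves to a concrete (graph, parameters, replicate
#' count) tuple via [resolve_preset()].  Presets cover star and
#' well-mixed four-patch metapopulations at low / intermediate / high
#' migration (expected migrants per edge per step ~0.1 / 1 / 10),
#' inward- and outward-weighted star variants (2:1 weight ratio), and
#' bottlenecked variants with a daily 5% serial-transfer survival.
#'
#' @return data frame with columns `name`, `topology`,
#'   `migration_level`, `asymmetry`, `bottleneck`, `expected_migrants`.
#' @export
list_presets <- function() {
  .preset_table()
}

#' Resolve a scenario preset to a concrete configuration
#'
#' @param name a preset name from [list_presets()].
#' @param n_reps replicate count override.
#' @param n_steps step-count override.
#' @param seed base RNG seed recorded in the scenario.
#' @param capacity patch-capacity override (the reference conditions
#'   use 1,600 spaces per patch).
#' @param asymmetry_ratio weight ratio of the favoured over the
#'   disfavoured direction for asymmetric star presets.
#' @return an object of class `scenario_config`: list with `name`,
#'   `graph`, `params`, `n_reps`, `seed`, `hash` (FNV-1a of the
#'   resolved configuration).
#' @export
resolve_preset <- function(name, n_reps = NULL, n_steps = NULL, seed = 1L,
                           capacity = NULL, asymmetry_ratio = NULL) {
  tab <- .preset_table()
  if (length(name) != 1 || !name %in% tab$name) {
    metamp_abort(sprintf("unknown preset '%s'; see list_presets()", name),
                 "metamp_invalid_parameter")
  }
  d <- .preset_defaults
  row <- tab[tab$name == name, ]
  capacity <- as.integer(capacity %||% d$capacity)
  ratio <- asymmetry_ratio %||% d$asymmetry_ratio
  mutant <- type_params(1, 1)
  m <- migration_for_em(unname(d$em_levels[row$migration_level]),
                        capacity = capacity, antibiotic = d$antibiotic,
                        mutant = mutant)
  graph <- if (row$topology == "mixed") {
    build_well_mixed(d$n_nodes, capacity)
  } else {
    w <- switch(row$asymmetry,
                balanced = c(1, 1),
                in_gt_out = c(ratio, 1),
                out_gt_in = c(1, ratio))
    build_star(d$n_nodes - 1L, capacity, w[1], w[2])
  }
  params <- sim_params(
    antibiotic = d$antibiotic,
    migration_prob = m,
    n_steps = as.integer(n_steps %||% d$n_steps),
    mutant = mutant,
    wild = calibrate_wild_kill(d$advantage, mutant, d$antibiotic),
    founders = d$founders,
    founder_mutants = d$founder_mutants,
    bottleneck_every = if (row$bottleneck) d$bottleneck_every else NULL,
    bottleneck_fraction = if (row$bottleneck) d$bottleneck_fraction else NULL,
    intro_node = "P3",
    seed = as.integer(seed)
  )
  sc <- list(name = name, graph = graph, params = params,
             n_reps = as.integer(n_reps %||% d$n_reps),
             seed = as.integer(seed))
  sc$hash <- config_hash(scenario_json(sc))
  structure(sc, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s [%s]: %d reps x %d steps, m = %g, seed %d\n",
              x$name, x$hash, x$n_reps, x$params$n_steps,
              x$params$migration_prob, x$seed))
  invisible(x)
}

# JSON serialization of a resolved scenario (graph + params + schedule),
# used both for the metadata file and for the configuration hash.
scenario_json <- function(scenario) {
  p <- scenario$params
  jsonlite::toJSON(list(
    name = scenario$name,
    n_reps = scenario$n_reps,
    seed = scenario$seed,
    graph = list(nodes = scenario$graph$nodes, edges = scenario$graph$edges),
    params = list(
      antibiotic = p$antibiotic, migration_prob = p$migration_prob,
      n_steps = p$n_steps,
      wild = unclass(p$wild), mutant = unclass(p$mutant),
      founders = p$founders, founder_mutants = p$founder_mutants,
      doubling_time_min = p$doubling_time_min,
      bottleneck_every = p$bottleneck_every,
      bottleneck_fraction = p$bottleneck_fraction,
      intro_node = p$intro_node
    ),
    package_version = as.character(utils::packageVersion("metamp"))
  ), dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
  null = "null")
}

#' Write an ensemble of trajectories as tidy CSV
#'
#' Columns `replicate`, `step`, `node_id`, `wild`, `mutant`, in
#' deterministic (replicate, step, node) order.
#'
#' @param trajs a `sim_ensemble`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  utils::write.csv(as.data.frame(trajs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run one scenario: simulate, summarize, optionally write outputs
#'
#' Runs the ensemble for a preset (or an already-resolved
#' `scenario_config`), computes the [ensemble_average()], and, when
#' `out_dir` is given, writes `<name>_trajectories.csv`,
#' `<name>_summary.csv` (step, mean_fraction, se, n_alive),
#' `<name>_majority.csv` (replicate, time_to_majority, fixed), and
#' `<name>_meta.json` (the resolved configuration, its hash, and the
#' seed).  Re-running the same scenario reproduces the outputs
#' byte-for-byte.
#'
#' @param scenario preset name or `scenario_config`.
#' @param out_dir output directory, created if needed; `NULL` writes
#'   nothing.
#' @param ... passed to [resolve_preset()] when `scenario` is a name.
#' @return list with `scenario`, `trajectories` (`sim_ensemble`), and
#'   `summary` (`ensemble_summary`), invisibly when writing files.
#' @export
run_scenario <- function(scenario, out_dir = NULL, ...) {
  if (is.character(scenario)) scenario <- resolve_preset(scenario, ...)
  if (!inherits(scenario, "scenario_config")) {
    metamp_abort("scenario must be a preset name or scenario_config",
                 "metamp_invalid_parameter")
  }
  trajs <- run_ensemble(scenario$graph, scenario$params,
                        n_reps = scenario$n_reps, base_seed = scenario$seed)
  summ <- ensemble_average(trajs)
  res <- list(scenario = scenario, trajectories = trajs, summary = summ)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    base <- file.path(out_dir, scenario$name)
    write_trajectories(trajs, paste0(base, "_trajectories.csv"))
    sdf <- as.data.frame(summ)
    sdf$config_hash <- scenario$hash
    utils::write.csv(sdf, paste0(base, "_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    maj <- attr(summ, "majority")
    maj$config_hash <- scenario$hash
    utils::write.csv(maj, paste0(base, "_majority.csv"),
                     row.names = FALSE, quote = FALSE)
    meta <- jsonlite::fromJSON(scenario_json(scenario), simplifyVector = FALSE)
    meta$config_hash <- scenario$hash
    meta$extinct_replicates <- attr(summ, "extinct")
    jsonlite::write_json(meta, paste0(base, "_meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    return(invisible(res))
  }
  res
}

#' Run a sweep over topology and migration level
#'
#' Runs every (topology, migration level) arm of the balanced presets
#' and, for each migration level present in both topologies, the
#' star-minus-mixed [amplification_curve()].
#'
#' @param topologies subset of `c("star", "mixed")`.
#' @param migration_levels subset of `c("low", "intermediate",
#'   "high")`.
#' @param n_reps,n_steps,seed overrides applied to every arm (see
#'   [resolve_preset()]).
#' @param out_dir optional output directory passed to
#'   [run_scenario()]; amplification curves are written there as
#'   `amplification_<level>.csv`.
#' @return list with `summaries` (named by preset) and `amplification`
#'   (named by migration level).
#' @export
run_sweep <- function(topologies = c("star", "mixed"),
                      migration_levels = c("low", "intermediate", "high"),
                      n_reps = NULL, n_steps = NULL, seed = 1L,
                      out_dir = NULL) {
  topologies <- unique(topologies)
  migration_levels <- unique(migration_levels)
  if (length(topologies) == 0 || length(migration_levels) == 0) {
    metamp_abort("the sweep grid is empty", "metamp_invalid_input")
  }
  bad_t <- setdiff(topologies, c("star", "mixed"))
  bad_m <- setdiff(migration_levels, c("low", "intermediate", "high"))
  if (length(bad_t) || length(bad_m)) {
    metamp_abort(sprintf("unknown sweep levels: %s",
                         paste(c(bad_t, bad_m), collapse = ", ")),
                 "metamp_invalid_input")
  }
  summaries <- list()
  for (topo in topologies) {
    for (lev in migration_levels) {
      nm <- paste0(topo, "_", lev, "_m")
      res <- run_scenario(nm, out_dir = out_dir, n_reps = n_reps,
                          n_steps = n_steps, seed = seed)
      summaries[[nm]] <- res$summary
    }
  }
  amp <- list()
  if (all(c("star", "mixed") %in% topologies)) {
    for (lev in migration_levels) {
      curve <- amplification_curve(summaries[[paste0("star_", lev, "_m")]],
                                   summaries[[paste0("mixed_", lev, "_m")]])
      amp[[lev]] <- curve
      if (!is.null(out_dir)) {
        utils::write.csv(curve,
                         file.path(out_dir, paste0("amplification_", lev, ".csv")),
                         row.names = FALSE, quote = FALSE)
      }
    }
  }
  list(summaries = summaries, amplification = amp)
}
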