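#' Per-type demographic parameters
#'
#' Each agent type (wild type or resistant mutant) is described by a
#' per-generation reproduction propensity and a first-order antibiotic
#' kill coefficient.  In a node with `empty` free spaces out of `K`, an
#' agent reproduces with probability `birth_rate * empty / K`
#' (logistic, Lotka-Volterra-like crowding) and dies with probability
#' `min(1, kill_rate * antibiotic)`.
#'
#' @param birth_rate per-step reproduction propensity, in \[0, 1\].
#' @param kill_rate first-order kill coefficient (>= 0); the product
#'   `kill_rate * antibiotic` is the per-step death probability
#'   (capped at 1).
#' @return an object of class `type_params`.
#' @examples
#' mutant <- type_params(birth_rate = 1, kill_rate = 1)
#' @export
type_params <- function(birth_rate, kill_rate) {
  if (length(birth_rate) != 1 || is.na(birth_rate) ||
      birth_rate < 0 || birth_rate > 1) {
    metamp_abort("birth_rate must be a single value in [0, 1]",
                 "metamp_invalid_parameter")
  }
  if (length(kill_rate) != 1 || is.na(kill_rate) || kill_rate < 0 ||
      !is.finite(kill_rate)) {
    metamp_abort("kill_rate must be a single finite value >= 0",
                 "metamp_invalid_parameter")
  }
  structure(list(birth_rate = as.numeric(birth_rate),
                 kill_rate = as.numeric(kill_rate)),
            class = "type_params")
}

#' @export
print.type_params <- function(x, ...) {
  cat(sprintf("<type_params> birth_rate = %g, kill_rate = %g\n",
              x$birth_rate, x$kill_rate))
  invisible(x)
}

#' Simulation parameters
#'
#' Bundles the environment (antibiotic concentration), the two competing
#' types, migration, founding conditions, the time schedule, and an
#' optional periodic bottleneck emulating serial-transfer dilution.
#'
#' Defaults encode the reference conditions used throughout: 1000
#' founders of which one is a resistant mutant introduced in a non-hub
#' patch, 240 generations (five experiment days at a 30-minute doubling
#' time, see [steps_for_days()]), mutant `birth_rate = 1`, `kill_rate =
#' 1` at antibiotic 0.25 (mutant effective carrying capacity 0.75 K),
#' and a wild type calibrated by [calibrate_wild_kill()] to give the
#' mutant a 10% per-step invasion advantage.
#'
#' @param antibiotic antibiotic concentration `A` (>= 0, arbitrary
#'   units).
#' @param migration_prob per-agent per-step migration probability `m`,
#'   in \[0, 1\].
#' @param n_steps number of generations to simulate (>= 0).
#' @param mutant,wild [type_params()] for the two types.
#' @param founders number of founding agents placed at step 0.
#' @param founder_mutants how many founders are resistant mutants (all
#'   placed in `intro_node`).
#' @param doubling_time_min generation time in minutes (bookkeeping for
#'   the day/step conversion).
#' @param bottleneck_every if non-`NULL`, apply a bottleneck every this
#'   many steps.
#' @param bottleneck_fraction per-agent survival probability of the
#'   bottleneck, in (0, 1\].
#' @param intro_node node id receiving the founder mutants; `NULL`
#'   selects `"P3"` when present (a leaf), otherwise the first non-hub
#'   node.
#' @param seed RNG seed used by [sim_run()]; `NULL` leaves the RNG
#'   state alone.
#' @return an object of class `sim_params`.
#' @examples
#' p <- sim_params(migration_prob = 1 / 1200, n_steps = 240, seed = 1)
#' @export
sim_params <- function(antibiotic = 0.25,
                       migration_prob = 0,
                       n_steps = 240L,
                       mutant = type_params(1, 1),
                       wild = calibrate_wild_kill(0.1, mutant, antibiotic),
                       founders = 1000L,
                       founder_mutants = 1L,
                       doubling_time_min = 30,
                       bottleneck_every = NULL,
                       bottleneck_fraction = NULL,
                       intro_node = NULL,
                       seed = NULL) {
  chk1 <- function(x, nm, lo, hi = Inf) {
    if (length(x) != 1 || is.na(x) || x < lo || x > hi) {
      metamp_abort(sprintf("%s must be a single value in [%s, %s]", nm, lo, hi),
                   "metamp_invalid_parameter")
    }
  }
  chk1(antibiotic, "antibiotic", 0)
  chk1(migration_prob, "migration_prob", 0, 1)
  chk1(n_steps, "n_steps", 0)
  chk1(founders, "founders", 0)
  chk1(founder_mutants, "founder_mutants", 0, founders)
  chk1(doubling_time_min, "doubling_time_min", .Machine$double.eps)
  if (!inherits(mutant, "type_params") || !inherits(wild, "type_params")) {
    metamp_abort("wild and mutant must be type_params objects",
                 "metamp_invalid_parameter")
  }
  if (!is.null(bottleneck_every) || !is.null(bottleneck_fraction)) {
    if (is.null(bottleneck_every) || is.null(bottleneck_fraction)) {
      metamp_abort("bottleneck_every and bottleneck_fraction must be given together",
                   "metamp_invalid_parameter")
    }
    chk1(bottleneck_every, "bottleneck_every", 1)
    if (bottleneck_fraction <= 0 || bottleneck_fraction > 1) {
      metamp_abort("bottleneck_fraction must be in (0, 1]",
                   "metamp_invalid_parameter")
    }
  }
  structure(list(
    antibiotic = as.numeric(antibiotic),
    migration_prob = as.numeric(migration_prob),
    n_steps = as.integer(n_steps),
    wild = wild,
    mutant = mutant,
    founders = as.integer(founders),
    founder_mutants = as.integer(founder_mutants),
    doubling_time_min = as.numeric(doubling_time_min),
    bottleneck_every = if (is.null(bottleneck_every)) NULL else as.integer(bottleneck_every),
    bottleneck_fraction = if (is.null(bottleneck_fraction)) NULL else as.numeric(bottleneck_fraction),
    intro_node = intro_node,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_params> A = %g, m = %g, %d steps\n",
    "  wild:   birth %g, kill %g\n",
    "  mutant: birth %g, kill %g\n",
    "  founders %d (%d mutant), intro node %s, seed %s\n"),
    x$antibiotic, x$migration_prob, x$n_steps,
    x$wild$birth_rate, x$wild$kill_rate,
    x$mutant$birth_rate, x$mutant$kill_rate,
    x$founders, x$founder_mutants,
    x$intro_node %||% "<auto>",
    if (is.null(x$seed)) "<none>" else x$seed))
  if (!is.null(x$bottleneck_every)) {
    cat(sprintf("  bottleneck: fraction %g every %d steps\n",
                x$bottleneck_fraction, x$bottleneck_every))
  }
  invisible(x)
}

#' Convert experiment days to simulation steps
#'
#' One simulation step is one generation; with a doubling time of `t`
#' minutes, `days` days correspond to `round(days * 24 * 60 / t)`
#' generations.  Five days at a 30-minute doubling time give 240 steps.
#'
#' @param days experiment duration in days (> 0).
#' @param doubling_time_min generation time in minutes (> 0).
#' @return integer number of steps.
#' @examples
#' steps_for_days(5, 30)  # 240
#' @export
steps_for_days <- function(days, doubling_time_min = 30) {
  if (length(days) != 1 || is.na(days) || days <= 0 ||
      length(doubling_time_min) != 1 || is.na(doubling_time_min) ||
      doubling_time_min <= 0) {
    metamp_abort("days and doubling_time_min must be positive",
                 "metamp_invalid_parameter")
  }
  as.integer(round(days * 24 * 60 / doubling_time_min))
}

#' Effective carrying capacity under antibiotic
#'
#' The equilibrium occupancy of a single patch holding one type: `(1 -
#' Z * A / R) * K`, floored at 0.  When `Z * A / R >= 1` (antibiotic at
#' or above the normalized resistance `R / Z`) the type is eliminated
#' and the effective capacity is 0.
#'
#' @param kill_rate first-order kill coefficient `Z` (>= 0).
#' @param antibiotic antibiotic concentration `A` (>= 0).
#' @param birth_rate growth rate `R` (> 0).
#' @param capacity spaces in the patch `K` (>= 1).
#' @return the effective carrying capacity (real; not rounded).
#' @examples
#' effective_carrying_capacity(1, 0.25, 1, 1600)  # 1200
#' @export
effective_carrying_capacity <- function(kill_rate, antibiotic, birth_rate, capacity) {
  if (length(birth_rate) != 1 || is.na(birth_rate) || birth_rate <= 0) {
    metamp_abort("birth_rate must be > 0", "metamp_invalid_parameter")
  }
  if (any(c(kill_rate, antibiotic) < 0) || capacity < 1) {
    metamp_abort("kill_rate and antibiotic must be >= 0 and capacity >= 1",
                 "metamp_invalid_parameter")
  }
  max(0, 1 - kill_rate * antibiotic / birth_rate) * capacity
}

#' Calibrate the wild-type kill rate from a target selective advantage
#'
#' The model states growth and kill rates for the resistant mutant; the
#' sensitive wild type shares the mutant's birth rate and is assigned a
#' larger kill coefficient.  This helper chooses the wild-type kill
#' rate so that a rare mutant invading a patch of wild type sitting at
#' its own carrying capacity grows by a factor `1 + advantage` per step
#' (invasion fitness; the resident's growth factor there is 1 by
#' definition of its equilibrium).  With a shared birth rate this gives
#' `Z_wild = Z_mutant + advantage / A`.
#'
#' The default of 10% per step makes a within-patch selective sweep
#' from a single copy take roughly 70 generations to majority, so that
#' patch-to-patch spread through a four-patch metapopulation plays out
#' across the standard 240-step (five-day) observation window.
#'
#' @param advantage per-step invasion growth advantage of the mutant
#'   (> 0).
#' @param mutant mutant [type_params()].
#' @param antibiotic antibiotic concentration (> 0; with no antibiotic
#'   the kill coefficient cannot encode a disadvantage).
#' @param birth_rate wild-type birth rate; defaults to the mutant's.
#' @return wild-type [type_params()].
#' @examples
#' calibrate_wild_kill(0.1, type_params(1, 1), 0.25)  # kill_rate 1.4
#' @export
calibrate_wild_kill <- function(advantage = 0.1,
                                mutant = type_params(1, 1),
                                antibiotic = 0.25,
                                birth_rate = mutant$birth_rate) {
  if (length(advantage) != 1 || is.na(advantage) || advantage <= 0) {
    metamp_abort("advantage must be > 0", "metamp_invalid_parameter")
  }
  if (length(antibiotic) != 1 || is.na(antibiotic) || antibiotic <= 0) {
    metamp_abort("antibiotic must be > 0 to calibrate a kill-rate difference",
                 "metamp_invalid_parameter")
  }
  kill_wild <- mutant$kill_rate * (birth_rate / mutant$birth_rate) +
    advantage / antibiotic
  if (kill_wild * antibiotic / birth_rate >= 1) {
    metamp_abort("calibration eliminates the wild type (Z*A/R >= 1); lower the advantage or antibiotic",
                 "metamp_invalid_parameter")
  }
  type_params(birth_rate = birth_rate, kill_rate = kill_wild)
}
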