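#' Three-parameter logistic spread curve
#'
#' The logistic growth model used to summarize the spread of the
#' resistant mutant through a metapopulation: of the three parameters
#' (initial proportion `N0`, rate `r`, plateau), `N0` is fixed to the
#' known inoculation proportion, leaving the spread rate (the `r_max`
#' analogue) and the final-frequency plateau (the carrying-capacity
#' analogue) free.
#'
#' @param t time (steps or days); vectorized.
#' @param N0 initial proportion at `t = 0`, in (0, plateau).
#' @param r logistic rate per unit of `t`.
#' @param plateau asymptotic proportion, in (N0, 1\].
#' @return `plateau / (1 + ((plateau - N0) / N0) * exp(-r * t))`;
#'   equals `N0` at `t = 0`.
#' @examples
#' logistic_curve(0:5, N0 = 0.001, r = 0.4, plateau = 0.95)
#' @export
logistic_curve <- function(t, N0, r, plateau) {
  if (length(N0) != 1 || length(plateau) != 1 || is.na(N0) || is.na(plateau) ||
      N0 <= 0 || N0 >= plateau || plateau > 1) {
    metamp_abort("need 0 < N0 < plateau <= 1", "metamp_invalid_parameter")
  }
  plateau / (1 + ((plateau - N0) / N0) * exp(-r * t))
}

# Deterministic initialization: r0 from the log-slope of the early
# (below half-plateau) points, plateau0 from the largest observed
# proportion, both clamped into bounds.
.fit_init <- function(times, props, N0) {
  plateau0 <- min(1, max(max(props, na.rm = TRUE), N0 * 1.0001 + 1e-8))
  early <- which(props < plateau0 / 2)
  if (length(early) < 3) early <- seq_len(min(3, length(times)))
  y <- log(pmax(props[early], N0 / 100))
  r0 <- tryCatch(unname(stats::coef(stats::lm(y ~ times[early]))[2]),
                 error = function(e) 0)
  if (!is.finite(r0)) r0 <- 0
  list(r = r0, plateau = plateau0)
}

#' Fit the logistic spread model by nonlinear least squares
#'
#' Levenberg-Marquardt NLS (via [minpack.lm::nlsLM()]) of
#' [logistic_curve()] to observed proportions with `N0` held fixed,
#' fitting on the proportion scale.  The initialization is
#' deterministic: the rate from the log-slope of the early points and
#' the plateau from the largest observed proportion (bounded into
#' `(N0, 1]`), so the fit is reproducible given the data.  If the LM
#' iteration fails, a bounded quasi-Newton minimization of the same
#' sum of squares is used as fallback; if that also fails the result
#' is flagged unconverged and carries no estimates.
#'
#' @param times observation times.
#' @param proportions observed mutant proportions (nominally in
#'   \[0, 1\]; small excursions from measurement noise are tolerated).
#' @param N0 fixed initial proportion (default 0.001, the 1:1000
#'   founding ratio).
#' @return an object of class `logistic_fit`: list with `r_max`,
#'   `plateau`, `fixed_N0`, `sse`, `converged`, `method`, `n`.
#' @examples
#' t <- 0:10
#' y <- logistic_curve(t, 0.001, 0.4, 0.95)
#' fit_logistic(t, y)
#' @export
fit_logistic <- function(times, proportions, N0 = 0.001) {
  if (length(times) != length(proportions) || length(times) < 3) {
    metamp_abort("need at least 3 (time, proportion) points of equal length",
                 "metamp_invalid_input")
  }
  if (any(!is.finite(times)) || any(!is.finite(proportions))) {
    metamp_abort("times and proportions must be finite", "metamp_invalid_input")
  }
  if (length(N0) != 1 || is.na(N0) || N0 <= 0 || N0 >= 1) {
    metamp_abort("N0 must be in (0, 1)", "metamp_invalid_parameter")
  }
  init <- .fit_init(times, proportions, N0)
  lower <- c(r = -Inf, plateau = N0 + 1e-9)
  upper <- c(r = Inf, plateau = 1)
  init$plateau <- min(max(init$plateau, lower["plateau"]), upper["plateau"])
  sse_of <- function(r, plateau) {
    sum((proportions - logistic_curve(times, N0, r, plateau))^2)
  }
  res <- tryCatch({
    fit <- suppressWarnings(minpack.lm::nlsLM(
      proportions ~ plateau / (1 + ((plateau - N0) / N0) * exp(-r * times)),
      start = init, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ))
    cf <- stats::coef(fit)
    list(r = unname(cf["r"]), plateau = unname(cf["plateau"]),
         converged = fit$convInfo$isConv %||% TRUE, method = "nlsLM")
  }, error = function(e) NULL)
  if (is.null(res)) {
    res <- tryCatch({
      opt <- stats::optim(unlist(init),
                          function(p) sse_of(p[1], p[2]),
                          method = "L-BFGS-B", lower = lower, upper = upper)
      list(r = unname(opt$par[1]), plateau = unname(opt$par[2]),
           converged = opt$convergence == 0, method = "optim")
    }, error = function(e) NULL)
  }
  if (is.null(res)) {
    out <- list(r_max = NA_real_, plateau = NA_real_, fixed_N0 = N0,
                sse = NA_real_, converged = FALSE, method = "none",
                n = length(times))
    return(structure(out, class = "logistic_fit"))
  }
  structure(list(r_max = res$r, plateau = res$plateau, fixed_N0 = N0,
                 sse = sse_of(res$r, res$plateau),
                 converged = isTRUE(res$converged), method = res$method,
                 n = length(times)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged && is.na(x$r_max)) {
    cat("<logistic_fit> not converged (no estimates)\n")
    return(invisible(x))
  }
  cat(sprintf("<logistic_fit> r_max = %.4g per step, plateau = %.4g (N0 fixed at %g)\n",
              x$r_max, x$plateau, x$fixed_N0))
  cat(sprintf("  SSE %.4g over %d points (%s%s)\n", x$sse, x$n, x$method,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit the logistic spread model to simulated trajectories
#'
#' Convenience wrappers: for a single `sim_trajectory` the
#' metapopulation mutant fraction is fitted against the step index; for
#' an `ensemble_summary` either the per-step mean curve (`pooled =
#' TRUE`) or each replicate separately (the default, matching
#' per-replicate summaries) is fitted.
#'
#' @param x a `sim_trajectory` or `ensemble_summary`.
#' @param N0 fixed initial proportion; `NULL` uses the observed
#'   fraction at step 0.
#' @param pooled for ensembles: fit the mean curve instead of each
#'   replicate.
#' @param ... unused.
#' @return for a trajectory, a `logistic_fit`; for an ensemble, a data
#'   frame with one row per fit (`replicate`, `r_max`, `plateau`,
#'   `sse`, `converged`; replicate `NA` for a pooled fit).
#' @export
fit_spread <- function(x, N0 = NULL, pooled = FALSE, ...) {
  UseMethod("fit_spread")
}

#' @rdname fit_spread
#' @export
fit_spread.sim_trajectory <- function(x, N0 = NULL, pooled = FALSE, ...) {
  f <- traj_fractions(x)
  keep <- !is.na(f)
  N0 <- N0 %||% f[1]
  fit_logistic(x$step[keep], f[keep], N0 = N0)
}

#' @rdname fit_spread
#' @export
fit_spread.ensemble_summary <- function(x, N0 = NULL, pooled = FALSE, ...) {
  if (pooled) {
    keep <- !is.na(x$mean_fraction)
    N0 <- N0 %||% x$mean_fraction[which(keep)[1]]
    fit <- fit_logistic(x$step[keep], x$mean_fraction[keep], N0 = N0)
    return(data.frame(replicate = NA_integer_, r_max = fit$r_max,
                      plateau = fit$plateau, sse = fit$sse,
                      converged = fit$converged))
  }
  fr <- attr(x, "fractions")
  out <- lapply(seq_len(nrow(fr)), function(i) {
    f <- fr[i, ]
    keep <- !is.na(f)
    if (sum(keep) < 3) {
      return(data.frame(replicate = i, r_max = NA_real_, plateau = NA_real_,
                        sse = NA_real_, converged = FALSE))
    }
    n0 <- N0 %||% max(f[keep][1], 1e-6)
    fit <- fit_logistic(x$step[keep], f[keep], N0 = n0)
    data.frame(replicate = i, r_max = fit$r_max, plateau = fit$plateau,
               sse = fit$sse, converged = fit$converged)
  })
  do.call(rbind, out)
}
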