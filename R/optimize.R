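#' Objective weights
#'
#' Weights of the two optimization targets: the fit objective compares
#' per-replicate scores to the human reference score `R_ref`; the
#' performance objective maximizes `a * mean + b * sd` of the scores.
#'
#' @param a Weight of the mean score. Default 1.
#' @param b Weight of the sample standard deviation. Default 0.
#' @param R_ref Human reference score in rounds on target. Default 7.9
#'   (the literature value for 40-round episodes).
#' @return An object of class `ibl_weights`.
#' @export
objective_weights <- function(a = 1, b = 0, R_ref = 7.9) {
  stopifnot(is.finite(a), is.finite(b), is.finite(R_ref))
  structure(list(a = a, b = b, R_ref = R_ref), class = "ibl_weights")
}

#' Root-mean-square deviation from a reference score
#'
#' `sqrt(mean((scores - R_ref)^2))`, the fit criterion between simulated
#' per-replicate scores and a human reference value.
#'
#' @param scores Numeric vector of per-replicate episode scores.
#' @param R_ref Reference score.
#' @return RMSD in rounds.
#' @export
score_rmsd <- function(scores, R_ref) {
  stopifnot(length(scores) >= 1L)
  sqrt(mean((scores - R_ref)^2))
}

# Build a config at theta = (tau, P), holding d and the remaining settings
# fixed at the template's values.
config_at <- function(theta, config) {
  p0 <- config$params
  cfg <- config
  cfg$params <- act_params(tau = theta[[1L]], P = theta[[2L]], d = p0$d,
                           s = p0$s, T = p0$T, M = p0$M)
  cfg
}

#' Fit objective at a parameter point
#'
#' RMSD between the per-replicate scores at `theta = (tau, P)` and the
#' human reference `R_ref`, evaluated on a frozen replicate batch (common
#' random numbers), so repeated evaluation at the same `theta` is
#' bit-identical. The decay `d` stays fixed at the config's value.
#'
#' @param theta Numeric vector `c(tau, P)`.
#' @param batch List of frozen `ibl_streams` replicates.
#' @param config An [sim_config()] template.
#' @param weights An [objective_weights()] object (only `R_ref` is used).
#' @return RMSD in rounds (to be minimized).
#' @export
fit_objective <- function(theta, batch, config, weights = objective_weights()) {
  res <- run_batch(config_at(theta, config), batch)
  score_rmsd(res$scores, weights$R_ref)
}

#' Performance objective at a parameter point
#'
#' `a * mean(scores) + b * sd(scores)` over a frozen replicate batch
#' (sample standard deviation, n-1 denominator). To be maximized.
#'
#' @inheritParams fit_objective
#' @return Weighted score in rounds.
#' @export
performance_objective <- function(theta, batch, config,
                                  weights = objective_weights()) {
  if (weights$b != 0 && length(batch) < 2L) {
    stop("b != 0 needs at least 2 replicates for a standard deviation")
  }
  res <- run_batch(config_at(theta, config), batch)
  weights$a * res$mean + weights$b * res$sd
}

#' Inclusive grid axis
#'
#' The lattice `lo, lo + step, ..., <= hi` with
#' `floor((hi - lo)/step) + 1` points (a small tolerance absorbs floating
#' point error in the division).
#'
#' @param lo,hi Axis range.
#' @param step Positive step.
#' @return Numeric vector of grid values.
#' @export
grid_axis <- function(lo, hi, step) {
  stopifnot(step > 0, hi >= lo)
  k <- floor((hi - lo) / step + 1e-9)
  lo + step * (0:k)
}

#' Parameter-grid sweep
#'
#' Evaluates the model on every point of a `(tau, P)` lattice, over a
#' frozen replicate batch, and records the mean score, its sample
#' standard deviation, and the learned-only mean (on-target rounds that
#' were decided by a retrieved instance). The sweep is embarrassingly
#' parallel over grid points; this implementation is serial and its
#' results are independent of evaluation order.
#'
#' @param tau_range,P_range Length-2 numeric ranges `c(lo, hi)`.
#' @param tau_step,P_step Positive steps.
#' @param batch List of frozen `ibl_streams` replicates.
#' @param config An [sim_config()] template (its `tau`/`P` are overridden
#'   at each grid point).
#' @return An object of class `ibl_sweep`: `tau_axis`, `P_axis`, matrices
#'   `mean_score`, `sd_score`, `learned_mean` of shape
#'   `(|tau_axis|, |P_axis|)`, and `n` (replicates).
#' @export
grid_sweep <- function(tau_range, tau_step, P_range, P_step, batch, config) {
  tau_axis <- grid_axis(tau_range[[1L]], tau_range[[2L]], tau_step)
  P_axis <- grid_axis(P_range[[1L]], P_range[[2L]], P_step)
  nt <- length(tau_axis); np <- length(P_axis)
  m <- matrix(NA_real_, nt, np)
  s <- matrix(NA_real_, nt, np)
  lm <- matrix(NA_real_, nt, np)
  for (it in seq_len(nt)) {
    for (ip in seq_len(np)) {
      res <- run_batch(config_at(c(tau_axis[it], P_axis[ip]), config), batch)
      m[it, ip] <- res$mean
      s[it, ip] <- res$sd
      lm[it, ip] <- res$learned_mean
    }
  }
  structure(list(tau_axis = tau_axis, P_axis = P_axis, mean_score = m,
                 sd_score = s, learned_mean = lm, n = length(batch)),
            class = "ibl_sweep")
}

#' Sweep grid in long format
#'
#' @param sweep An `ibl_sweep` object.
#' @return A data frame with columns `tau`, `P`, `mean`, `sd`,
#'   `learned_mean`, one row per grid point.
#' @export
sweep_to_long <- function(sweep) {
  stopifnot(inherits(sweep, "ibl_sweep"))
  g <- expand.grid(tau = sweep$tau_axis, P = sweep$P_axis,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(tau = g$tau, P = g$P,
             mean = as.vector(sweep$mean_score),
             sd = as.vector(sweep$sd_score),
             learned_mean = as.vector(sweep$learned_mean))
}

#' Corner-biased multi-start points
#'
#' Four start points placed a fixed fraction into the box from each
#' corner, the standard multi-start layout for the two local solvers.
#'
#' @param lower,upper Length-2 bound vectors.
#' @param frac Fraction of each axis range to move in from the corners.
#'   Default 0.2.
#' @return A list of 4 numeric start vectors.
#' @export
default_starts <- function(lower, upper, frac = 0.2) {
  stopifnot(length(lower) == 2L, length(upper) == 2L, all(upper > lower))
  r <- upper - lower
  lapply(list(c(frac, frac), c(frac, 1 - frac),
              c(1 - frac, frac), c(1 - frac, 1 - frac)),
         function(f) lower + f * r)
}

NLOPT_METHODS <- c(neldermead = "NLOPT_LN_NELDERMEAD",
                   bobyqa = "NLOPT_LN_BOBYQA",
                   esch = "NLOPT_GN_ESCH",
                   crs = "NLOPT_GN_CRS2_LM")

#' Derivative-free and heuristic optimization driver
#'
#' Optimizes a deterministic objective over box bounds with one of four
#' solvers: two local derivative-free methods (`"neldermead"`, a simplex
#' method, and `"bobyqa"`, which builds quadratic models of the
#' objective) and two heuristic global methods (`"esch"`, an evolutionary
#' algorithm, and `"crs"`, controlled random search with local mutation).
#' All four are delegated to the NLopt library via \pkg{nloptr}. Local
#' methods are run from each start point (multi-start); the global
#' methods ignore starts beyond the first and are bounded by an
#' evaluation budget rather than wall-clock time, so runs are
#' hardware-independent.
#'
#' The objective must be a deterministic function of `theta` (evaluate
#' simulated objectives on a frozen replicate batch), otherwise solvers
#' chase noise.
#'
#' @param objective Function of a length-2 numeric `theta`.
#' @param method One of `"neldermead"`, `"bobyqa"`, `"esch"`, `"crs"`.
#' @param lower,upper Box bounds (length 2).
#' @param starts List of start vectors; default [default_starts()].
#' @param maximize If `TRUE` the objective is maximized. Default `FALSE`.
#' @param xtol_rel Relative parameter tolerance used as stopping rule for
#'   the local solvers. Default 0.1.
#' @param maxeval Evaluation budget per start. Default 200 for local
#'   solvers; use a few thousand for the global ones.
#' @return A list of one result per start (a single result for the global
#'   methods), each a list with `theta_hat`, `objective_value` (on the
#'   original, unnegated scale), `n_evaluations`, `trajectory` (matrix of
#'   iterates, one row per evaluation: `tau`, `P`, `value`), `method`,
#'   and `start_point`.
#' @export
run_optimizer <- function(objective, method = c("neldermead", "bobyqa",
                                                "esch", "crs"),
                          lower, upper, starts = default_starts(lower, upper),
                          maximize = FALSE, xtol_rel = 0.1, maxeval = 200L) {
  method <- match.arg(method)
  stopifnot(length(lower) == 2L, length(upper) == 2L)
  for (s in starts) {
    if (any(s < lower) || any(s > upper)) {
      stop("start point (", paste(signif(s, 4), collapse = ", "),
           ") outside bounds")
    }
  }
  if (method %in% c("esch", "crs")) starts <- starts[1L]
  sgn <- if (maximize) -1 else 1

  lapply(starts, function(x0) {
    rec <- new.env(parent = emptyenv())
    rec$tr <- vector("list", 0L)
    f <- function(theta) {
      v <- tryCatch(objective(theta), error = function(e) {
        stop("objective evaluation failed at theta = (",
             paste(signif(theta, 6), collapse = ", "), "): ",
             conditionMessage(e))
      })
      rec$tr[[length(rec$tr) + 1L]] <- c(theta, v)
      sgn * v
    }
    ans <- nloptr::nloptr(
      x0 = x0, eval_f = f, lb = lower, ub = upper,
      opts = list(algorithm = NLOPT_METHODS[[method]],
                  xtol_rel = xtol_rel, maxeval = as.integer(maxeval))
    )
    tr <- do.call(rbind, rec$tr)
    colnames(tr) <- c("tau", "P", "value")
    list(theta_hat = ans$solution,
         objective_value = sgn * ans$objective,
         n_evaluations = nrow(tr),
         trajectory = tr,
         method = method,
         start_point = x0)
  })
}

#' Best result of a multi-start run
#'
#' @param results List returned by [run_optimizer()].
#' @param maximize Must match the `maximize` used in the run.
#' @return The single best result element.
#' @export
best_result <- function(results, maximize = FALSE) {
  vals <- vapply(results, `[[`, numeric(1), "objective_value")
  results[[if (maximize) which.max(vals) else which.min(vals)]]
}

#' End-to-end parameter optimization of the model
#'
#' Convenience driver for the two study tasks: builds a frozen replicate
#' batch from a master seed, forms the requested objective, and runs a
#' solver with multi-start over the standard bounds
#' `tau` in `[-8.5, 1]`, `P` in `[0.5, 35]` (the sweep ranges).
#'
#' @param mode `"fit"` (minimize the RMSD to `R_ref`) or `"performance"`
#'   (maximize `a * mean + b * sd`).
#' @param master_seed Master seed for the frozen batch.
#' @param n Number of replicates. Default 100.
#' @param config An [sim_config()] template; default: 40 rounds,
#'   `p1 = 6`, `d = 0.5`, noise off.
#' @param weights An [objective_weights()] object.
#' @param method Solver, see [run_optimizer()].
#' @param lower,upper Bounds. Defaults to the sweep ranges.
#' @param ... Passed to [run_optimizer()] (`starts`, `xtol_rel`,
#'   `maxeval`).
#' @return A list with `best` (the best [run_optimizer()] result),
#'   `results` (all starts), `mode`, `n`, and `master_seed`.
#' @export
optimize_model <- function(mode = c("fit", "performance"), master_seed,
                           n = 100L,
                           config = sim_config(act_params(tau = 0, P = 10)),
                           weights = objective_weights(),
                           method = "neldermead",
                           lower = c(-8.5, 0.5), upper = c(1, 35), ...) {
  mode <- match.arg(mode)
  batch <- make_batch(master_seed, n, N_r = config$N_r,
                      noise_enabled = config$noise_enabled)
  maximize <- mode == "performance"
  obj <- if (mode == "fit") {
    function(theta) fit_objective(theta, batch, config, weights)
  } else {
    function(theta) performance_objective(theta, batch, config, weights)
  }
  results <- run_optimizer(obj, method = method, lower = lower, upper = upper,
                           maximize = maximize, ...)
  list(best = best_result(results, maximize = maximize), results = results,
       mode = mode, n = as.integer(n), master_seed = as.integer(master_seed))
}
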