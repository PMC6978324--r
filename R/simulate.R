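#' Overdamped Langevin dynamics on the double well
#'
#' Euler-Maruyama integration of `dx = -grad U(x) dt + sqrt(2 kT dt) xi` on
#' the sodium-tilted double well.  The scheme is explicit; `dt` must stay
#' below the stability bound [em_stability_dt()] (the integrator aborts with
#' an explicit error naming `dt` if a position diverges).  Output is
#' bit-reproducible for identical `(spec, sodium_state, n_steps, dt, seed,
#' start)`.
#'
#' @param spec a [potential_spec()].
#' @param sodium_state 0 or 1, the sodium condition of the trajectory.
#' @param n_steps number of integration steps (>= 0).
#' @param dt integration time step, reduced units.
#' @param seed integer seed; one generator per trajectory, recorded in the
#'   output.
#' @param start numeric 2-vector initial position (default: the E well).
#' @return A `latent_trajectory`: list with `positions` ((n_steps + 1) x 2
#'   matrix including the start), `dt`, `seed`, `sodium_state` and
#'   `bias_log` (`NULL`; populated only by [simulate_targeted()]).
#' @export
simulate_overdamped <- function(spec, sodium_state = 0, n_steps = 10000,
                                dt = 1e-3, seed = 1,
                                start = spec$well_E_center) {
  stopifnot(inherits(spec, "potential_spec"), n_steps >= 0, dt > 0,
            length(start) == 2L)
  bound <- em_stability_dt(spec, sodium_state)
  if (dt >= bound)
    stop(sprintf("dt = %g exceeds the Euler-Maruyama stability bound %.3g",
                 dt, bound))
  pos <- if (n_steps == 0L) {
    matrix(as.numeric(start), 1, 2)
  } else {
    withr::with_seed(seed,
      cpp_simulate_overdamped(spec_pars(spec, sodium_state),
                              as.integer(n_steps), dt, spec$temperature,
                              as.numeric(start)))
  }
  latent_trajectory(pos, dt = dt, seed = seed, sodium_state = sodium_state)
}

latent_trajectory <- function(positions, dt, seed, sodium_state,
                              bias_log = NULL) {
  stopifnot(nrow(positions) >= 1L, dt > 0)
  colnames(positions) <- c("z1", "z2")
  structure(list(positions = positions, dt = dt, seed = seed,
                 sodium_state = sodium_state, bias_log = bias_log),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("Latent trajectory: %d frames, dt %g, seed %d, Na+ %d%s\n",
              nrow(x$positions), x$dt, x$seed, x$sodium_state,
              if (!is.null(x$bias_log)) ", targeted (bias log attached)" else ""))
  invisible(x)
}

#' Thin a latent trajectory by a stride
#'
#' @param latent a `latent_trajectory`.
#' @param stride keep every `stride`-th frame (first frame always kept).
#' @return a `latent_trajectory` with `dt` scaled by `stride`.
#' @export
thin_latent <- function(latent, stride) {
  stopifnot(inherits(latent, "latent_trajectory"), stride >= 1)
  keep <- seq(1L, nrow(latent$positions), by = as.integer(stride))
  latent_trajectory(latent$positions[keep, , drop = FALSE],
                    dt = latent$dt * stride, seed = latent$seed,
                    sodium_state = latent$sodium_state)
}

#' Targeted-sampling schedule (ramped deviation target)
#'
#' Mirrors a targeted-MD protocol: the restraint target is lowered linearly
#' from `start_target` to `end_target` over `ramp_steps`, then held constant
#' for `hold_steps`.
#'
#' @param start_target,end_target deviation targets (length units);
#'   `start_target > end_target >= 0`.
#' @param ramp_steps,hold_steps step counts (>= 0; ramp + hold >= 1).
#' @param force_constant harmonic force constant (energy per squared
#'   deviation).
#' @return object of class `targeted_schedule`.
#' @export
targeted_schedule <- function(start_target = 2.3, end_target = 1.0,
                              ramp_steps = 10000, hold_steps = 4000,
                              force_constant = 100) {
  stopifnot(start_target > end_target, end_target >= 0,
            ramp_steps >= 0, hold_steps >= 0, ramp_steps + hold_steps >= 1,
            force_constant >= 0)
  structure(list(start_target = start_target, end_target = end_target,
                 ramp_steps = as.integer(ramp_steps),
                 hold_steps = as.integer(hold_steps),
                 force_constant = force_constant),
            class = "targeted_schedule")
}

#' Per-step target sequence of a schedule
#'
#' @param schedule a [targeted_schedule()].
#' @return numeric vector of length `ramp_steps + hold_steps`: exact linear
#'   ramp from `start_target` to `end_target`, then the held end target.
#' @export
schedule_targets <- function(schedule) {
  stopifnot(inherits(schedule, "targeted_schedule"))
  ramp <- if (schedule$ramp_steps > 0)
    seq(schedule$start_target, schedule$end_target,
        length.out = schedule$ramp_steps)
  else numeric(0)
  c(ramp, rep(schedule$end_target, schedule$hold_steps))
}

#' Targeted (biased) sampling toward a reference point
#'
#' Overdamped Langevin dynamics with a one-sided harmonic restraint
#' `0.5 k (d - target)^2` on the Euclidean deviation `d` of the current
#' position from `reference`, applied only while `d > target`.  The target
#' follows the schedule's linear ramp and hold.  In latent space the
#' deviation is a plain Euclidean distance (the structural, Kabsch-aligned
#' RMSD lives in the featurization module).
#'
#' @inheritParams simulate_overdamped
#' @param reference numeric 2-vector, the target conformation.
#' @param schedule a [targeted_schedule()].
#' @return a `latent_trajectory` whose `bias_log` is a data frame with one
#'   row per step: `target`, `deviation` (at the start of the step) and
#'   `bias_energy`.
#' @export
simulate_targeted <- function(spec, sodium_state = 0, reference, schedule,
                              dt = 1e-3, seed = 1,
                              start = spec$well_E_center) {
  stopifnot(inherits(spec, "potential_spec"), length(reference) == 2L)
  bound <- em_stability_dt(spec, sodium_state)
  if (dt >= bound)
    stop(sprintf("dt = %g exceeds the Euler-Maruyama stability bound %.3g",
                 dt, bound))
  targets <- schedule_targets(schedule)
  res <- withr::with_seed(seed,
    cpp_simulate_targeted(spec_pars(spec, sodium_state), as.numeric(reference),
                          targets, schedule$force_constant, dt,
                          spec$temperature, as.numeric(start)))
  latent_trajectory(res$positions, dt = dt, seed = seed,
                    sodium_state = sodium_state,
                    bias_log = data.frame(target = targets,
                                          deviation = res$deviation,
                                          bias_energy = res$bias_energy))
}

#' Sample a discrete Markov chain
#'
#' Oracle generator for the MSM estimation stage: draws a state sequence from
#' a row-stochastic transition matrix.  States are 1-based.
#'
#' @param T row-stochastic matrix (rows must sum to 1 within 1e-10).
#' @param n_steps number of transitions to sample.
#' @param seed integer seed (deterministic output).
#' @param start_state starting state in `1..nrow(T)`.
#' @return integer vector of `n_steps + 1` states (including the start),
#'   with attribute `lag_unit = 1`.
#' @export
sample_markov_chain <- function(T, n_steps, seed = 1, start_state = 1) {
  T <- as.matrix(T)
  if (nrow(T) != ncol(T)) stop("T must be square")
  if (any(T < 0)) stop("T must be non-negative")
  if (any(abs(rowSums(T) - 1) > 1e-10))
    stop("T is not row-stochastic: rows must sum to 1 within 1e-10")
  if (start_state < 1 || start_state > nrow(T))
    stop(sprintf("start_state %d out of range 1..%d", start_state, nrow(T)))
  states <- withr::with_seed(seed,
    cpp_sample_markov_chain(T, as.integer(n_steps), as.integer(start_state)))
  attr(states, "lag_unit") <- 1
  states
}
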