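# Pulling-direction optimization: candidate directions are parameterized by
# nutation/precession angles (theta, phi) about the initial direction n0,
# each candidate is scored by the windowed average pulling force of a short
# trial segment restarted from a checkpoint (common random numbers across
# candidates), and the (t0, f0) trigger decides when to re-optimize.

#' Controller configuration for pulling runs
#'
#' Defaults follow the standard constant-velocity SMD protocol: spring
#' constant 200 kJ/mol/nm^2, pulling speed 0.002 nm/ps, 1-ps force windows,
#' optimization trigger t0 = 5 ps and f0 = 250 pN, and a 0.6 nm separation
#' cut-off ending the dissociation.
#'
#' @param k spring constant, kJ/mol/nm^2.
#' @param v pulling speed, nm/ps.
#' @param t0 minimal time between direction optimizations, ps.
#' @param f0_pN minimal trailing-window average force for triggering an
#'   optimization, pN (stored internally in kJ/mol/nm as `f0`). `Inf`
#'   disables optimization entirely.
#' @param window force-averaging window T, ps.
#' @param cutoff_separation separation ending the run, nm.
#' @param max_time wall guard, ps; runs that last this long without
#'   unbinding are flagged.
#' @param n0 initial pulling direction, unit 3-vector.
#' @param equil_time unrestrained equilibration before pulling, ps.
#' @param engine an [engine_params()].
#' @param recenter if `TRUE`, candidate angles are measured about the
#'   *current* pulling direction at each optimization instead of the fixed
#'   initial one (the literal fixed-n0 hemisphere is the default).
#' @param traj_stride record the ligand position every this many steps
#'   (0 disables trajectory recording).
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(k = 200, v = 0.002, t0 = 5, f0_pN = 250,
                              window = 1, cutoff_separation = 0.6,
                              max_time = 1e4, n0 = c(0, 0, 1),
                              equil_time = 100, engine = engine_params(),
                              recenter = FALSE, traj_stride = 50L) {
  .assert_scalar(t0, "t0", positive = TRUE)
  if (!(length(f0_pN) == 1L && (is.infinite(f0_pN) || f0_pN >= 0)))
    stop("f0_pN must be >= 0 (Inf disables optimization)", call. = FALSE)
  .assert_scalar(window, "window", positive = TRUE)
  .assert_unit(n0, "n0")
  structure(list(k = k, v = v, t0 = t0, f0 = force_from_pn(f0_pN),
                 f0_pN = f0_pN, window = window,
                 cutoff_separation = cutoff_separation, max_time = max_time,
                 n0 = n0 / sqrt(sum(n0^2)), equil_time = equil_time,
                 engine = engine, recenter = isTRUE(recenter),
                 traj_stride = as.integer(traj_stride)),
            class = "controller_config")
}

#' Pulling direction from nutation/precession angles
#'
#' Returns the unit vector at nutation angle `theta` (in `[0, pi/2]`, so all
#' candidates stay in the hemisphere of `n0`) and precession angle `phi`
#' (in `[-pi, pi]`) about the axis `n0`. The phi = 0 reference axis is the
#' component of the world x-axis orthogonal to `n0` (the y-axis if `n0` is
#' parallel to x), which makes runs reproducible.
#'
#' @param theta nutation angle, rad, in `[0, pi/2]`.
#' @param phi precession angle, rad, in `[-pi, pi]`.
#' @param n0 axis, unit 3-vector.
#' @return unit 3-vector with `dot(result, n0) = cos(theta)`.
#' @export
direction_from_angles <- function(theta, phi, n0) {
  if (!is.finite(theta) || theta < -1e-12 || theta > pi / 2 + 1e-12)
    stop("theta out of [0, pi/2]", call. = FALSE)
  if (!is.finite(phi) || phi < -pi - 1e-12 || phi > pi + 1e-12)
    stop("phi out of [-pi, pi]", call. = FALSE)
  .assert_unit(n0, "n0")
  n0 <- n0 / sqrt(sum(n0^2))
  ref <- c(1, 0, 0)
  if (abs(sum(ref * n0)) > 1 - 1e-8) ref <- c(0, 1, 0)
  e1 <- ref - sum(ref * n0) * n0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n0[2] * e1[3] - n0[3] * e1[2],
          n0[3] * e1[1] - n0[1] * e1[3],
          n0[1] * e1[2] - n0[2] * e1[1])
  cos(theta) * n0 + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
}

#' Should a direction optimization run now?
#'
#' True iff the time since the last optimization strictly exceeds `t0` and
#' the average pulling force over the trailing window exceeds `f0`.
#'
#' @param t current time, ps.
#' @param t_last_opt time of the last optimization (or pull start), ps.
#' @param f_recent trailing-window average pulling force, kJ/mol/nm.
#' @param cfg a [controller_config()].
#' @return logical.
#' @export
should_optimize <- function(t, t_last_opt, f_recent, cfg) {
  stopifnot(t >= t_last_opt)
  (t - t_last_opt) > cfg$t0 && f_recent > cfg$f0
}

#' Trial average force of a candidate pulling direction
#'
#' Restores the snapshot (including its RNG stream, so all candidates see
#' identical noise -- common random numbers), switches the pulling direction
#' to the candidate, simulates one window of length `cfg$window`, and
#' returns the mean scalar pulling force. The caller's live state and RNG
#' stream are untouched.
#'
#' @param snap a [checkpoint()] snapshot taken at the optimization time.
#' @param theta,phi candidate angles (see [direction_from_angles()]).
#' @param pull the [pull_spec()] active at the snapshot.
#' @param cfg a [controller_config()].
#' @param l the landscape.
#' @param axis axis the angles are measured about (defaults to `cfg$n0`).
#' @return mean pulling force over the trial window, kJ/mol/nm.
#' @export
trial_average_force <- function(snap, theta, phi, pull, cfg, l,
                                axis = cfg$n0) {
  n_new <- direction_from_angles(theta, phi, axis)
  s <- restore(snap)
  p2 <- switch_direction(pull, n_new, s)
  n_steps <- as.integer(round(cfg$window / cfg$engine$dt))
  res <- .run_segment(s, l, p2, cfg$engine, max_steps = n_steps)
  mean(res$forces)
}

#' Optimize the pulling direction from a checkpoint
#'
#' Minimizes the trial average pulling force over the angle box
#' `[-pi, pi] x [0, pi/2]` with the multi-population entropy GA
#' ([evolve()]); the fitness of a candidate is [trial_average_force()].
#'
#' @param snap snapshot at the optimization time.
#' @param pull active [pull_spec()].
#' @param cfg a [controller_config()].
#' @param ga_cfg a [ga_config()]; `NULL` uses [sasmd_ga_defaults()].
#' @param l the landscape.
#' @return list with `direction` (unit 3-vector), `angles`
#'   (`c(phi, theta)`), and `record`: an optimization record with `t_opt`,
#'   `theta`, `phi`, `objective_value` (the trial force of the chosen
#'   direction, kJ/mol/nm), `n_evaluations`, `ga_history`, `converged`.
#' @export
optimize_direction <- function(snap, pull, cfg, ga_cfg = NULL, l) {
  if (is.null(ga_cfg)) ga_cfg <- sasmd_ga_defaults()
  axis <- if (cfg$recenter) pull$n else cfg$n0
  fitness <- function(x) {
    trial_average_force(snap, theta = x[2], phi = x[1], pull, cfg, l,
                        axis = axis)
  }
  bounds <- rbind(c(-pi, 0), c(pi, pi / 2))
  res <- evolve(fitness, bounds, ga_cfg)
  dir <- direction_from_angles(res$best_x[2], res$best_x[1], axis)
  list(direction = dir, angles = res$best_x,
       record = list(t_opt = snap$t, phi = res$best_x[1],
                     theta = res$best_x[2],
                     objective_value = res$best_f,
                     objective_pN = force_to_pn(res$best_f),
                     n_evaluations = res$n_evaluations,
                     ga_history = res$history,
                     converged = res$converged))
}

#' Default GA settings for in-run direction optimization
#'
#' A deliberately small budget (16 populations x 4 individuals x 3
#' generations = 192 trial segments per optimization) so that one
#' optimization costs well under 200 short trial simulations; the standalone
#' [ga_config()] defaults are larger and meant for general objectives.
#'
#' @return a [ga_config()].
#' @export
sasmd_ga_defaults <- function() {
  ga_config(m = 16L, pop_size = 4L, n_generations = 3L,
            mutation_rate = 0.25, early_stop_window = 5L)
}

#' Self-adaptive SMD run
#'
#' Equilibrates, then pulls with the harmonic spring while monitoring the
#' trailing 1-ps average force; whenever the (t0, f0) trigger fires, the run
#' is checkpointed, the pulling direction re-optimized by the entropy GA
#' (trial segments restart from the checkpoint with common random numbers),
#' and the main trajectory re-simulated from the checkpoint with the
#' adopted direction (trial segments are never reused). Terminates when the
#' ligand separation exceeds the cut-off or `max_time` elapses.
#'
#' With `f0_pN = Inf` the trigger never fires and the run is bit-identical
#' to [run_csmd()] at the same seed.
#'
#' @inheritParams run_csmd
#' @param ga_cfg GA settings for each direction optimization
#'   (default [sasmd_ga_defaults()]).
#' @return a `rupture_result` (see [run_csmd()]) whose `records` field holds
#'   one optimization record per direction switch.
#' @export
run_sasmd <- function(l, cfg = controller_config(), ga_cfg = NULL,
                      seed = 1L) {
  if (is.null(ga_cfg)) ga_cfg <- sasmd_ga_defaults()
  .run_pull(l, cfg, seed, optimize = TRUE, ga_cfg = ga_cfg)
}

#' Write the per-run optimization log CSV
#'
#' Columns: `t_opt_ps`, `theta_rad`, `phi_rad`, `objective_pN`, `n_evals`.
#'
#' @param result a `rupture_result` from [run_sasmd()].
#' @param path output path.
#' @export
write_optimization_log <- function(result, path) {
  recs <- result$records
  df <- data.frame(
    t_opt_ps = vapply(recs, `[[`, 0, "t_opt"),
    theta_rad = vapply(recs, `[[`, 0, "theta"),
    phi_rad = vapply(recs, `[[`, 0, "phi"),
    objective_pN = vapply(recs, `[[`, 0, "objective_pN"),
    n_evals = vapply(recs, `[[`, 0, "n_evaluations"))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
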