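# Overdamped Langevin propagation with exact checkpoint/restore.
#
# The simulation state carries its own RNG stream (a saved `.Random.seed`),
# so a state object IS a complete restart point: candidate pulling directions
# can be evaluated from identical starting conditions, including identical
# noise realizations (common random numbers).

#' Engine parameters for the overdamped Langevin integrator
#'
#' The update is Euler-Maruyama:
#' `dr = (f_total / friction) dt + sqrt(2 kB T dt / friction) xi`,
#' with `xi` standard normal per axis and `f_total` the landscape force plus
#' any external (steering) force. The default friction of 100 kJ/mol/nm^2/ps
#' makes the ligand's diffusive relaxation time in the standard well
#' (`friction / well curvature` = 100/800 ps ~ 0.13 ps) much shorter than
#' the 5 ps optimization interval, so windowed forces probe the landscape
#' rather than the integrator.
#'
#' @param dt time step, ps (default 0.002 = 2 fs).
#' @param friction drag coefficient gamma, kJ/mol/nm^2/ps.
#' @param temperature kelvin; 0 gives deterministic gradient descent.
#' @return an object of class `engine_params`.
#' @export
engine_params <- function(dt = 0.002, friction = 100, temperature = 300) {
  .assert_scalar(dt, "dt", positive = TRUE)
  .assert_scalar(friction, "friction", positive = TRUE)
  .assert_scalar(temperature, "temperature", nonneg = TRUE)
  structure(list(dt = dt, friction = friction, temperature = temperature),
            class = "engine_params")
}

#' Create a simulation state
#'
#' @param r ligand position, 3-vector nm.
#' @param t simulation time, ps.
#' @param seed optional integer: if given, the state's RNG stream is
#'   initialized from `set.seed(seed)`; otherwise the current global stream
#'   is captured. The caller-visible global RNG is left untouched.
#' @return an object of class `sim_state` with fields `r`, `t`, `rng_state`.
#' @export
sim_state <- function(r, t = 0, seed = NULL) {
  stopifnot(length(r) == 3L, all(is.finite(r)))
  rng <- .with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    .get_rng_state()
  })
  structure(list(r = as.numeric(r), t = as.numeric(t), rng_state = rng),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state: t = %.3f ps, r = (%.4f, %.4f, %.4f) nm>\n",
              x$t, x$r[1], x$r[2], x$r[3]))
  invisible(x)
}

#' Advance the state by one Euler-Maruyama step
#'
#' @param s a [sim_state()].
#' @param l a `sasmd_landscape`.
#' @param f_ext constant external force over the step, 3-vector kJ/mol/nm.
#' @param p [engine_params()].
#' @return the updated `sim_state`.
#' @export
step_sim <- function(s, l, f_ext = c(0, 0, 0), p = engine_params()) {
  stopifnot(inherits(s, "sim_state"), inherits(l, "sasmd_landscape"))
  if (length(f_ext) != 3L || !all(is.finite(f_ext)))
    stop("f_ext must be a finite 3-vector", call. = FALSE)
  .with_preserved_rng({
    .set_rng_state(s$rng_state)
    res <- cpp_step(l$descriptor, s$r, s$t, as.numeric(f_ext),
                    p$dt, p$friction, p$temperature)
    s$r <- res$r
    s$t <- res$t
    s$rng_state <- .get_rng_state()
  })
  s
}

# Core segment runner shared by equilibration, C-SMD and SA-SMD drivers and
# by trial force evaluations. `pull` may be NULL (free dynamics).
.run_segment <- function(s, l, pull, p, max_steps, cutoff_sep = -1,
                         trigger = NULL, traj_stride = 0L) {
  pv <- if (is.null(pull)) c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0)
        else c(pull$k, pull$v, pull$n, pull$r_ref, pull$t_start, pull$x_offset)
  trig_on <- !is.null(trigger)
  res <- NULL
  .with_preserved_rng({
    .set_rng_state(s$rng_state)
    res <- cpp_run_segment(l$descriptor, s$r, s$t, pv,
                           p$dt, p$friction, p$temperature,
                           as.integer(max_steps), cutoff_sep,
                           trig_on,
                           if (trig_on) trigger$t_last_opt else 0,
                           if (trig_on) trigger$t0 else 0,
                           if (trig_on) trigger$f0 else Inf,
                           if (trig_on) as.integer(trigger$window_w) else 1L,
                           as.integer(traj_stride))
    s$r <- res$r
    s$t <- res$t
    s$rng_state <- .get_rng_state()
  })
  list(state = s, forces = res$forces, n_steps = res$n_steps,
       exit = c("max_steps", "cutoff", "trigger")[res$exit + 1L],
       traj = if (traj_stride > 0 && length(res$traj_t) > 0) res$traj else NULL,
       traj_t = if (traj_stride > 0) res$traj_t else NULL)
}

#' Checkpoint a simulation state
#'
#' Returns a deep, immutable copy of the state including its RNG stream.
#' (R's copy-on-modify semantics make the returned object independent of any
#' further stepping of `s`.)
#'
#' @param s a [sim_state()].
#' @return an object of class `sasmd_snapshot`.
#' @export
checkpoint <- function(s) {
  stopifnot(inherits(s, "sim_state"))
  snap <- unclass(s)
  class(snap) <- c("sasmd_snapshot", "sim_state")
  snap
}

#' Restore a simulation state from a snapshot
#'
#' @param snap a snapshot from [checkpoint()] (or read back from disk).
#' @return a `sim_state` identical in all fields to the checkpointed one;
#'   stepping it reproduces the original trajectory bit-exactly.
#' @export
restore <- function(snap) {
  if (!inherits(snap, "sasmd_snapshot") ||
      is.null(snap$r) || is.null(snap$t) || is.null(snap$rng_state) ||
      length(snap$r) != 3L || !all(is.finite(snap$r)))
    stop("corrupted snapshot", call. = FALSE)
  structure(list(r = snap$r, t = snap$t, rng_state = snap$rng_state),
            class = "sim_state")
}

#' Write / read a snapshot to disk
#'
#' @param snap a `sasmd_snapshot`.
#' @param path file path.
#' @return `snapshot_read()` returns the snapshot.
#' @export
snapshot_write <- function(snap, path) {
  stopifnot(inherits(snap, "sasmd_snapshot"))
  saveRDS(snap, path)
  invisible(path)
}

#' @rdname snapshot_write
#' @export
snapshot_read <- function(path) {
  snap <- readRDS(path)
  if (!inherits(snap, "sasmd_snapshot")) stop("corrupted snapshot", call. = FALSE)
  snap
}

#' Unrestrained equilibration
#'
#' Propagates the state for `duration` ps with no external force, the
#' analogue of the unrestrained equilibration run preceding a pulling
#' simulation.
#'
#' @param s a [sim_state()].
#' @param l a `sasmd_landscape`.
#' @param duration ps (>= 0).
#' @param p [engine_params()].
#' @param record_stride if > 0, record the position every `record_stride`
#'   steps; the samples are attached as attribute `"traj"` (matrix) and
#'   `"traj_t"` (times).
#' @return the equilibrated `sim_state`.
#' @export
equilibrate <- function(s, l, duration, p = engine_params(),
                        record_stride = 0L) {
  .assert_scalar(duration, "duration", nonneg = TRUE)
  n <- round(duration / p$dt)
  if (n == 0) return(s)
  # chunk long runs (bounded per-call allocations); chunks are a multiple of
  # the recording stride so sampling stays uniform
  chunk <- 1000000L
  if (record_stride > 0) chunk <- max(record_stride * (chunk %/% record_stride),
                                      record_stride)
  traj <- list(); traj_t <- list()
  left <- n
  while (left > 0) {
    res <- .run_segment(s, l, pull = NULL, p, max_steps = min(left, chunk),
                        traj_stride = record_stride)
    s <- res$state
    if (record_stride > 0 && !is.null(res$traj)) {
      traj[[length(traj) + 1L]] <- res$traj
      traj_t[[length(traj_t) + 1L]] <- res$traj_t
    }
    left <- left - min(left, chunk)
  }
  if (record_stride > 0) {
    attr(s, "traj") <- do.call(rbind, traj)
    attr(s, "traj_t") <- unlist(traj_t)
  }
  s
}
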