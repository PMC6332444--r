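# Constant-velocity harmonic steering (the moving-spring SMD potential),
# windowed force averaging, rupture-force extraction and the conventional
# fixed-direction (C-SMD) driver.
#
# The steering potential is U = k/2 * [v t - (R(t) - R(0)) . n]^2; the scalar
# pulling force logged every step is the signed projection k*x along the
# current direction n (negative if the ligand overtakes the constraint
# point). Across direction switches the accumulated spring extension is
# carried in `x_offset` so the force magnitude is continuous.

#' Harmonic steering specification
#'
#' @param k spring constant, kJ/mol/nm^2 (default 200).
#' @param v pulling speed, nm/ps (default 0.002).
#' @param n pulling direction, unit 3-vector.
#' @param r_ref reference ligand position at the start of this pulling
#'   segment, nm.
#' @param t_start segment-local time origin for the `v*t` term, ps.
#' @param x_offset spring extension carried over from previous segments, nm.
#' @return an object of class `pull_spec`.
#' @export
pull_spec <- function(k = 200, v = 0.002, n = c(0, 0, 1),
                      r_ref = c(0, 0, 0), t_start = 0, x_offset = 0) {
  .assert_scalar(k, "k", positive = TRUE)
  .assert_scalar(v, "v", nonneg = TRUE)
  .assert_unit(n, "n", tol = 1e-12)
  stopifnot(length(r_ref) == 3L, all(is.finite(r_ref)))
  structure(list(k = k, v = v, n = as.numeric(n), r_ref = as.numeric(r_ref),
                 t_start = t_start, x_offset = x_offset),
            class = "pull_spec")
}

# current spring extension (nm) of spec p at state s
.extension <- function(p, s) {
  p$v * (s$t - p$t_start) + p$x_offset - sum((s$r - p$r_ref) * p$n)
}

#' Instantaneous steering force
#'
#' Returns `k * x * n` where
#' `x = v (t - t_start) + x_offset - (r - r_ref) . n` is the spring
#' extension. The force may point against `n` if the ligand has overtaken
#' the constraint point.
#'
#' @param p a [pull_spec()].
#' @param s a [sim_state()].
#' @return 3-vector force, kJ/mol/nm.
#' @export
steering_force <- function(p, s) {
  stopifnot(inherits(p, "pull_spec"), inherits(s, "sim_state"))
  p$k * .extension(p, s) * p$n
}

#' Switch the pulling direction with force continuity
#'
#' Starts a new pulling segment along `n_new` from the current state: the
#' reference position and time origin are reset to the current ones and the
#' accumulated extension under the old spec is carried into `x_offset`, so
#' the steering-force magnitude is continuous across the switch.
#'
#' @param p the current [pull_spec()].
#' @param n_new new unit pulling direction.
#' @param s the [sim_state()] at the switch instant.
#' @return a new `pull_spec`.
#' @export
switch_direction <- function(p, n_new, s) {
  .assert_unit(n_new, "n_new", tol = 1e-9)
  pull_spec(k = p$k, v = p$v, n = n_new / sqrt(sum(n_new^2)), r_ref = s$r,
            t_start = s$t, x_offset = .extension(p, s))
}

#' Windowed average force profile
#'
#' Partitions uniformly spaced scalar force samples into consecutive
#' non-overlapping windows of length `window` ps and averages within each; a
#' trailing partial window is dropped. The window midpoint times are reported
#' relative to the first sample's segment.
#'
#' @param times sample times, ps (uniformly spaced).
#' @param forces scalar pulling-force samples (projection on the current
#'   pulling direction), kJ/mol/nm.
#' @param window window length T, ps; must be an integer multiple of the
#'   sample spacing (default 1 ps).
#' @return an object of class `force_profile`: a data frame with columns
#'   `t_mid` (ps) and `f_avg` (kJ/mol/nm), with the window length stored in
#'   attribute `"window"`.
#' @export
windowed_average <- function(times, forces, window = 1) {
  stopifnot(length(times) == length(forces))
  if (length(times) < 2L) {
    prof <- data.frame(t_mid = numeric(0), f_avg = numeric(0))
    attr(prof, "window") <- window
    class(prof) <- c("force_profile", "data.frame")
    return(prof)
  }
  dt <- times[2] - times[1]
  w <- window / dt
  if (w < 1 - 1e-9)
    stop("window smaller than the sample interval", call. = FALSE)
  if (abs(w - round(w)) > 1e-6)
    stop("window must be an integer multiple of the sample interval",
         call. = FALSE)
  w <- as.integer(round(w))
  n_win <- length(forces) %/% w
  if (n_win == 0L) {
    prof <- data.frame(t_mid = numeric(0), f_avg = numeric(0))
  } else {
    used <- forces[seq_len(n_win * w)]
    f_avg <- colMeans(matrix(used, nrow = w))
    t0 <- times[1]
    t_mid <- t0 + (seq_len(n_win) - 0.5) * window - dt / 2
    prof <- data.frame(t_mid = t_mid, f_avg = f_avg)
  }
  attr(prof, "window") <- window
  class(prof) <- c("force_profile", "data.frame")
  prof
}

# concatenate per-segment profiles (t_mid strictly increasing by construction)
.bind_profiles <- function(profiles, window) {
  keep <- profiles[vapply(profiles, nrow, 0L) > 0L]
  prof <- if (length(keep)) do.call(rbind, lapply(keep, as.data.frame))
          else data.frame(t_mid = numeric(0), f_avg = numeric(0))
  attr(prof, "window") <- window
  class(prof) <- c("force_profile", "data.frame")
  prof
}

#' Rupture force of a force profile
#'
#' The rupture force is the maximum windowed time-averaged pulling force
#' encountered during the run; ties are broken by the earliest window.
#'
#' @param fp a [windowed_average()] profile.
#' @return `list(force, time)`: the maximum `f_avg` (kJ/mol/nm) and its
#'   window midpoint time (ps).
#' @export
rupture_force <- function(fp) {
  if (!nrow(fp)) stop("empty force profile", call. = FALSE)
  i <- which.max(fp$f_avg)
  list(force = fp$f_avg[i], time = fp$t_mid[i])
}

#' Write a force profile CSV
#'
#' Columns `t_mid_ps`, `f_avg_kJ_mol_nm`, `f_avg_pN`.
#'
#' @param fp a force profile.
#' @param path output path.
#' @export
write_force_profile <- function(fp, path) {
  df <- data.frame(t_mid_ps = fp$t_mid, f_avg_kJ_mol_nm = fp$f_avg,
                   f_avg_pN = force_to_pn(fp$f_avg))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# Shared pulling driver for C-SMD (optimize = FALSE) and SA-SMD
# (optimize = TRUE). When the trigger never fires the two modes consume the
# RNG stream identically, so SA-SMD with f0 = Inf is bit-identical to C-SMD.
.run_pull <- function(l, cfg, seed, optimize = FALSE, ga_cfg = NULL,
                      chunk_steps = 500000L) {
  stopifnot(inherits(l, "sasmd_landscape"), inherits(cfg, "controller_config"))
  p <- cfg$engine
  .with_preserved_rng(.run_pull_impl(l, cfg, seed, optimize, ga_cfg,
                                     chunk_steps, p))
}

.run_pull_impl <- function(l, cfg, seed, optimize, ga_cfg, chunk_steps, p) {
  # the simulation stream lives in the state; the ambient stream (used by
  # the GA's genetic operators) is seeded from the same run seed and then
  # decoupled by one draw
  set.seed(seed)
  state <- sim_state(r = l$center, t = 0, seed = NULL)
  invisible(runif(1))
  state <- equilibrate(state, l, cfg$equil_time, p)

  pull <- pull_spec(k = cfg$k, v = cfg$v, n = cfg$n0, r_ref = state$r,
                    t_start = state$t)
  window_w <- as.integer(round(cfg$window / p$dt))
  t_last_opt <- state$t
  t_end_max <- state$t + cfg$max_time

  seg_times <- list(); seg_forces <- list(); profiles <- list()
  traj <- list(); traj_t <- list()
  records <- list()
  n_switch <- 0L
  unbound <- FALSE
  seg_t0 <- state$t
  cur_times <- list(); cur_forces <- list()

  finish_segment <- function() {
    tt <- unlist(cur_times); ff <- unlist(cur_forces)
    if (length(tt) >= window_w)
      profiles[[length(profiles) + 1L]] <<- windowed_average(tt, ff, cfg$window)
  }

  repeat {
    remaining <- as.integer(round((t_end_max - state$t) / p$dt))
    if (remaining <= 0L) break
    res <- .run_segment(state, l, pull, p,
                        max_steps = min(remaining, chunk_steps),
                        cutoff_sep = cfg$cutoff_separation,
                        trigger = if (optimize)
                          list(t_last_opt = t_last_opt, t0 = cfg$t0,
                               f0 = cfg$f0, window_w = window_w),
                        traj_stride = cfg$traj_stride)
    if (res$n_steps > 0) {
      cur_times[[length(cur_times) + 1L]] <-
        state$t + seq_len(res$n_steps) * p$dt - p$dt
      cur_forces[[length(cur_forces) + 1L]] <- res$forces
      if (!is.null(res$traj)) {
        traj[[length(traj) + 1L]] <- res$traj
        traj_t[[length(traj_t) + 1L]] <- res$traj_t
      }
    }
    state <- res$state
    if (res$exit == "cutoff") { unbound <- TRUE; break }
    if (res$exit == "max_steps") next  # chunk boundary or true max_time
    # trigger fired: optimize the pulling direction from a checkpoint
    finish_segment()
    f_recent <- mean(utils::tail(unlist(cur_forces), window_w))
    cur_times <- list(); cur_forces <- list()
    snap <- checkpoint(state)
    opt <- optimize_direction(snap, pull, cfg, ga_cfg, l)
    opt$record$f_recent <- f_recent
    records[[length(records) + 1L]] <- opt$record
    state <- restore(snap)
    pull <- switch_direction(pull, opt$direction, state)
    n_switch <- n_switch + 1L
    t_last_opt <- state$t
  }
  finish_segment()

  profile <- .bind_profiles(profiles, cfg$window)
  rup <- if (nrow(profile)) rupture_force(profile)
         else list(force = NA_real_, time = NA_real_)
  structure(list(
    rupture_force = rup$force,
    rupture_force_pN = force_to_pn(rup$force),
    rupture_time = rup$time,
    end_time = state$t,
    n_direction_switches = n_switch,
    unbound = unbound,
    profile = profile,
    records = records,
    trajectory = if (length(traj)) do.call(rbind, traj) else NULL,
    trajectory_t = if (length(traj_t)) unlist(traj_t) else NULL,
    mode = if (optimize) "sasmd" else "csmd",
    seed = seed,
    final_state = state
  ), class = "rupture_result")
}

#' Conventional fixed-direction SMD run
#'
#' Equilibrates, then pulls along the fixed initial direction `cfg$n0` until
#' the ligand separation exceeds the cut-off distance or `max_time` elapses
#' (in which case the result is flagged as not unbound). No direction
#' optimizations are executed.
#'
#' @param l a `sasmd_landscape`.
#' @param cfg a [controller_config()].
#' @param seed integer seed; fixed seed gives a bit-identical result.
#' @return an object of class `rupture_result` with fields `rupture_force`
#'   (kJ/mol/nm), `rupture_force_pN`, `rupture_time`, `end_time`,
#'   `n_direction_switches` (0 here), `unbound`, `profile`, `trajectory`.
#' @export
run_csmd <- function(l, cfg = controller_config(), seed = 1L) {
  .run_pull(l, cfg, seed, optimize = FALSE)
}

#' @export
print.rupture_result <- function(x, ...) {
  cat(sprintf("<rupture_result: %s, seed %d>\n", x$mode, x$seed))
  cat(sprintf("  rupture force: %.1f kJ/mol/nm (%.1f pN) at t = %.1f ps\n",
              x$rupture_force, x$rupture_force_pN, x$rupture_time))
  cat(sprintf("  end time: %.1f ps, switches: %d, unbound: %s\n",
              x$end_time, x$n_direction_switches, x$unbound))
  invisible(x)
}
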