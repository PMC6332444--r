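# Experiment orchestration: cut-off-force and pulling-rate sweeps, paired
# C-SMD/SA-SMD comparisons, family runs and rupture-force vs binding-energy
# correlation analysis.

#' Specify a one-variable sweep
#'
#' @param variable `"cutoff_force"` (values in pN) or `"pulling_rate"`
#'   (values in nm/ps).
#' @param values ordered vector of at least two values.
#' @param n_seeds independent runs per value.
#' @param base_config the [controller_config()] every run starts from.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(variable = c("cutoff_force", "pulling_rate"),
                       values, n_seeds = 5L,
                       base_config = controller_config()) {
  variable <- match.arg(variable)
  if (length(values) < 2L) stop("need >= 2 sweep values", call. = FALSE)
  if (n_seeds < 1L) stop("n_seeds must be >= 1", call. = FALSE)
  structure(list(variable = variable, values = as.numeric(values),
                 n_seeds = as.integer(n_seeds), base_config = base_config),
            class = "sweep_spec")
}

#' Run a parameter sweep of SA-SMD simulations
#'
#' For every value x seed combination one SA-SMD run is executed; a sweep of
#' the cut-off force also includes C-SMD reference rows (one per seed),
#' labelled with value `Inf` -- the conventional-SMD limit of an infinite
#' trigger force.
#'
#' @param spec a [sweep_spec()].
#' @param l the landscape.
#' @param ga_cfg GA settings (default [sasmd_ga_defaults()]).
#' @param seeds seeds to use (default `seq_len(spec$n_seeds)`).
#' @return data frame with columns `value`, `seed`, `rupture_force_pN`,
#'   `n_switches`, `end_time_ps`, `unbound`, `failed`.
#' @export
run_sweep <- function(spec, l, ga_cfg = NULL, seeds = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (is.null(seeds)) seeds <- seq_len(spec$n_seeds)
  values <- spec$values
  if (spec$variable == "cutoff_force") values <- c(values, Inf)
  rows <- list()
  for (val in values) {
    cfg <- spec$base_config
    if (spec$variable == "cutoff_force") {
      cfg$f0_pN <- val
      cfg$f0 <- force_from_pn(val)
    } else {
      cfg$v <- val
    }
    for (s in seeds) {
      row <- tryCatch({
        res <- if (is.infinite(cfg$f0)) run_csmd(l, cfg, seed = s)
               else run_sasmd(l, cfg, ga_cfg, seed = s)
        data.frame(value = val, seed = s,
                   rupture_force_pN = res$rupture_force_pN,
                   n_switches = res$n_direction_switches,
                   end_time_ps = res$end_time, unbound = res$unbound,
                   failed = FALSE)
      }, error = function(e) {
        warning("sweep run failed (value = ", val, ", seed = ", s, "): ",
                conditionMessage(e), call. = FALSE)
        data.frame(value = val, seed = s, rupture_force_pN = NA_real_,
                   n_switches = NA_integer_, end_time_ps = NA_real_,
                   unbound = NA, failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Run a landscape family with repeated SA-SMD simulations
#'
#' Executes `n_repeats` independent SA-SMD runs per family member and
#' summarizes the rupture forces. The standard error is the sample standard
#' deviation (n - 1 denominator) divided by `sqrt(n)`; it is reported as
#' `NA` for a single repeat.
#'
#' Complexes of very different binding strength have very different force
#' scales, so a single absolute trigger force would either never fire for the
#' weak binders or pin the strong ones; the trigger is therefore calibrated
#' per member when `f0_fraction` is given: one conventional (C-SMD) run per
#' member measures its fixed-direction rupture force and the optimization
#' trigger is set to that fraction of it. This mirrors the practice of tuning
#' the cut-off force on a reference complex before a family study.
#'
#' @param fam a family from [make_family()].
#' @param cfg a [controller_config()].
#' @param ga_cfg GA settings.
#' @param n_repeats independent simulations per member (>= 1).
#' @param seeds vector of `n_repeats` seeds (default `1:n_repeats`);
#'   every member uses the same seed list offset by its index so members are
#'   independent but the whole experiment is reproducible.
#' @param f0_fraction if non-`NULL`, set each member's trigger force to
#'   `f0_fraction` times its C-SMD rupture force (measured by one
#'   calibration run per member); `NULL` uses `cfg$f0_pN` as-is.
#' @param calibration_seed seed base for the calibration runs.
#' @return an object of class `family_run_result`: a data frame with columns
#'   `member_id`, `well_depth`, `reference_energy`, `mean_rupture_force_pN`,
#'   `std_error_pN`, `n_runs`, `failed` (and `csmd_rupture_force_pN`,
#'   `f0_pN` when calibration is used).
#' @export
run_family <- function(fam, cfg = controller_config(), ga_cfg = NULL,
                       n_repeats = 4L, seeds = NULL, f0_fraction = NULL,
                       calibration_seed = 900L) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)
  rows <- lapply(seq_along(fam), function(i) {
    member <- fam[[i]]
    cfg_i <- cfg
    csmd_rup <- NA_real_
    if (!is.null(f0_fraction)) {
      cs <- run_csmd(member$landscape, cfg, seed = calibration_seed + i)
      csmd_rup <- cs$rupture_force_pN
      cfg_i$f0_pN <- f0_fraction * csmd_rup
      cfg_i$f0 <- force_from_pn(cfg_i$f0_pN)
    }
    forces <- rep(NA_real_, n_repeats)
    for (rp in seq_len(n_repeats)) {
      forces[rp] <- tryCatch(
        run_sasmd(member$landscape, cfg_i, ga_cfg,
                  seed = seeds[rp] + 1000L * i)$rupture_force_pN,
        error = function(e) {
          warning("family run failed (member ", member$member_id,
                  ", repeat ", rp, "): ", conditionMessage(e), call. = FALSE)
          NA_real_
        })
    }
    ok <- is.finite(forces)
    data.frame(member_id = member$member_id,
               well_depth = member$well_depth,
               reference_energy = member$reference_energy,
               mean_rupture_force_pN = if (any(ok)) mean(forces[ok]) else NA_real_,
               std_error_pN = if (sum(ok) >= 2L)
                 sd(forces[ok]) / sqrt(sum(ok)) else NA_real_,
               n_runs = sum(ok), failed = !all(ok),
               csmd_rupture_force_pN = csmd_rup,
               f0_pN = cfg_i$f0_pN)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("family_run_result", "data.frame")
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with >= 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  cor(x, y, method = "pearson")
}

#' Correlate family rupture forces with reference binding energies
#'
#' Computes the Pearson correlation between the mean rupture force and the
#' reference binding energy across a family, plus the least-squares line.
#' Reference energies are negative (more negative = stronger binding), so a
#' method that ranks affinity correctly shows a *negative* slope: deeper
#' wells give larger rupture forces.
#'
#' @param fr a [run_family()] result with >= 3 members.
#' @return an object of class `correlation_report`: list with `r`, `slope`
#'   (pN per kJ/mol), `intercept`, `n`, and the underlying `table`.
#' @export
correlation_report <- function(fr) {
  tab <- fr[is.finite(fr$mean_rupture_force_pN), , drop = FALSE]
  if (nrow(tab) < 3L) stop("need >= 3 members with results", call. = FALSE)
  r <- pearson(tab$reference_energy, tab$mean_rupture_force_pN)
  fit <- lm(mean_rupture_force_pN ~ reference_energy, data = tab)
  structure(list(r = r, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), n = nrow(tab),
                 table = as.data.frame(tab)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n")
  cat("  rupture force (pN) vs reference binding energy (kJ/mol, negative =",
      "stronger)\n")
  cat(sprintf("  n = %d complexes, Pearson r = %.3f\n", x$n, x$r))
  cat(sprintf("  fit: force = %.2f %+.2f * energy (expected slope sign: negative)\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Write a correlation report CSV
#'
#' @param rep a [correlation_report()].
#' @param path output path.
#' @export
write_correlation_report <- function(rep, path) {
  write.csv(rep$table, path, row.names = FALSE)
  invisible(rep$table)
}

#' Paired C-SMD vs SA-SMD comparison
#'
#' Runs both modes at each seed on the same landscape and configuration.
#'
#' @param l the landscape.
#' @param cfg a [controller_config()].
#' @param ga_cfg GA settings.
#' @param seeds vector of seeds (>= 1).
#' @return an object of class `mode_comparison`: list with per-pair data
#'   frame `pairs` (seed, csmd/sasmd rupture forces pN, end times,
#'   switches), aggregate `means`, and the raw results in `runs`.
#' @export
compare_modes <- function(l, cfg = controller_config(), ga_cfg = NULL,
                          seeds = 1:5) {
  stopifnot(length(seeds) >= 1L)
  runs <- lapply(seeds, function(s) {
    list(csmd = run_csmd(l, cfg, seed = s),
         sasmd = run_sasmd(l, cfg, ga_cfg, seed = s))
  })
  pairs <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    a <- runs[[i]]$csmd; b <- runs[[i]]$sasmd
    data.frame(seed = seeds[i],
               csmd_rupture_pN = a$rupture_force_pN,
               sasmd_rupture_pN = b$rupture_force_pN,
               csmd_end_ps = a$end_time, sasmd_end_ps = b$end_time,
               sasmd_switches = b$n_direction_switches,
               csmd_unbound = a$unbound, sasmd_unbound = b$unbound)
  }))
  means <- c(csmd_rupture_pN = mean(pairs$csmd_rupture_pN),
             sasmd_rupture_pN = mean(pairs$sasmd_rupture_pN),
             sasmd_switches = mean(pairs$sasmd_switches))
  structure(list(pairs = pairs, means = means, runs = runs),
            class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("<mode_comparison>\n")
  cat(sprintf("  C-SMD  mean rupture: %.1f pN\n", x$means["csmd_rupture_pN"]))
  cat(sprintf("  SA-SMD mean rupture: %.1f pN (mean %.1f switches)\n",
              x$means["sasmd_rupture_pN"], x$means["sasmd_switches"]))
  invisible(x)
}

#' Append run summaries to a runs.csv ledger
#'
#' One line per run: `run_id`, `mode`, `seed`, `v`, `f0_pN`,
#' `rupture_force_pN`, `rupture_time_ps`, `end_time_ps`, `n_switches`,
#' `unbound`.
#'
#' @param result a `rupture_result`.
#' @param cfg the [controller_config()] used.
#' @param path ledger path (created with a header if absent).
#' @param run_id identifier string.
#' @export
append_runs_ledger <- function(result, cfg, path, run_id = "run") {
  df <- data.frame(run_id = run_id, mode = result$mode, seed = result$seed,
                   v = cfg$v, f0_pN = cfg$f0_pN,
                   rupture_force_pN = result$rupture_force_pN,
                   rupture_time_ps = result$rupture_time,
                   end_time_ps = result$end_time,
                   n_switches = result$n_direction_switches,
                   unbound = result$unbound)
  write.table(df, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path),
              qmethod = "double")
  invisible(df)
}
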