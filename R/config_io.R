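# Structured configuration files and trajectory output.

#' Read a structured configuration file
#'
#' YAML with sections `landscape`, `controller`, `ga`, `experiment`
#' (all optional; missing entries fall back to the package defaults). See
#' `system.file("extdata", "example_config.yaml", package = "sasmd")` for a
#' commented schema with units.
#'
#' @param path YAML file path.
#' @return list with elements `landscape_params` (ready for
#'   [make_funnel_landscape()]), `controller` (a [controller_config()]),
#'   `ga` (a [ga_config()]) and `experiment` (raw list).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lp <- default_funnel_params()
  if (!is.null(raw$landscape)) {
    ls <- raw$landscape
    for (nm in setdiff(names(ls), "channels")) lp[[nm]] <- ls[[nm]]
    if (!is.null(ls$channels)) {
      lp$channels <- lapply(ls$channels, function(ch) {
        ch$direction <- as.numeric(ch$direction)
        ch
      })
    }
  }
  ctrl_args <- raw$controller %||% list()
  if (!is.null(ctrl_args$engine))
    ctrl_args$engine <- do.call(engine_params, ctrl_args$engine)
  if (!is.null(ctrl_args$n0)) ctrl_args$n0 <- as.numeric(ctrl_args$n0)
  controller <- do.call(controller_config, ctrl_args)
  ga <- do.call(ga_config, raw$ga %||% list())
  list(landscape_params = lp, controller = controller, ga = ga,
       experiment = raw$experiment %||% list())
}

#' Write a trajectory in XYZ format
#'
#' One pseudo-atom per frame; the comment line carries the frame time in ps.
#' Coordinates are written in nm (XYZ has no unit convention; the header
#' comment states it).
#'
#' @param positions n x 3 matrix of positions, nm.
#' @param times length-n vector of frame times, ps.
#' @param path output path.
#' @param atom element label to use for the pseudo-atom.
#' @export
write_xyz <- function(positions, times, path, atom = "C") {
  stopifnot(is.matrix(positions), ncol(positions) == 3L,
            nrow(positions) == length(times))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(times)) {
    writeLines(c("1", sprintf("t = %.4f ps (coordinates in nm)", times[i]),
                 sprintf("%s %12.6f %12.6f %12.6f", atom,
                         positions[i, 1], positions[i, 2], positions[i, 3])),
               con)
  }
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Columns `t`, `x`, `y`, `z` (ps / nm).
#'
#' @inheritParams write_xyz
#' @export
write_trajectory_csv <- function(positions, times, path) {
  stopifnot(is.matrix(positions), ncol(positions) == 3L,
            nrow(positions) == length(times))
  df <- data.frame(t = times, x = positions[, 1], y = positions[, 2],
                   z = positions[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
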