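# Shared fixtures for the test suite. Everything is generated in code.

# standard two-channel demo landscape
std_landscape <- function(well_depth = 50) {
  make_funnel_landscape(default_funnel_params(well_depth = well_depth))
}

# single soft channel along +z: the quasi-static 1-D test case
axial_landscape <- function(well_depth = 50, barrier = 12) {
  par <- default_funnel_params(well_depth = well_depth)
  par$channels <- list(list(direction = c(0, 0, 1),
                            barrier_height = barrier, width = 0.15))
  make_funnel_landscape(par)
}

# dense 1-D scan oracle along a direction: directional energy maximum and
# maximal slope, independent of the engine
scan_direction <- function(l, dir, rmax = 2, dr = 0.001) {
  rho <- seq(0, rmax, by = dr)
  e <- energy(l, outer(rho, dir))
  list(rho = rho, e = e, max_e = max(e),
       max_slope = max(diff(e) / dr),
       argmax_slope = rho[which.max(diff(e) / dr)])
}

# finite-difference gradient at a point (central differences)
fd_grad <- function(l, r, h = 1e-5) {
  vapply(1:3, function(a) {
    e <- numeric(3); e[a] <- h
    (energy(l, r + e) - energy(l, r - e)) / (2 * h)
  }, 0)
}

# short controller config for fast runs in tests
fast_config <- function(...) {
  controller_config(max_time = 4000, ...)
}
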