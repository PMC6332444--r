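# Synthetic anisotropic binding-funnel energy surfaces.
#
# The surface stands in for a solvated protein-ligand complex: a Gaussian
# binding well of depth D (the analogue of |dG_bind|) sits at the well center,
# surrounded by a radial barrier shell whose height is angularly modulated.
# Low-barrier angular sectors ("channels") are the exit routes; the high "rim"
# between them is the protein wall. Energies are kJ/mol, lengths nm.

#' Default parameter set for the standard two-channel funnel landscape
#'
#' The standard demo geometry used throughout the package: a 50 kJ/mol Gaussian
#' well (width 0.25 nm), a barrier shell at 0.8 nm whose rim is 250 kJ/mol,
#' one moderate channel (barrier 45 kJ/mol) along the +z axis -- the
#' conventional pulling direction, so a fixed-direction pull is laterally
#' trapped in a groove, as it would be in a corrugated protein exit -- and one
#' soft channel (barrier 20 kJ/mol) rotated `soft_angle` away from +z in the
#' xz-plane. Angular channel widths are 0.15 rad. The soft-channel escape is
#' thermally activated at the standard 250 pN trigger force, which gives the
#' rupture force its pulling-rate dependence.
#'
#' @param well_depth depth of the binding well, kJ/mol (proxy for binding
#'   free energy magnitude).
#' @param soft_angle angle (rad) between the soft exit channel and the +z
#'   axis.
#' @return a list of landscape parameters accepted by
#'   [make_funnel_landscape()].
#' @examples
#' l <- make_funnel_landscape(default_funnel_params())
#' @export
default_funnel_params <- function(well_depth = 50, soft_angle = pi / 4) {
  list(
    center = c(0, 0, 0),
    well_depth = well_depth,
    well_width = 0.25,          # nm, Gaussian sigma of the well; the
                                # isotropic well's maximum slope (~200 pN at
                                # depth 50) then sits below the standard
                                # 250 pN trigger, so escape-route anisotropy
                                # (the rim), not the well itself, decides
                                # which pulling directions can unbind
    barrier_radius = 0.8,       # nm, radius of the barrier shell
    rim_height = 250,           # kJ/mol, barrier between channels
    background_stiffness = 0,   # kJ/mol/nm^2, optional confinement
    envelope_radius = 0.8,      # nm, binding-site envelope for separation()
    # pocket wall: high energy outside the tube-like exit channels over the
    # pocket's radial range, zero at the pocket bottom where the channels
    # converge and zero in the far field. Without it the well is an open
    # ball and repeated re-optimization can relieve spring tension
    # indefinitely by dragging the ligand back and forth through the core.
    wall_height = 200,          # kJ/mol
    wall_radius = 0.55,         # nm, radius of maximal wall
    wall_lambda = 0.40,         # nm, radial softness of the wall profile
    tube_radius = 0.06,         # nm, half-width of the channel tubes at
                                # the pocket bottom
    channels = list(
      list(direction = c(sin(soft_angle), 0, cos(soft_angle)),
           barrier_height = 12, width = 0.15),
      list(direction = c(0, 0, 1),
           barrier_height = 45, width = 0.15)
    )
  )
}

# pack a landscape into the flat numeric vector the C++ code consumes
.land_pack <- function(l) {
  if (l$kind == "harmonic") {
    p <- numeric(12)
    p[1] <- 1
    p[2:4] <- l$center
    p[5] <- l$stiffness
    p[10] <- l$envelope_radius
    return(p)
  }
  nch <- length(l$channels)
  p <- numeric(16 + 5 * nch)
  p[1] <- 0
  p[2:4] <- l$center
  p[5] <- l$well_depth
  p[6] <- l$well_width
  p[7] <- l$barrier_radius
  p[8] <- l$rim_height
  p[9] <- l$background_stiffness
  p[10] <- l$envelope_radius
  p[11] <- l$eps
  p[12] <- l$wall_height
  p[13] <- l$wall_radius
  p[14] <- l$wall_lambda
  p[15] <- l$tube_radius
  p[16] <- nch
  for (c in seq_len(nch)) {
    o <- 16 + 5 * (c - 1)
    ch <- l$channels[[c]]
    p[(o + 1):(o + 3)] <- ch$direction
    p[o + 4] <- ch$barrier_height
    p[o + 5] <- ch$width
  }
  p
}

#' Construct a synthetic binding-funnel landscape
#'
#' Builds a smooth, closed-form anisotropic funnel: an isotropic Gaussian well
#' of depth `well_depth` plus a radial barrier shell `s(rho) = x e^(1-x)`,
#' `x = (rho/barrier_radius)^2` (unit maximum at `barrier_radius`), angularly
#' modulated so that each configured channel direction carries its own barrier
#' height while the rim height applies elsewhere. An optional pocket-wall term
#' (`wall_height > 0`) confines the ligand to the exit channels over the
#' pocket's radial range, emulating the steric walls of a binding pocket. The
#' form is twice differentiable everywhere and its analytic gradient is
#' available through [grad()].
#'
#' @param params landscape parameter list, see [default_funnel_params()] for
#'   the fields and units.
#' @param seed integer stored with the landscape; construction itself is
#'   deterministic in `(params, seed)`.
#' @return an object of class `sasmd_landscape`.
#' @examples
#' l <- make_funnel_landscape(default_funnel_params(well_depth = 40))
#' energy(l, c(0, 0, 0))   # -40 at the well bottom
#' @export
make_funnel_landscape <- function(params = default_funnel_params(), seed = 1L) {
  .assert_scalar(params$well_depth, "well_depth", positive = TRUE)
  .assert_scalar(params$barrier_radius, "barrier_radius", positive = TRUE)
  .assert_scalar(params$well_width, "well_width", positive = TRUE)
  if (length(params$channels) < 1L)
    stop("at least one channel is required", call. = FALSE)
  for (ch in params$channels) {
    .assert_unit(ch$direction, "channel direction")
    .assert_scalar(ch$barrier_height, "barrier_height", nonneg = TRUE)
    .assert_scalar(ch$width, "channel width", positive = TRUE)
  }
  if (length(params$channels) > 8L)
    stop("at most 8 channels are supported", call. = FALSE)
  l <- list(
    kind = "funnel",
    center = as.numeric(params$center),
    well_depth = params$well_depth,
    well_width = params$well_width,
    barrier_radius = params$barrier_radius,
    rim_height = params$rim_height,
    background_stiffness = params$background_stiffness %||% 0,
    envelope_radius = params$envelope_radius %||% params$barrier_radius,
    eps = params$eps %||% 1e-5,
    wall_height = params$wall_height %||% 0,
    wall_radius = params$wall_radius %||% 0.55,
    wall_lambda = params$wall_lambda %||% 0.40,
    tube_radius = params$tube_radius %||% 0,
    channels = params$channels,
    seed = as.integer(seed)
  )
  l$descriptor <- .land_pack(l)
  class(l) <- "sasmd_landscape"
  l
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an isotropic harmonic reference landscape
#'
#' `U(r) = stiffness/2 * |r - center|^2`. Used for engine validation against
#' closed-form statistical mechanics (equipartition, Boltzmann statistics) and
#' as a fully isotropic control surface.
#'
#' @param center 3-vector, nm.
#' @param stiffness kJ/mol/nm^2.
#' @param envelope_radius binding-site envelope radius for [separation()], nm.
#' @return an object of class `sasmd_landscape`.
#' @export
make_harmonic_landscape <- function(center = c(0, 0, 0), stiffness = 1000,
                                    envelope_radius = 0) {
  .assert_scalar(stiffness, "stiffness", positive = TRUE)
  l <- list(kind = "harmonic", center = as.numeric(center),
            stiffness = stiffness, envelope_radius = envelope_radius)
  l$descriptor <- .land_pack(l)
  class(l) <- "sasmd_landscape"
  l
}

.as_points <- function(r) {
  if (is.matrix(r)) {
    stopifnot(ncol(r) == 3L)
    r
  } else {
    stopifnot(length(r) == 3L)
    matrix(r, nrow = 1L)
  }
}

#' Potential energy of the landscape
#'
#' @param l a `sasmd_landscape`.
#' @param r a 3-vector (nm) or an n x 3 matrix of points.
#' @return energy in kJ/mol (vector of length n).
#' @export
energy <- function(l, r) {
  stopifnot(inherits(l, "sasmd_landscape"))
  pts <- .as_points(r)
  if (!all(is.finite(pts))) stop("non-finite coordinates", call. = FALSE)
  cpp_energy(l$descriptor, pts)
}

#' Analytic gradient of the landscape energy
#'
#' @inheritParams energy
#' @return gradient(s) in kJ/mol/nm; a 3-vector for a single point, an n x 3
#'   matrix otherwise.
#' @export
grad <- function(l, r) {
  stopifnot(inherits(l, "sasmd_landscape"))
  pts <- .as_points(r)
  if (!all(is.finite(pts))) stop("non-finite coordinates", call. = FALSE)
  g <- cpp_grad(l$descriptor, pts)
  if (!is.matrix(r)) g[1, ] else g
}

#' Receptor-ligand separation surrogate
#'
#' Distance from the binding-site envelope (a sphere of radius
#' `envelope_radius` around the well center): zero inside the envelope,
#' increasing along any outward ray beyond it. Stands in for the minimum
#' receptor-ligand atom distance that terminates a dissociation run.
#'
#' @inheritParams energy
#' @return separation in nm (>= 0).
#' @export
separation <- function(l, r) {
  stopifnot(inherits(l, "sasmd_landscape"))
  pts <- .as_points(r)
  d <- sqrt(rowSums(sweep(pts, 2L, l$center)^2))
  pmax(0, d - l$envelope_radius)
}

#' @export
print.sasmd_landscape <- function(x, ...) {
  if (x$kind == "harmonic") {
    cat(sprintf("<sasmd_landscape: harmonic, stiffness %.1f kJ/mol/nm^2>\n",
                x$stiffness))
  } else {
    cat(sprintf(
      "<sasmd_landscape: funnel, depth %.1f kJ/mol, %d channel(s), rim %.0f kJ/mol>\n",
      x$well_depth, length(x$channels), x$rim_height))
    for (ch in x$channels)
      cat(sprintf("  channel: barrier %.1f kJ/mol, width %.2f rad, dir (%.2f, %.2f, %.2f)\n",
                  ch$barrier_height, ch$width,
                  ch$direction[1], ch$direction[2], ch$direction[3]))
  }
  invisible(x)
}

#' Specify a family of landscapes differing only in well depth
#'
#' The synthetic analogue of a congeneric series of complexes sharing one
#' receptor: channel layout and all geometric parameters are reused across
#' members, and only the well depth -- the stand-in for the experimental
#' binding free energy -- varies over `depth_range`.
#'
#' @param n_members number of complexes in the family (>= 2).
#' @param depth_range `c(min, max)` well depth, kJ/mol.
#' @param seed integer seed (controls depth placement when
#'   `spacing = "random"`).
#' @param geometry shared landscape parameter list (channel layout etc.);
#'   its `well_depth` entry is overridden per member.
#' @param spacing `"even"` for evenly spaced depths, `"random"` for seeded
#'   uniform draws.
#' @return an object of class `sasmd_family_spec`.
#' @export
family_spec <- function(n_members, depth_range, seed = 1L,
                        geometry = default_funnel_params(),
                        spacing = c("even", "random")) {
  if (n_members < 2L) stop("n_members must be >= 2", call. = FALSE)
  if (length(depth_range) != 2L || depth_range[1] <= 0 ||
      depth_range[2] <= depth_range[1])
    stop("depth_range must be c(min, max) with 0 < min < max", call. = FALSE)
  structure(list(n_members = as.integer(n_members),
                 depth_range = as.numeric(depth_range),
                 seed = as.integer(seed), geometry = geometry,
                 spacing = match.arg(spacing)),
            class = "sasmd_family_spec")
}

#' Generate a landscape family
#'
#' @param spec a [family_spec()].
#' @return a list with one element per member:
#'   `list(member_id, landscape, well_depth, reference_energy)` where
#'   `reference_energy = -well_depth` (kJ/mol, more negative = stronger
#'   binding).
#' @examples
#' fam <- make_family(family_spec(4, c(20, 60)))
#' sapply(fam, `[[`, "well_depth")
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "sasmd_family_spec"))
  depths <- if (spec$spacing == "even") {
    seq(spec$depth_range[1], spec$depth_range[2], length.out = spec$n_members)
  } else {
    .with_preserved_rng({
      set.seed(spec$seed)
      sort(runif(spec$n_members, spec$depth_range[1], spec$depth_range[2]))
    })
  }
  lapply(seq_len(spec$n_members), function(i) {
    par <- spec$geometry
    par$well_depth <- depths[i]
    list(member_id = sprintf("m%02d", i),
         landscape = make_funnel_landscape(par, seed = spec$seed + i),
         well_depth = depths[i],
         reference_energy = -depths[i])
  })
}

#' Write a family manifest CSV
#'
#' Columns: `member_id`, `well_depth`, `reference_energy`.
#'
#' @param fam result of [make_family()].
#' @param path output CSV path.
#' @return the manifest data frame, invisibly.
#' @export
write_family_manifest <- function(fam, path) {
  df <- data.frame(member_id = vapply(fam, `[[`, "", "member_id"),
                   well_depth = vapply(fam, `[[`, 0, "well_depth"),
                   reference_energy = vapply(fam, `[[`, 0, "reference_energy"))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
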