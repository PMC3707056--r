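#' Phantom specification for a double-ring barrel complex
#'
#' Geometry and composition of the synthetic chaperonin phantom: two stacked
#' rings of eight Gaussian subunits each (exact D8 symmetry by construction),
#' an equatorial wall connecting them, a hollow central chamber, and two
#' optional asymmetric features - an off-axis interior globule (the
#' "cavity-occupied" state) and extra apical density beyond one ring (the
#' "fibril-bound" state).
#'
#' All physical quantities are in Angstrom.  The defaults model a ~950 kDa,
#' ~160 A wide complex sampled at 4.4 A/voxel in a 48-voxel box; they are the
#' package's fixed study conditions (see the methods vignette for rationale).
#'
#' @param box Grid extent in voxels.
#' @param voxel_size Sampling in Angstrom per voxel.
#' @param ring_radius Distance of subunit centers from the symmetry axis.
#' @param ring_half_separation Axial offset of each ring from the equator.
#' @param subunits_per_ring Number of subunits per ring (8 for this family).
#' @param subunit_sigma Gaussian width of one subunit blob.
#' @param wall_density Relative amplitude of the equatorial wall.
#' @param cavity_radius,cavity_half_height Cylindrical chamber dimensions;
#'   the barrel is carved hollow inside this region.
#' @param occupancy_fraction Integrated interior density divided by the
#'   integrated barrel density (`f`); `f = 60/950` emulates a ~60 kDa cargo
#'   inside a ~950 kDa complex.
#' @param interior_offset Radial displacement of the interior globule from
#'   the axis (a nonzero offset makes the cargo D8-asymmetric, so symmetry-
#'   restricted refinement has something to localize).
#' @param interior_sigma Gaussian width of the interior globule.
#' @param apical_fraction Integrated apical extra density (beyond one ring's
#'   tips) divided by the barrel integral; nonzero emulates a fibril-bound
#'   particle.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(box = 48L,
                         voxel_size = 4.4,
                         ring_radius = 55,
                         ring_half_separation = 28,
                         subunits_per_ring = 8L,
                         subunit_sigma = 13,
                         wall_density = 0.3,
                         cavity_radius = 38,
                         cavity_half_height = 40,
                         occupancy_fraction = 0,
                         interior_offset = 13,
                         interior_sigma = 9,
                         apical_fraction = 0) {
  if (occupancy_fraction < 0) abort("`occupancy_fraction` must be >= 0")
  if (apical_fraction < 0) abort("`apical_fraction` must be >= 0")
  half_box <- box * voxel_size / 2
  if (ring_radius + 2 * subunit_sigma > half_box)
    abort("barrel does not fit the box: increase `box` or shrink the geometry")
  structure(as.list(environment())[names(formals(phantom_spec))],
            class = "phantom_spec")
}

#' Build a phantom density map
#'
#' Realizes a [phantom_spec] as a [density_map]: a sum of Gaussian subunit
#' blobs at the 2 x 8 ring positions plus an equatorial wall, carved exactly
#' hollow inside the cavity cylinder, plus (optionally) an interior globule
#' scaled so its realized integral is `occupancy_fraction` times the barrel
#' integral, and an on-axis apical blob beyond one ring.
#'
#' With `occupancy_fraction = 0` and `apical_fraction = 0` the map is exactly
#' C8-symmetric about Z and two-fold symmetric between rings (D8).
#'
#' @param spec A [phantom_spec].
#' @return A [density_map].
#' @examples
#' ph <- build_phantom(phantom_spec(box = 32, voxel_size = 6.6))
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$box
  vs <- spec$voxel_size
  ctr <- n %/% 2
  # physical coordinates (A) relative to the rotation-center voxel
  ax <- (seq_len(n) - 1 - ctr) * vs
  X <- array(ax, c(n, n, n))
  Y <- array(rep(ax, each = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  R2 <- X^2 + Y^2

  gauss_blob <- function(cx, cy, cz, sigma) {
    exp(-((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2) / (2 * sigma^2))
  }

  barrel <- array(0, c(n, n, n))
  ang <- 2 * pi * (seq_len(spec$subunits_per_ring) - 1) / spec$subunits_per_ring
  for (a in ang) {
    cx <- spec$ring_radius * cos(a)
    cy <- spec$ring_radius * sin(a)
    for (cz in c(-1, 1) * spec$ring_half_separation)
      barrel <- barrel + gauss_blob(cx, cy, cz, spec$subunit_sigma)
  }
  # equatorial wall: rotationally symmetric shell at the ring radius
  wall <- spec$wall_density *
    exp(-(sqrt(R2) - spec$ring_radius)^2 / (2 * spec$subunit_sigma^2)) *
    exp(-(Z / spec$ring_half_separation)^4)
  barrel <- barrel + wall

  # carve the chamber: zero inside the cavity cylinder, smooth 1.5-voxel ramp
  # outside it (the window is rotationally and flip symmetric, so carving
  # preserves exact D8 symmetry)
  inside_r <- spec$cavity_radius - sqrt(R2)        # > 0 inside radially
  inside_z <- spec$cavity_half_height - abs(Z)     # > 0 inside axially
  depth <- pmin(inside_r, inside_z)                # > 0 strictly inside
  ramp <- 1.5 * vs
  s <- pmin(pmax(-depth / ramp, 0), 1)             # 0 inside .. 1 outside
  window <- s * s * (3 - 2 * s)
  barrel <- barrel * window

  vol <- barrel
  barrel_integral <- sum(barrel)

  if (spec$occupancy_fraction > 0) {
    glob <- gauss_blob(spec$interior_offset, 0, 0, spec$interior_sigma)
    glob[depth <= 0] <- 0   # truncate to the chamber
    glob <- glob * (spec$occupancy_fraction * barrel_integral / sum(glob))
    vol <- vol + glob
  }
  if (spec$apical_fraction > 0) {
    z_ap <- spec$ring_half_separation + 2 * spec$subunit_sigma
    ap <- gauss_blob(0, 0, z_ap, 1.2 * spec$subunit_sigma)
    ap <- ap * (spec$apical_fraction * barrel_integral / sum(ap))
    vol <- vol + ap
  }
  density_map(vol, voxel_size = vs)
}

# cavity mask of a phantom spec, in voxels, on the phantom's own grid
phantom_cavity_mask <- function(spec) {
  mask_cylinder(radius = spec$cavity_radius / spec$voxel_size,
                height = 2 * spec$cavity_half_height / spec$voxel_size)
}
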