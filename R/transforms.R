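#' Rigid transform (ZYZ Euler angles + translation)
#'
#' A rotation expressed as intrinsic ZYZ Euler angles in degrees (rotate about
#' Z by `phi`, then about the new Y by `theta`, then about the new Z by `psi`)
#' followed by a translation in voxels.  Rotations act about the voxel at
#' index `floor(N/2)` (0-based) of the cubic grid, matching the Fourier-space
#' center used elsewhere in the package.
#'
#' @param euler Numeric length-3: `c(phi, theta, psi)` in degrees.
#' @param shift Numeric length-3 translation in voxels, applied after the
#'   rotation.
#' @return An object of class `rigid_transform`. Angles are normalized to
#'   `[0, 360)`.
#' @examples
#' t <- rigid_transform(c(40, 20, 10), shift = c(1, 0, -2))
#' compose_transforms(invert_transform(t), t)  # ~ identity
#' @export
rigid_transform <- function(euler = c(0, 0, 0), shift = c(0, 0, 0)) {
  stopifnot(length(euler) == 3, length(shift) == 3)
  euler <- as.numeric(euler) %% 360
  structure(list(euler = euler, shift = as.numeric(shift)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> euler (%.2f, %.2f, %.2f) deg, shift (%.2f, %.2f, %.2f) vox\n",
              x$euler[1], x$euler[2], x$euler[3],
              x$shift[1], x$shift[2], x$shift[3]))
  invisible(x)
}

#' Rotation matrix of a ZYZ Euler triple
#'
#' @param euler `c(phi, theta, psi)` in degrees (intrinsic ZYZ).
#' @return A 3x3 rotation matrix.
#' @export
euler_matrix <- function(euler) {
  r <- euler * pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(r[1]) %*% ry(r[2]) %*% rz(r[3])
}

#' Euler angles of a rotation matrix (ZYZ, degrees)
#'
#' Inverse of [euler_matrix()].  At the gimbal-degenerate poles
#' (`theta` near 0 or 180) `psi` is set to 0 and the full in-plane angle is
#' assigned to `phi`.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric length-3 Euler triple in `[0, 360)`.
#' @export
matrix_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (sin(theta) > 1e-9) {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else if (ct > 0) {      # theta ~ 0: R = Rz(phi + psi)
    phi <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {                  # theta ~ 180: R = Rz(phi - psi) Ry(180)
    phi <- atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  }
  (c(phi, theta, psi) * 180 / pi) %% 360
}

#' @rdname rigid_transform
#' @param t,t1,t2 `rigid_transform` objects.
#' @details `compose_transforms(t2, t1)` is the transform equivalent to
#'   applying `t1` first, then `t2`; `invert_transform(t)` composes with `t`
#'   to the identity (up to interpolation when applied to voxel data).
#' @export
compose_transforms <- function(t2, t1) {
  R2 <- euler_matrix(t2$euler); R1 <- euler_matrix(t1$euler)
  rigid_transform(matrix_euler(R2 %*% R1),
                  shift = t2$shift + as.vector(R2 %*% t1$shift))
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(t) {
  R <- euler_matrix(t$euler)
  rigid_transform(matrix_euler(t(R)), shift = -as.vector(t(R) %*% t$shift))
}

#' Apply a rigid transform to a density map
#'
#' Rotates the map about the grid-center voxel (index `floor(N/2)`, 0-based)
#' and then shifts it, resampling with trilinear interpolation; samples that
#' fall outside the grid are filled with zero.
#'
#' @param map A [density_map].
#' @param t A [rigid_transform].
#' @return The transformed [density_map].
#' @export
apply_transform <- function(map, t) {
  stopifnot(is_density_map(map), inherits(t, "rigid_transform"))
  out <- .cpp_affine_resample(map$data, euler_matrix(t$euler), t$shift)
  density_map(out, voxel_size = map$voxel_size, origin = map$origin)
}

# rotate a raw array (internal fast path used by the alignment search)
rotate_array <- function(arr, Rmat, shift = c(0, 0, 0)) {
  .cpp_affine_resample(arr, Rmat, shift)
}

# geodesic angle (degrees) between two rotations given as euler triples;
# optionally modulo a point group (smallest angle over group elements)
rotation_distance <- function(e1, e2, group = NULL) {
  R1 <- euler_matrix(e1); R2 <- euler_matrix(e2)
  ang <- function(Ra, Rb) {
    tr <- sum(diag(t(Ra) %*% Rb))
    acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
  }
  if (is.null(group)) return(ang(R1, R2))
  min(vapply(group, function(g) ang(R1 %*% g, R2), numeric(1)))
}

#' Elements of the D8 point group
#'
#' The sixteen rotations of the dihedral group of an eightfold double ring:
#' eight rotations about Z in 45-degree steps, and the same eight composed
#' with a two-fold flip about X (the in-plane axis exchanging the two rings).
#'
#' @return A list of 16 [rigid_transform]s (identity first).
#' @export
d8_elements <- function() {
  out <- vector("list", 16)
  flip <- euler_matrix(c(0, 180, 180))  # = 180 deg rotation about X
  for (k in 0:7) {
    Rz <- euler_matrix(c(45 * k, 0, 0))
    out[[k + 1]] <- rigid_transform(matrix_euler(Rz))
    out[[k + 9]] <- rigid_transform(matrix_euler(Rz %*% flip))
  }
  out
}
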