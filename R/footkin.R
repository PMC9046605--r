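## Multi-segment foot kinematics: Joint Coordinate System decomposition for the
## shank-calcaneus-midfoot-metatarsus-hallux chain, plus the planar arch and
## metatarsal angles. All angles in degrees; rotation matrices are 3x3
## orthonormal, columns = segment axes expressed in the lab frame, with
## x anterior-posterior, y vertical, z medio-lateral.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the lab/segment axes, angle in degrees.
#' `rot_z` carries sagittal-plane rotation (medio-lateral axis), `rot_x`
#' frontal-plane rotation (anterior-posterior axis), `rot_y` transverse-plane
#' rotation (vertical axis).
#'
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Compose a relative joint rotation from JCS angles
#'
#' Builds the distal-relative-to-proximal rotation whose Joint Coordinate
#' System decomposition is exactly the given angle triple: first rotation
#' about the proximal z axis (sagittal), then about the floating x axis
#' (frontal), then about the distal y axis (transverse):
#' `R = Rz(sagittal) Rx(frontal) Ry(transverse)`.
#'
#' This is the exact inverse of [jcs_angles()]; the pair round-trips to
#' machine precision away from the gimbal singularity (|frontal| = 90 deg).
#'
#' @param sagittal,frontal,transverse angles in degrees.
#' @return 3x3 rotation matrix (distal expressed in the proximal frame).
#' @export
jcs_compose <- function(sagittal, frontal, transverse) {
  rot_z(sagittal) %*% rot_x(frontal) %*% rot_y(transverse)
}

#' Joint Coordinate System angle decomposition
#'
#' Decomposes the relative rotation `R = t(pose_proximal) %*% pose_distal`
#' into the three clinical rotation components: sagittal about the proximal
#' z (medio-lateral) axis, transverse about the distal y (vertical) axis,
#' and frontal about their mutual-perpendicular floating axis. For the
#' shank-calcaneus joint the frontal component is signed eversion (+) /
#' inversion (-); sagittal is dorsiflexion (+).
#'
#' @param pose_proximal,pose_distal 3x3 orthonormal rotation matrices
#'   (segment axes in the lab frame).
#' @return named numeric vector `c(sagittal, frontal, transverse)` in
#'   degrees, with attribute `gimbal = TRUE` when the frontal component is
#'   within 1 degree of +/-90 (decomposition ill-conditioned).
#' @export
jcs_angles <- function(pose_proximal, pose_distal) {
  if (!is_rotation_matrix(pose_proximal) || !is_rotation_matrix(pose_distal))
    stop("poses must be orthonormal rotation matrices with det +1", call. = FALSE)
  R <- crossprod(pose_proximal, pose_distal)   # t(Rp) %*% Rd
  jcs_decompose(R)
}

## Decompose a relative rotation R = Rz(a) Rx(b) Ry(c). Internal core shared
## by jcs_angles and the trajectory path.
jcs_decompose <- function(R) {
  sb <- min(1, max(-1, R[3, 2]))
  frontal <- asin(sb)
  sagittal <- atan2(-R[1, 2], R[2, 2])
  transverse <- atan2(-R[3, 1], R[3, 3])
  out <- c(sagittal = rad2deg(sagittal),
           frontal = rad2deg(frontal),
           transverse = rad2deg(transverse))
  if (abs(abs(out[["frontal"]]) - 90) < 1) attr(out, "gimbal") <- TRUE
  out
}

#' JCS angle trajectories for a joint
#'
#' Applies [jcs_angles()] sample-by-sample to two pose trajectories.
#'
#' @param poses_proximal,poses_distal arrays of dimension `c(3, 3, n)`.
#' @return matrix `n x 3` with columns sagittal, frontal, transverse
#'   (degrees); attribute `gimbal` flags any ill-conditioned sample.
#' @export
jcs_angle_series <- function(poses_proximal, poses_distal) {
  stopifnot(length(dim(poses_proximal)) == 3, length(dim(poses_distal)) == 3,
            dim(poses_proximal)[3] == dim(poses_distal)[3])
  n <- dim(poses_proximal)[3]
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("sagittal", "frontal", "transverse")))
  gimbal <- FALSE
  for (i in seq_len(n)) {
    R <- crossprod(poses_proximal[, , i], poses_distal[, , i])
    a <- jcs_decompose(R)
    out[i, ] <- a
    if (isTRUE(attr(a, "gimbal"))) gimbal <- TRUE
  }
  if (gimbal) attr(out, "gimbal") <- TRUE
  out
}

#' Medial longitudinal arch angle
#'
#' Apex angle of the arch triad: the angle at the arch-apex landmark between
#' the limb to the heel marker and the limb to the first metatarsal head
#' marker. A flatter arch gives a larger angle (180 deg in the collinear
#' limit).
#'
#' @param heel_marker,mid_marker,first_met_head_marker numeric length-3
#'   positions (any common unit); `mid_marker` is the apex vertex.
#' @return angle in degrees, in (0, 180].
#' @export
mla_angle <- function(heel_marker, mid_marker, first_met_head_marker) {
  u <- heel_marker - mid_marker
  v <- first_met_head_marker - mid_marker
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate arch triad: apex coincides with a limb marker", call. = FALSE)
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(cr^2))
  if (s / (nu * nv) < 1e-12 && sum(u * v) > 0)
    stop("collinear arch markers with apex outside the heel-head segment", call. = FALSE)
  rad2deg(atan2(s, sum(u * v)))
}

#' Sagittal inclination of a metatarsal axis to the ground
#'
#' Angle between the base-to-head axis and the ground plane, signed positive
#' when the head lies below the base (a declining metatarsal).
#'
#' @param base_marker,head_marker numeric length-3 positions.
#' @param vertical_axis unit-up direction of the lab frame (default y-up).
#' @return angle in degrees in (-90, 90).
#' @export
metatarsal_inclination <- function(base_marker, head_marker,
                                   vertical_axis = c(0, 1, 0)) {
  v <- head_marker - base_marker
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length metatarsal axis", call. = FALSE)
  up <- vertical_axis / sqrt(sum(vertical_axis^2))
  rad2deg(asin(min(1, max(-1, -sum(v * up) / nv))))
}

#' Transverse-plane divergence between two metatarsal axes
#'
#' Signed angle between the two axes after projecting out the vertical
#' component (projection onto the ground plane), measured from `axis_a` to
#' `axis_b` about the vertical axis (right-hand rule).
#'
#' @param axis_a,axis_b numeric length-3 direction vectors.
#' @param vertical_axis unit-up direction (default y-up).
#' @return signed angle in degrees in (-180, 180].
#' @export
metatarsal_divergence <- function(axis_a, axis_b, vertical_axis = c(0, 1, 0)) {
  up <- vertical_axis / sqrt(sum(vertical_axis^2))
  pa <- axis_a - sum(axis_a * up) * up
  pb <- axis_b - sum(axis_b * up) * up
  na_ <- sqrt(sum(pa^2)); nb_ <- sqrt(sum(pb^2))
  if (na_ < 1e-12 * sqrt(sum(axis_a^2)) || nb_ < 1e-12 * sqrt(sum(axis_b^2)))
    stop("axis has vanishing ground-plane projection", call. = FALSE)
  cr <- c(pa[2] * pb[3] - pa[3] * pb[2],
          pa[3] * pb[1] - pa[1] * pb[3],
          pa[1] * pb[2] - pa[2] * pb[1])
  rad2deg(atan2(sum(cr * up), sum(pa * pb)))
}

#' Build a segment pose from a marker triad
#'
#' Thin adapter for marker-level input: constructs an orthonormal segment
#' frame with origin at `origin`, x axis toward `anterior_marker`, and z axis
#' perpendicular to the plane of the triad (Gram-Schmidt orthogonalization).
#'
#' @param origin,anterior_marker,plane_marker numeric length-3 marker
#'   positions; must be non-collinear.
#' @return list with `R` (3x3 rotation, columns = axes) and `origin`.
#' @export
markers_to_pose <- function(origin, anterior_marker, plane_marker) {
  x <- anterior_marker - origin
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("coincident origin and anterior marker", call. = FALSE)
  x <- x / nx
  w <- plane_marker - origin
  z <- c(x[2] * w[3] - x[3] * w[2],
         x[3] * w[1] - x[1] * w[3],
         x[1] * w[2] - x[2] * w[1])
  nz <- sqrt(sum(z^2))
  if (nz < 1e-12 * sqrt(sum(w^2))) stop("collinear marker triad", call. = FALSE)
  z <- z / nz
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  list(R = cbind(x, y, z, deparse.level = 0), origin = origin)
}
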