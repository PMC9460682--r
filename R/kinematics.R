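# Euler-sequence decompositions and the scapulothoracic / humerothoracic
# rotation angles.
#
# All rotation matrices act on column vectors (active convention); a frame's
# axes matrix maps frame coordinates to world coordinates, so the rotation
# of a child frame relative to a parent frame is t(parent$axes) %*% child$axes.
# Public interfaces are in degrees; internals are radians.

GIMBAL_TOL <- 1e-7   # |cos(middle angle)| below this aborts a Y-X-Z decomposition

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Elementary rotation matrices
#'
#' Active right-handed rotations about the coordinate axes, angle in degrees.
#'
#' @param angle_deg rotation angle, degrees.
#' @return a 3x3 rotation matrix.
#' @export
rot_x <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

check_rotation <- function(R) {
  if (!is.matrix(R) || any(dim(R) != 3L) ||
      max(abs(crossprod(R) - diag(3))) > 1e-7 || det(R) < 0) {
    sta_error("sta_validation_error", "not a proper rotation matrix")
  }
  R
}

#' Rotation of one frame relative to another
#'
#' Returns the rotation matrix of `child` expressed in `parent` coordinates:
#' `t(parent$axes) %*% child$axes`.
#'
#' @param child,parent `sta_frame` objects.
#' @return 3x3 proper rotation matrix.
#' @export
relative_rotation <- function(child, parent) {
  stopifnot(is_frame(child), is_frame(parent))
  unname(crossprod(parent$axes, child$axes))
}

#' Y-X-Z Euler decomposition
#'
#' Factors a rotation as `R = Ry(y) %*% Rx(x) %*% Rz(z)` (intrinsic y-x'-z'',
#' the ISB scapulothoracic sequence). Angles are returned in degrees in
#' (-180, 180]. Near gimbal lock (|cos x| < 1e-7, i.e. the middle angle
#' within ~1e-5 degrees of +/-90) the outer angles are indeterminate and an
#' error of class `"sta_gimbal_lock_error"` is raised.
#'
#' @param R 3x3 proper rotation matrix.
#' @return named numeric: `y`, `x`, `z` (degrees).
#' @export
decompose_yxz <- function(R) {
  check_rotation(R)
  sx <- -R[2L, 3L]
  sx <- max(-1, min(1, sx))
  cx <- sqrt(max(0, 1 - sx * sx))
  if (cx < GIMBAL_TOL) {
    sta_error("sta_gimbal_lock_error",
              "Y-X-Z sequence is gimbal locked (middle angle at %.1f degrees)",
              rad2deg(asin(sx)))
  }
  c(y = rad2deg(atan2(R[1L, 3L], R[3L, 3L])),
    x = rad2deg(asin(sx)),
    z = rad2deg(atan2(R[2L, 1L], R[2L, 2L])))
}

#' Y-X-Y Euler decomposition
#'
#' Factors a rotation as `R = Ry(y1) %*% Rx(x) %*% Ry(y2)` (the ISB
#' humerothoracic sequence). The middle angle `x` lies in [0, 180] and is
#' always well defined; when `x` is within `tol_deg` of 0 or 180 the split
#' between `y1` and `y2` is indeterminate (only their sum, respectively
#' difference, is identifiable) and the result carries
#' `attr(, "indeterminate") = TRUE` with the whole Y rotation assigned to
#' `y1`.
#'
#' @param R 3x3 proper rotation matrix.
#' @param tol_deg degeneracy tolerance on the middle angle, degrees.
#' @return named numeric: `y1`, `x`, `y2` (degrees).
#' @export
decompose_yxy <- function(R, tol_deg = 1e-6) {
  check_rotation(R)
  cb <- max(-1, min(1, R[2L, 2L]))
  b <- acos(cb)
  if (rad2deg(min(b, pi - b)) < tol_deg) {
    # pure Y rotation (b ~ 0) or flipped (b ~ 180): put everything in y1
    y1 <- if (b < pi / 2) atan2(R[1L, 3L], R[1L, 1L]) else atan2(-R[1L, 3L], R[1L, 1L])
    out <- c(y1 = rad2deg(y1), x = rad2deg(b), y2 = 0)
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  out <- c(y1 = rad2deg(atan2(R[1L, 2L], R[3L, 2L])),
           x = rad2deg(b),
           y2 = rad2deg(atan2(R[2L, 1L], -R[2L, 3L])))
  attr(out, "indeterminate") <- FALSE
  out
}

#' Compose Euler sequences
#'
#' Inverses of [decompose_yxz()] / [decompose_yxy()]; angles in degrees.
#'
#' @param y,x,z,y1,y2 angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
compose_yxz <- function(y, x, z) rot_y(y) %*% rot_x(x) %*% rot_z(z)

#' @rdname compose_yxz
#' @export
compose_yxy <- function(y1, x, y2) rot_y(y1) %*% rot_x(x) %*% rot_y(y2)

#' Humerothoracic elevation angle
#'
#' The elevation of the humerus relative to the thorax: the magnitude of the
#' middle (X) angle of the Y-X-Y decomposition of the humerothoracic
#' rotation, in degrees. ISB defines elevation as a negative rotation; it is
#' reported here as a positive magnitude, matching common clinical usage.
#'
#' @param hum,thx humerus and thorax `sta_frame`s.
#' @return elevation in degrees, in [0, 180].
#' @export
humerothoracic_elevation <- function(hum, thx) {
  ang <- decompose_yxy(relative_rotation(hum, thx))
  abs(unname(ang["x"]))
}

#' Scapulothoracic rotation angles
#'
#' Decomposes the rotation of the scapula relative to the thorax with the
#' ISB Y-X-Z sequence and maps the raw Euler angles to clinically named
#' components: internal rotation = +y, upward rotation = -x (the ISB X
#' rotation is positive downward), posterior tilt = +z. All in degrees.
#'
#' @param scap,thx scapula and thorax `sta_frame`s (right-side convention).
#' @return named numeric: `upward_rotation`, `internal_rotation`,
#'   `posterior_tilt` (degrees).
#' @export
scapulothoracic_angles <- function(scap, thx) {
  e <- decompose_yxz(relative_rotation(scap, thx))
  c(upward_rotation  = -unname(e["x"]),
    internal_rotation = unname(e["y"]),
    posterior_tilt    = unname(e["z"]))
}

#' Rotation matrix for named scapulothoracic angles
#'
#' Inverse of the [scapulothoracic_angles()] mapping; used to plant known
#' scapular orientations in synthetic cohorts.
#'
#' @param upward_rotation,internal_rotation,posterior_tilt degrees.
#' @return 3x3 rotation matrix (scapula axes in thorax coordinates).
#' @export
scapulothoracic_rotation <- function(upward_rotation, internal_rotation,
                                     posterior_tilt) {
  compose_yxz(internal_rotation, -upward_rotation, posterior_tilt)
}

#' Marker-based scapular frame
#'
#' The scapular anatomical frame built from the skin-marker centers instead
#' of the bony landmarks; contract identical to [build_scapula_frame()].
#' The angular discrepancy between this frame and the bone-based frame
#' quantifies the soft-tissue artifact.
#'
#' @param markers a `markers` [landmark_set()] with AA, TS, AI centers.
#' @return An `sta_frame`.
#' @export
marker_based_frame <- function(markers) {
  build_scapula_frame(lm_point(markers, "AA"), lm_point(markers, "TS"),
                      lm_point(markers, "AI"))
}
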