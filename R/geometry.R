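# Rigid-body primitives: anatomical frames, sphere fits, frame transforms.
#
# Conventions used throughout the package:
#  * all lengths in millimetres;
#  * the laboratory (world) frame is right-handed with +X pointing forward
#    (anterior), +Y up (superior) and +Z to the subject's right;
#  * a frame is stored as an origin plus a 3x3 matrix whose COLUMNS are the
#    frame's X, Y, Z axes expressed in world coordinates;
#  * left shoulders are mirrored to the right-side convention before any
#    frame is built (see [mirror_left_to_right()]).

DEGENERACY_TOL <- 1e-6   # mm^2, cross-product norm below which geometry is degenerate
ORTHO_TOL <- 1e-9

sta_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sta_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    sta_error("sta_validation_error", "%s must be 3 finite coordinates", what)
  }
  p
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "axis") {
  n <- vnorm(v)
  if (n < sqrt(DEGENERACY_TOL)) {
    sta_error("sta_degenerate_geometry_error",
              "degenerate geometry: %s direction has near-zero length (%.3g mm)",
              what, n)
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct an anatomical coordinate frame
#'
#' A frame couples an origin (mm, world coordinates) with a right-handed
#' orthonormal triad of axes. The axes are stored as the columns of a 3x3
#' matrix, so `f$axes` is the rotation that maps frame coordinates to world
#' coordinates.
#'
#' @param origin numeric length-3, mm.
#' @param x,y,z unit axis vectors in world coordinates.
#' @return An object of class `"sta_frame"` with elements `origin` and `axes`.
#' @export
new_frame <- function(origin, x, y, z) {
  origin <- as_point3(origin, "origin")
  R <- cbind(X = as_point3(x, "X axis"), Y = as_point3(y, "Y axis"),
             Z = as_point3(z, "Z axis"))
  if (max(abs(crossprod(R) - diag(3))) > 1e-7) {
    sta_error("sta_validation_error", "frame axes are not orthonormal")
  }
  if (det(R) < 0) {
    sta_error("sta_validation_error", "frame axes are left-handed (det < 0)")
  }
  structure(list(origin = origin, axes = R), class = "sta_frame")
}

#' @export
print.sta_frame <- function(x, ...) {
  cat("<sta_frame>\n origin (mm):", format(round(x$origin, 3)), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

is_frame <- function(f) inherits(f, "sta_frame")

#' Landmark sets
#'
#' A landmark set is a named collection of 3-D points belonging to one bone
#' (or to the skin-marker centers) of one shoulder, in world coordinates.
#'
#' Required landmark names per bone: thorax `IJ, C7, PX, T8`; scapula
#' `AA, TS, AI`; humerus `EL, EM` plus either a head center `GH` or at least
#' four humeral-head surface points (names beginning `HH`); markers
#' `AA, TS, AI` (the marker centers over those bony landmarks).
#'
#' @param points named list of length-3 numeric vectors, or a numeric matrix
#'   with 3 columns and row names.
#' @param bone one of `"thorax"`, `"humerus"`, `"scapula"`, `"markers"`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `"landmark_set"`: a points matrix (rows =
#'   landmarks, columns = x, y, z in mm) plus `bone` and `side` attributes.
#' @export
landmark_set <- function(points, bone = c("thorax", "humerus", "scapula", "markers"),
                         side = c("right", "left")) {
  bone <- match.arg(bone)
  side <- match.arg(side)
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as_point3))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L || is.null(rownames(points))) {
    sta_error("sta_validation_error", "points must be a named list or a 3-column matrix with row names")
  }
  if (anyDuplicated(rownames(points))) {
    sta_error("sta_validation_error", "duplicate landmark names: %s",
              paste(unique(rownames(points)[duplicated(rownames(points))]), collapse = ", "))
  }
  if (any(!is.finite(points))) {
    sta_error("sta_validation_error", "non-finite landmark coordinates")
  }
  colnames(points) <- c("x", "y", "z")
  required <- switch(bone,
    thorax  = c("IJ", "C7", "PX", "T8"),
    scapula = c("AA", "TS", "AI"),
    markers = c("AA", "TS", "AI"),
    humerus = c("EL", "EM"))
  missing <- setdiff(required, rownames(points))
  if (length(missing)) {
    sta_error("sta_validation_error", "%s landmark set is missing: %s",
              bone, paste(missing, collapse = ", "))
  }
  if (bone == "humerus" && !("GH" %in% rownames(points)) &&
      sum(startsWith(rownames(points), "HH")) < 4L) {
    sta_error("sta_validation_error",
              "humerus needs a GH head center or >= 4 head-surface points (HH*)")
  }
  structure(points, bone = bone, side = side, class = c("landmark_set", "matrix", "array"))
}

lm_point <- function(lm, name) {
  if (!(name %in% rownames(lm))) {
    sta_error("sta_validation_error", "landmark '%s' not present", name)
  }
  as.numeric(lm[name, ])
}

#' Thorax anatomical frame (ISB)
#'
#' Origin at the deepest point of the sternal notch (IJ). Y points upward
#' along the line from the midpoint of PX (xiphoid) and T8 to the midpoint
#' of IJ and C7; Z is perpendicular to the plane through IJ, C7 and the
#' PX/T8 midpoint, pointing to the subject's right; X = Y x Z points
#' forward. The right-pointing sign of Z follows from the fixed cross-product
#' ordering `(IJ - mid(PX,T8)) x (C7 - mid(PX,T8))`, which is intrinsic to
#' the landmarks, so constructed frames are exactly equivariant under rigid
#' motions of the input.
#'
#' @param lm a thorax [landmark_set()] (right-side convention).
#' @return An [new_frame()] object.
#' @export
build_thorax_frame <- function(lm) {
  ij <- lm_point(lm, "IJ"); c7 <- lm_point(lm, "C7")
  px <- lm_point(lm, "PX"); t8 <- lm_point(lm, "T8")
  mid_lo <- (px + t8) / 2
  mid_hi <- (ij + c7) / 2
  y <- unitize(mid_hi - mid_lo, "thorax Y (spine line)")
  zn <- cross3(ij - mid_lo, c7 - mid_lo)
  if (vnorm(zn) < DEGENERACY_TOL) {
    sta_error("sta_degenerate_geometry_error",
              "thorax landmarks IJ, C7, mid(PX,T8) are collinear")
  }
  z <- zn / vnorm(zn)
  # y lies in the IJ/C7/mid plane by construction, so y and z are orthogonal
  x <- cross3(y, z)
  new_frame(ij, x, y, z)
}

#' Scapular anatomical frame (ISB)
#'
#' Origin at the acromial angle AA; Z along TS -> AA pointing laterally
#' (to the right, after left-shoulder mirroring); X perpendicular to the
#' scapular plane through AI, AA, TS pointing forward (ordering
#' `(AI - AA) x (TS - AA)`); Y = Z x X pointing up.
#'
#' @param AA,TS,AI acromial angle, root of the scapular spine and inferior
#'   angle, length-3 numeric (mm, world, right-side convention).
#' @return An [new_frame()] object.
#' @export
build_scapula_frame <- function(AA, TS, AI) {
  AA <- as_point3(AA, "AA"); TS <- as_point3(TS, "TS"); AI <- as_point3(AI, "AI")
  z <- unitize(AA - TS, "scapula Z (TS->AA)")
  xn <- cross3(AI - AA, TS - AA)
  if (vnorm(xn) < DEGENERACY_TOL) {
    sta_error("sta_degenerate_geometry_error", "AA, TS, AI are collinear")
  }
  x <- xn / vnorm(xn)   # perpendicular to the scapular plane, Z in-plane => x _|_ z
  y <- cross3(z, x)
  new_frame(AA, x, y, z)
}

#' Humeral anatomical frame (ISB)
#'
#' Origin at the humeral-head center GH (given directly or recovered by
#' [fit_sphere()] from head-surface points named `HH*`); Y from the
#' epicondyle midpoint up to GH; X perpendicular to the EL/EM/GH plane
#' pointing forward (ordering `(EL - GH) x (EM - GH)`); Z = X x Y pointing
#' right.
#'
#' @param lm a humerus [landmark_set()] (right-side convention).
#' @return An [new_frame()] object.
#' @export
build_humerus_frame <- function(lm) {
  el <- lm_point(lm, "EL"); em <- lm_point(lm, "EM")
  if ("GH" %in% rownames(lm)) {
    gh <- lm_point(lm, "GH")
  } else {
    head_pts <- lm[startsWith(rownames(lm), "HH"), , drop = FALSE]
    gh <- fit_sphere(head_pts)$center
  }
  y <- unitize(gh - (el + em) / 2, "humerus Y (shaft line)")
  xn <- cross3(el - gh, em - gh)
  if (vnorm(xn) < DEGENERACY_TOL) {
    sta_error("sta_degenerate_geometry_error", "GH, EL, EM are collinear")
  }
  x <- xn / vnorm(xn)
  # x is normal to the EL/EM/GH plane and y lies in it, hence orthogonal
  z <- cross3(x, y)
  new_frame(gh, x, y, z)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to n >= 4 non-coplanar points by the algebraic linear
#' formulation: writing |p|^2 = 2 p . c + (r^2 - |c|^2) gives an
#' overdetermined linear system in the center c and an intercept, solved by
#' QR least squares. Exact on noiseless spherical data. An optional
#' geometric refinement minimizes the sum of squared radial residuals.
#'
#' @param points matrix with 3 columns (or list of length-3 vectors), mm.
#' @param refine logical; if `TRUE`, polish the algebraic solution with a
#'   geometric (Gauss-Newton via `stats::nlm`) refinement. Default `FALSE`
#'   for determinism.
#' @return list with `center` (length-3, mm) and `radius` (mm).
#' @export
fit_sphere <- function(points, refine = FALSE) {
  if (is.list(points)) points <- do.call(rbind, lapply(points, as_point3))
  points <- unclass(as.matrix(points))
  attr(points, "bone") <- NULL; attr(points, "side") <- NULL
  if (nrow(points) < 4L) {
    sta_error("sta_degenerate_geometry_error", "sphere fit needs >= 4 points, got %d", nrow(points))
  }
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4L) {
    sta_error("sta_degenerate_geometry_error", "sphere fit: points are coplanar or degenerate")
  }
  sol <- qr.coef(qrA, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) {
    sta_error("sta_degenerate_geometry_error", "sphere fit produced non-positive radius")
  }
  radius <- sqrt(r2)
  if (refine) {
    obj <- function(par) {
      d <- sqrt(rowSums((points - rep(par[1:3], each = nrow(points)))^2))
      sum((d - par[4])^2)
    }
    opt <- stats::nlm(obj, c(center, radius), gradtol = 1e-12, steptol = 1e-12)
    center <- opt$estimate[1:3]
    radius <- opt$estimate[4]
  }
  list(center = as.numeric(center), radius = as.numeric(radius))
}

#' Express a world point in frame coordinates
#'
#' `world_to_frame()` returns the coordinates of `p` in frame `f`:
#' `t(axes) %*% (p - origin)`. `frame_to_world()` is the exact inverse.
#'
#' @param p length-3 numeric (mm) or an n x 3 matrix of points.
#' @param f an `sta_frame`.
#' @return coordinates with the same shape as `p`.
#' @export
world_to_frame <- function(p, f) {
  stopifnot(is_frame(f))
  if (is.matrix(p)) {
    return(sweep(p, 2L, f$origin) %*% f$axes)
  }
  as.numeric(crossprod(f$axes, as_point3(p) - f$origin))
}

#' @rdname world_to_frame
#' @export
frame_to_world <- function(p, f) {
  stopifnot(is_frame(f))
  if (is.matrix(p)) {
    return(sweep(p %*% t(f$axes), 2L, -f$origin))
  }
  as.numeric(f$axes %*% as_point3(p) + f$origin)
}

#' Mirror a left-shoulder landmark set to the right-side convention
#'
#' ISB axis polarities (Z lateral, X forward) are stated for right shoulders.
#' Left-shoulder data are reflected through the sagittal plane by negating
#' the world Z coordinate (the lab axis pointing to the subject's right) of
#' every point; the set is then relabelled as right-sided. Applying the
#' function twice restores the original left-sided coordinates (a mirrored
#' set remembers its provenance). Calling this on genuinely right-sided
#' data is a no-op with a warning.
#'
#' @param lm a [landmark_set()].
#' @param axis index of the world mediolateral axis (default 3, i.e. Z).
#' @return the mirrored `landmark_set`, side `"right"`.
#' @export
mirror_left_to_right <- function(lm, axis = 3L) {
  stopifnot(inherits(lm, "landmark_set"))
  if (attr(lm, "side") == "right" && !isTRUE(attr(lm, "mirrored"))) {
    warning("mirror_left_to_right() called on right-side data; returning unchanged")
    return(lm)
  }
  undo <- isTRUE(attr(lm, "mirrored"))
  pts <- unclass(lm)
  attr(pts, "mirrored") <- NULL
  pts[, axis] <- -pts[, axis]
  out <- landmark_set(pts, bone = attr(lm, "bone"),
                      side = if (undo) "left" else "right")
  if (!undo) attr(out, "mirrored") <- TRUE
  out
}
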