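# Skin-marker displacement in the bone-fixed scapular frame.
#
# Expressing a marker's position in the scapular frame of its own pose and
# differencing across poses is equivalent to superimposing the (rigid)
# scapula of the two poses and measuring the marker translation — no
# explicit surface registration is needed.

SCAPULAR_MARKERS <- c("AA", "TS", "AI")

#' Marker center from a segmented marker mesh
#'
#' Spherical skin markers are segmented from CT as surface meshes; the
#' marker center is recovered by a least-squares sphere fit to the mesh
#' vertices ([fit_sphere()]), which stays unbiased when the skin-facing side
#' of the marker is occluded (a centroid would be pulled toward the visible
#' cap). Falls back to the vertex centroid, with a warning, if the fit is
#' degenerate (e.g. a flattened patch).
#'
#' @param vertices n x 3 matrix (or list of length-3 vectors) of mesh
#'   vertices, mm.
#' @return length-3 numeric center, mm.
#' @export
marker_center_from_mesh <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as_point3))
  vertices <- as.matrix(vertices)
  if (nrow(vertices) == 0L) {
    sta_error("sta_validation_error", "empty vertex set")
  }
  if (nrow(vertices) < 4L) {
    sta_error("sta_degenerate_geometry_error",
              "marker center needs >= 4 vertices, got %d", nrow(vertices))
  }
  tryCatch(fit_sphere(vertices)$center, sta_degenerate_geometry_error = function(e) {
    warning("sphere fit degenerate (", conditionMessage(e),
            "); falling back to vertex centroid")
    colMeans(vertices)
  })
}

#' Displacement of one skin marker in the bone-fixed scapular frame
#'
#' The marker center of each pose is expressed in the bone-based scapular
#' frame of the same pose; the displacement is the difference
#' elevated - reference of those frame coordinates. Components follow the
#' scapular axes: anterior = +X, superior = +Y, lateral = +Z (right-side
#' convention; left shoulders must be mirrored first, so "lateral" is +Z
#' for every shoulder). `total` is the Euclidean norm
#' `sqrt((Xe-Xr)^2 + (Ye-Yr)^2 + (Ze-Zr)^2)`.
#'
#' @param marker_ref,marker_elev marker center, world mm, reference and
#'   elevated pose.
#' @param scap_frame_ref,scap_frame_elev bone-based scapular `sta_frame` of
#'   the matching pose.
#' @return list with `ref` and `elev` scapular-frame coordinates plus
#'   `anterior`, `superior`, `lateral`, `total` (mm).
#' @export
displacement_in_scapular_frame <- function(marker_ref, marker_elev,
                                           scap_frame_ref, scap_frame_elev) {
  r <- world_to_frame(marker_ref, scap_frame_ref)
  e <- world_to_frame(marker_elev, scap_frame_elev)
  d <- e - r
  list(ref = r, elev = e,
       anterior = d[1L], superior = d[2L], lateral = d[3L],
       total = vnorm(d))
}

#' Displacement table for a cohort
#'
#' One row per (shoulder, landmark): the AA, TS and AI skin-marker
#' displacements in the bone-fixed scapular frame for every shoulder of a
#' cohort. Shoulders with a missing marker get that row flagged
#' (`complete = FALSE`, displacement NA) and a message is logged; flagged
#' rows are excluded from downstream statistics.
#'
#' @param shoulders a list of shoulder records (see [pose_cohort()] /
#'   [read_landmarks()]).
#' @return `data.frame` with columns `subject_id`, `side`, `landmark`,
#'   `anterior_mm`, `superior_mm`, `lateral_mm`, `total_mm`, `complete`,
#'   ordered by shoulder then landmark (AA, TS, AI).
#' @export
cohort_displacements <- function(shoulders) {
  rows <- vector("list", length(shoulders) * 3L)
  k <- 0L
  for (sh in shoulders) {
    sh <- normalize_shoulder(sh)
    frames <- shoulder_scapula_frames(sh)
    for (lmk in SCAPULAR_MARKERS) {
      k <- k + 1L
      ok <- lmk %in% rownames(sh$poses$reference$markers) &&
        lmk %in% rownames(sh$poses$elevated$markers)
      if (ok) {
        d <- displacement_in_scapular_frame(
          lm_point(sh$poses$reference$markers, lmk),
          lm_point(sh$poses$elevated$markers, lmk),
          frames$reference, frames$elevated)
        rows[[k]] <- data.frame(
          subject_id = sh$subject_id, side = sh$side, landmark = lmk,
          anterior_mm = d$anterior, superior_mm = d$superior,
          lateral_mm = d$lateral, total_mm = d$total, complete = TRUE,
          stringsAsFactors = FALSE)
      } else {
        message("shoulder ", sh$subject_id, "/", sh$side,
                ": marker ", lmk, " missing; row flagged")
        rows[[k]] <- data.frame(
          subject_id = sh$subject_id, side = sh$side, landmark = lmk,
          anterior_mm = NA_real_, superior_mm = NA_real_,
          lateral_mm = NA_real_, total_mm = NA_real_, complete = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(subject_id = character(), side = character(),
                      landmark = character(), anterior_mm = numeric(),
                      superior_mm = numeric(), lateral_mm = numeric(),
                      total_mm = numeric(), complete = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Mirror a shoulder record to the right-side convention if needed.
normalize_shoulder <- function(sh) {
  if (identical(sh$side, "left")) {
    for (pose in names(sh$poses)) {
      sh$poses[[pose]] <- lapply(sh$poses[[pose]], mirror_left_to_right)
    }
    sh$side_analyzed <- "right(mirrored)"
  }
  sh
}

shoulder_scapula_frames <- function(sh) {
  lapply(sh$poses, function(p) {
    build_scapula_frame(lm_point(p$scapula, "AA"), lm_point(p$scapula, "TS"),
                        lm_point(p$scapula, "AI"))
  })
}
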