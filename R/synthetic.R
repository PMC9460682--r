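# Synthetic two-pose cohorts with planted bone kinematics and planted
# soft-tissue artifact.
#
# The generator builds each shoulder from a fixed template anatomy whose
# local landmark coordinates are chosen so that the anatomical frame built
# from them is the identity; posing the bone with a rotation R therefore
# yields a constructed frame with axes exactly R, and planted angles are
# recovered exactly by the analysis pipeline when noise is zero.

#' Template anatomy
#'
#' A fixed, plausible adult-male landmark geometry (mm) for a right
#' shoulder, expressed in the ISB world convention (+X forward, +Y up,
#' +Z right) with the thorax frame equal to the world frame and the
#' scapula/humerus given in their own anatomical frames (so that frames
#' built from the local coordinates are identity frames):
#' inter-landmark scales are anatomical (AA-TS 110 mm, AA-AI ~145 mm,
#' humeral shaft 300 mm, humeral head radius 25 mm). Deterministic:
#' repeated calls are identical.
#'
#' @param head_points number of humeral-head surface points to include
#'   (names `HH1..`), spread over the superior hemisphere; 0 omits them.
#' @return list with `thorax`, `scapula_local`, `humerus_local` matrices
#'   and `head_radius`.
#' @export
make_template_anatomy <- function(head_points = 12L) {
  thorax <- rbind(IJ = c(0, 0, 0), C7 = c(-60, 20, 0),
                  PX = c(20, -150, 0), T8 = c(-80, -130, 0))
  scapula_local <- rbind(AA = c(0, 0, 0), TS = c(0, 0, -110),
                         AI = c(0, -120, -80))
  humerus_local <- rbind(GH = c(0, 0, 0), EL = c(0, -300, 25),
                         EM = c(0, -300, -25))
  r <- 25
  if (head_points > 0L) {
    i <- seq_len(head_points)
    # deterministic spiral on the superior hemisphere of the head sphere
    phi <- acos(1 - i / (head_points + 1))       # polar angle from +Y
    theta <- i * pi * (3 - sqrt(5))              # golden-angle azimuth
    hh <- cbind(r * sin(phi) * cos(theta), r * cos(phi), r * sin(phi) * sin(theta))
    rownames(hh) <- paste0("HH", i)
    humerus_local <- rbind(humerus_local, hh)
  }
  colnames(thorax) <- colnames(scapula_local) <- colnames(humerus_local) <-
    c("x", "y", "z")
  list(thorax = thorax, scapula_local = scapula_local,
       humerus_local = humerus_local, head_radius = r)
}

#' Soft-tissue-artifact model
#'
#' Per-landmark mean displacement vectors (anterior, superior, lateral; mm,
#' in the elevated-pose scapular frame) and per-landmark 3x3 covariance of
#' the between-shoulder variation, plus an isotropic landmark-identification
#' noise standard deviation applied to every landmark coordinate.
#'
#' @param mean named list AA/TS/AI of length-3 numeric (mm).
#' @param cov named list AA/TS/AI of 3x3 symmetric PSD matrices (mm^2).
#' @param noise_sd landmark noise sd, mm.
#' @return list of class `"sta_model"`.
#' @export
sta_model <- function(mean, cov, noise_sd = 0) {
  stopifnot(setequal(names(mean), SCAPULAR_MARKERS),
            setequal(names(cov), SCAPULAR_MARKERS), noise_sd >= 0)
  for (lmk in SCAPULAR_MARKERS) {
    mean[[lmk]] <- as_point3(mean[[lmk]], paste0(lmk, " mean displacement"))
    S <- as.matrix(cov[[lmk]])
    if (any(dim(S) != 3L) || max(abs(S - t(S))) > 1e-9 ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
      sta_error("sta_validation_error", "%s covariance must be symmetric PSD", lmk)
    }
    cov[[lmk]] <- S
  }
  structure(list(mean = mean, cov = cov, noise_sd = noise_sd),
            class = "sta_model")
}

zero_sta_model <- function(noise_sd = 0) {
  z <- stats::setNames(lapply(SCAPULAR_MARKERS, function(i) c(0, 0, 0)),
                       SCAPULAR_MARKERS)
  zc <- stats::setNames(lapply(SCAPULAR_MARKERS, function(i) diag(0, 3)),
                        SCAPULAR_MARKERS)
  sta_model(z, zc, noise_sd)
}

#' Cohort specification
#'
#' All tunable parameters of the synthetic two-pose cohort. Defaults are
#' deliberately neutral (zero STA, zero noise); [default_study_spec()]
#' carries the study-emulating values.
#'
#' @param n_shoulders cohort size (shoulders; two consecutive shoulders
#'   share a subject and a BMI).
#' @param seed RNG seed for the draw.
#' @param ref_angles,elev_angles named length-3 numeric mean scapulothoracic
#'   angles per pose: `upward_rotation`, `internal_rotation`,
#'   `posterior_tilt` (deg; anterior tilt is negative).
#' @param angle_sd named length-3 per-component between-shoulder sd for each
#'   pose: list(reference=, elevated=) (deg).
#' @param ht_elevation,ht_elevation_sd mean and sd humerothoracic elevation
#'   per pose (deg), named reference/elevated.
#' @param sta an [sta_model()].
#' @param bmi_mean,bmi_sd cohort BMI distribution (kg/m^2).
#' @param bmi_slope fractional change of the AA mean displacement per unit
#'   BMI above `bmi_mean` (larger physique, larger acromial artifact).
#' @param alternate_sides if `TRUE`, odd shoulders are right, even are left
#'   (mirrored world data).
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_shoulders = 20L,
                        seed = 20220829L,
                        ref_angles = c(upward_rotation = 2.2,
                                       internal_rotation = 29.5,
                                       posterior_tilt = -8.8),
                        elev_angles = c(upward_rotation = 40.5,
                                        internal_rotation = 42.3,
                                        posterior_tilt = 21.3),
                        angle_sd = list(
                          reference = c(upward_rotation = 4.2,
                                        internal_rotation = 5.4,
                                        posterior_tilt = 4.2),
                          elevated = c(upward_rotation = 8.5,
                                       internal_rotation = 6.8,
                                       posterior_tilt = 5.8)),
                        ht_elevation = c(reference = 4.3, elevated = 146.1),
                        ht_elevation_sd = c(reference = 2.2, elevated = 4.5),
                        sta = zero_sta_model(),
                        bmi_mean = 22.2, bmi_sd = 1.4,
                        bmi_slope = 0,
                        alternate_sides = TRUE) {
  if (n_shoulders < 1L) sta_error("sta_validation_error", "n_shoulders must be >= 1")
  stopifnot(inherits(sta, "sta_model"), bmi_sd >= 0,
            all(unlist(angle_sd) >= 0), all(ht_elevation_sd >= 0))
  structure(list(n_shoulders = as.integer(n_shoulders), seed = as.integer(seed),
                 ref_angles = ref_angles, elev_angles = elev_angles,
                 angle_sd = angle_sd, ht_elevation = ht_elevation,
                 ht_elevation_sd = ht_elevation_sd, sta = sta,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_slope = bmi_slope,
                 alternate_sides = alternate_sides),
            class = "cohort_spec")
}

#' Study-emulating cohort specification
#'
#' The default synthetic world: n = 20 shoulders (10 subjects, alternating
#' sides); bone kinematics drawn around the cohort mean scapulothoracic and
#' humerothoracic angles with their reported between-shoulder sd; STA mean
#' displacement vectors set to the reported directional medians
#' (AA +16.7/+24.5/+0.7, TS +16.7/+42.7/+21.6, AI -12.1/+58.7/-22.5 mm in
#' anterior/superior/lateral) with independent per-component dispersion
#' derived from the reported interquartile ranges (sd = IQR/1.349, the
#' Gaussian width matching that IQR); landmark noise 0.5 mm (CT voxel
#' scale); a linear BMI link on the AA displacement magnitude
#' (`bmi_slope` = 0.11 per kg/m^2) sized to give a rank correlation around
#' 0.7 at n = 20.
#'
#' @param n_shoulders cohort size, default 20.
#' @param seed RNG seed, default 20220829.
#' @return a [cohort_spec()].
#' @export
default_study_spec <- function(n_shoulders = 20L, seed = 20220829L) {
  iqr_sd <- function(w) w / (2 * stats::qnorm(0.75))   # IQR -> Gaussian sd
  means <- list(AA = c(16.7, 24.5, 0.7),
                TS = c(16.7, 42.7, 21.6),
                AI = c(-12.1, 58.7, -22.5))
  iqr_w <- list(AA = c(19.3 - 14.0, 27.2 - 20.6, 4.4 - (-3.5)),
                TS = c(23.2 - 10.9, 47.4 - 38.5, 27.9 - 15.3),
                AI = c(14.6 - 1.5, 69.2 - 52.3, 30.6 - 10.3))
  covs <- lapply(iqr_w, function(w) diag(iqr_sd(w)^2))
  cohort_spec(n_shoulders = n_shoulders, seed = seed,
              sta = sta_model(means, covs, noise_sd = 0.5),
              bmi_slope = 0.11)
}

# Draw from N(mean, cov) given the (possibly rank-deficient) covariance.
mvn_draw <- function(mean, cov) {
  ev <- eigen(cov, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3L)
  as.numeric(mean + L %*% stats::rnorm(3L))
}

#' Generate a synthetic two-pose cohort
#'
#' For each shoulder: draws per-shoulder bone angles around the spec means,
#' poses the template scapula and humerus in both arm positions, places
#' reference-pose skin markers exactly on the bony landmarks and elevated-
#' pose markers at the bony landmark plus an STA displacement drawn from the
#' [sta_model()] and expressed along the elevated-pose scapular axes (the
#' planted vector is therefore exactly what the analysis pipeline measures),
#' applies isotropic landmark noise, and — when `alternate_sides` — mirrors
#' even-numbered shoulders into left-sided world coordinates.
#'
#' STA lives only in the elevated pose: the measurement is a between-pose
#' difference, so only that difference is identifiable, and planting it in
#' one pose makes planted values equal expected measurements.
#'
#' @param spec a [cohort_spec()].
#' @return list of shoulder records; each has `subject_id`, `side`, `bmi`,
#'   `planted` (angles and STA vectors) and `poses$reference` /
#'   `poses$elevated`, each a list of `landmark_set`s
#'   (`thorax`, `humerus`, `scapula`, `markers`).
#' @export
pose_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- make_template_anatomy()
  set.seed(spec$seed)
  shoulders <- vector("list", spec$n_shoulders)
  n_subjects <- ceiling(spec$n_shoulders / 2)
  bmis <- stats::rnorm(n_subjects, spec$bmi_mean, spec$bmi_sd)
  for (i in seq_len(spec$n_shoulders)) {
    subject <- (i + 1L) %/% 2L
    side <- if (spec$alternate_sides && i %% 2L == 0L) "left" else "right"
    bmi <- bmis[subject]
    # per-shoulder bone kinematics
    ang <- list(
      reference = spec$ref_angles + stats::rnorm(3L) * spec$angle_sd$reference,
      elevated  = spec$elev_angles + stats::rnorm(3L) * spec$angle_sd$elevated)
    ht <- c(reference = spec$ht_elevation[["reference"]] +
              stats::rnorm(1L) * spec$ht_elevation_sd[["reference"]],
            elevated = spec$ht_elevation[["elevated"]] +
              stats::rnorm(1L) * spec$ht_elevation_sd[["elevated"]])
    # planted STA draws (elevated pose, scapular-frame components)
    bmi_gain <- 1 + spec$bmi_slope * (bmi - spec$bmi_mean)
    sta_draw <- lapply(SCAPULAR_MARKERS, function(lmk) {
      m <- spec$sta$mean[[lmk]]
      if (lmk == "AA") m <- m * bmi_gain
      mvn_draw(m, spec$sta$cov[[lmk]])
    })
    names(sta_draw) <- SCAPULAR_MARKERS
    poses <- list()
    for (pose in c("reference", "elevated")) {
      R_st <- scapulothoracic_rotation(ang[[pose]][["upward_rotation"]],
                                       ang[[pose]][["internal_rotation"]],
                                       ang[[pose]][["posterior_tilt"]])
      R_ht <- rot_x(-ht[[pose]])
      aa_origin <- if (pose == "reference") c(-30, 10, 170) else c(-20, 40, 175)
      gh_origin <- if (pose == "reference") c(0, -20, 190) else c(5, 10, 195)
      scap_world <- sweep(tpl$scapula_local %*% t(R_st), 2L, -aa_origin)
      hum_world <- sweep(tpl$humerus_local %*% t(R_ht), 2L, -gh_origin)
      rownames(scap_world) <- rownames(tpl$scapula_local)
      rownames(hum_world) <- rownames(tpl$humerus_local)
      markers <- scap_world[SCAPULAR_MARKERS, , drop = FALSE]
      if (pose == "elevated") {
        for (lmk in SCAPULAR_MARKERS) {
          markers[lmk, ] <- markers[lmk, ] + as.numeric(R_st %*% sta_draw[[lmk]])
        }
      }
      sets <- list(thorax = tpl$thorax, humerus = hum_world,
                   scapula = scap_world, markers = markers)
      if (spec$sta$noise_sd > 0) {
        sets <- lapply(sets, function(m) {
          m + matrix(stats::rnorm(length(m), 0, spec$sta$noise_sd), nrow(m), 3L)
        })
      }
      if (side == "left") {
        sets <- lapply(sets, function(m) { m[, 3L] <- -m[, 3L]; m })
      }
      poses[[pose]] <- list(
        thorax = landmark_set(sets$thorax, "thorax", side),
        humerus = landmark_set(sets$humerus, "humerus", side),
        scapula = landmark_set(sets$scapula, "scapula", side),
        markers = landmark_set(sets$markers, "markers", side))
    }
    shoulders[[i]] <- list(
      subject_id = sprintf("S%02d", subject), side = side, bmi = bmi,
      planted = list(angles = ang, ht_elevation = ht, sta = sta_draw),
      poses = poses)
  }
  shoulders
}
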