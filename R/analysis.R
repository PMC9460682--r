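# Cohort-level orchestration: frames -> displacements -> angles -> statistics.

#' Per-shoulder angle table
#'
#' Builds the thorax, humerus and (bone- and marker-based) scapular frames
#' of both poses for every shoulder and returns the scapulothoracic angles
#' and humerothoracic elevation. Left shoulders are mirrored to the
#' right-side convention first, so angle signs share one convention.
#'
#' @param shoulders list of shoulder records ([pose_cohort()] /
#'   [read_landmarks()]).
#' @return `data.frame` with columns `subject_id`, `side`, `pose`, `basis`
#'   (`bone` or `marker`), `upward_rotation_deg`, `internal_rotation_deg`,
#'   `posterior_tilt_deg`, `ht_elevation_deg`.
#' @export
cohort_angles <- function(shoulders) {
  rows <- list()
  for (sh in shoulders) {
    sh <- normalize_shoulder(sh)
    for (pose in c("reference", "elevated")) {
      p <- sh$poses[[pose]]
      thx <- build_thorax_frame(p$thorax)
      hum <- build_humerus_frame(p$humerus)
      ht <- humerothoracic_elevation(hum, thx)
      bone_frame <- build_scapula_frame(lm_point(p$scapula, "AA"),
                                        lm_point(p$scapula, "TS"),
                                        lm_point(p$scapula, "AI"))
      bases <- list(bone = bone_frame, marker = marker_based_frame(p$markers))
      for (basis in names(bases)) {
        a <- scapulothoracic_angles(bases[[basis]], thx)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sh$subject_id, side = sh$side, pose = pose,
          basis = basis,
          upward_rotation_deg = a[["upward_rotation"]],
          internal_rotation_deg = a[["internal_rotation"]],
          posterior_tilt_deg = a[["posterior_tilt"]],
          ht_elevation_deg = ht, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(subject_id = character(), side = character(),
                      pose = character(), basis = character(),
                      upward_rotation_deg = numeric(),
                      internal_rotation_deg = numeric(),
                      posterior_tilt_deg = numeric(),
                      ht_elevation_deg = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

angle_components <- c("upward_rotation_deg", "internal_rotation_deg",
                      "posterior_tilt_deg")

#' Full cohort analysis
#'
#' Runs the whole measurement and statistics pipeline on a cohort:
#' displacement table, angle table, normality-gated descriptives, the
#' Friedman + Bonferroni-Wilcoxon landmark comparison (totals and each
#' direction), paired t-tests of bone- vs marker-based angles per component
#' and pose, the 3 x 3 Spearman matrix of displacement totals against
#' elevated-pose bone-minus-marker angle differences, and (when BMI is
#' available) Spearman correlations of displacement totals with BMI.
#'
#' @param shoulders list of shoulder records.
#' @param alpha significance level for all tests (default 0.05).
#' @return list of class `"sta_analysis"`: `displacements`, `angles`,
#'   `descriptives`, `landmark_tests`, `angle_tests`, `correlations`,
#'   `bmi_correlations`, `alpha`, `n_shoulders`.
#' @export
analyze_cohort <- function(shoulders, alpha = 0.05) {
  disp <- cohort_displacements(shoulders)
  ang <- cohort_angles(shoulders)
  ok <- disp[disp$complete, , drop = FALSE]
  key <- function(df) paste(df$subject_id, df$side)

  measures <- c(total = "total_mm", anterior = "anterior_mm",
                superior = "superior_mm", lateral = "lateral_mm")
  descriptives <- list()
  landmark_tests <- list()
  for (m in names(measures)) {
    col <- measures[[m]]
    per_lmk <- split(ok[[col]], ok$landmark)[SCAPULAR_MARKERS]
    descriptives[[m]] <- lapply(per_lmk, describe, alpha = alpha)
    shoulders_complete <- Reduce(intersect, lapply(
      split(key(ok), ok$landmark)[SCAPULAR_MARKERS], unique))
    paired <- lapply(SCAPULAR_MARKERS, function(lmk) {
      sub <- ok[ok$landmark == lmk, , drop = FALSE]
      sub[[col]][match(shoulders_complete, key(sub))]
    })
    names(paired) <- SCAPULAR_MARKERS
    landmark_tests[[m]] <- tryCatch(
      compare_three_landmarks(paired$AA, paired$TS, paired$AI, alpha = alpha),
      sta_validation_error = function(e) {
        list(friedman = list(statistic = NA_real_, df = 2L, p = NA_real_),
             pairwise = NULL, note = conditionMessage(e))
      })
  }

  # bone vs marker angles, per component and pose
  angle_tests <- list()
  for (pose in c("reference", "elevated")) {
    for (comp in angle_components) {
      bone <- ang[ang$pose == pose & ang$basis == "bone", ]
      mark <- ang[ang$pose == pose & ang$basis == "marker", ]
      mark <- mark[match(key(bone), key(mark)), ]
      res <- tryCatch(paired_t(bone[[comp]], mark[[comp]]),
                      sta_validation_error = function(e) {
                        list(mean_diff = mean(bone[[comp]] - mark[[comp]]),
                             sd_diff = stats::sd(bone[[comp]] - mark[[comp]]),
                             n = nrow(bone), statistic = NA_real_,
                             df = nrow(bone) - 1L, p = NA_real_,
                             note = conditionMessage(e))
                      })
      angle_tests[[pose]][[comp]] <- res
    }
  }

  # elevated-pose angle differences (bone - marker) per shoulder
  bone_e <- ang[ang$pose == "elevated" & ang$basis == "bone", ]
  mark_e <- ang[ang$pose == "elevated" & ang$basis == "marker", ]
  mark_e <- mark_e[match(key(bone_e), key(mark_e)), ]
  diffs <- lapply(angle_components, function(comp) bone_e[[comp]] - mark_e[[comp]])
  names(diffs) <- angle_components

  correlations <- list()
  for (lmk in SCAPULAR_MARKERS) {
    sub <- ok[ok$landmark == lmk, , drop = FALSE]
    idx <- match(key(bone_e), key(sub))
    tot <- sub$total_mm[idx]
    correlations[[lmk]] <- lapply(diffs, function(d) {
      keep <- is.finite(tot) & is.finite(d)
      if (sum(keep) < 5L) return(list(rho = NA_real_, p = NA_real_, n = sum(keep)))
      tryCatch(spearman_rank(tot[keep], d[keep]),
               sta_validation_error = function(e) {
                 list(rho = NA_real_, p = NA_real_, n = sum(keep),
                      note = conditionMessage(e))
               })
    })
  }

  bmi <- vapply(shoulders, function(sh) {
    if (is.null(sh$bmi)) NA_real_ else sh$bmi
  }, numeric(1))
  names(bmi) <- vapply(shoulders, function(sh) paste(sh$subject_id, sh$side),
                       character(1))
  bmi_correlations <- NULL
  if (all(is.finite(bmi))) {
    bmi_correlations <- lapply(SCAPULAR_MARKERS, function(lmk) {
      sub <- ok[ok$landmark == lmk, , drop = FALSE]
      tryCatch(spearman_rank(sub$total_mm, bmi[key(sub)]),
               sta_validation_error = function(e) {
                 list(rho = NA_real_, p = NA_real_, n = nrow(sub),
                      note = conditionMessage(e))
               })
    })
    names(bmi_correlations) <- SCAPULAR_MARKERS
  }

  structure(list(displacements = disp, angles = ang,
                 descriptives = descriptives, landmark_tests = landmark_tests,
                 angle_tests = angle_tests, correlations = correlations,
                 bmi_correlations = bmi_correlations, alpha = alpha,
                 n_shoulders = length(shoulders)),
            class = "sta_analysis")
}

#' @export
print.sta_analysis <- function(x, ...) {
  cat("<sta_analysis>", x$n_shoulders, "shoulders,",
      sum(x$displacements$complete), "complete marker rows\n")
  td <- x$descriptives$total
  for (lmk in names(td)) {
    d <- td[[lmk]]
    cat(sprintf("  %s total movement: median %.1f (IQR %.1f-%.1f) mm%s\n",
                lmk, d$median, d$q1, d$q3,
                if (d$normal) sprintf(", mean %.1f +/- %.1f", d$mean, d$sd) else ""))
  }
  cat(sprintf("  Friedman (totals): chi2 = %.2f, p = %.3g\n",
              x$landmark_tests$total$friedman$statistic,
              x$landmark_tests$total$friedman$p))
  invisible(x)
}
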