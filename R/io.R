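# File I/O: landmark CSV/JSON dialect, STL marker meshes, report bundles,
# and the pipeline orchestrator.
#
# Landmark file schema (CSV or the JSON equivalent): one row per landmark,
# columns subject_id, side {left|right}, pose {reference|elevated},
# bone {thorax|humerus|scapula|markers}, landmark, x_mm, y_mm, z_mm.
# World frame: lab-fixed, +x forward, +y up, +z to the subject's right.

LANDMARK_COLUMNS <- c("subject_id", "side", "pose", "bone", "landmark",
                      "x_mm", "y_mm", "z_mm")
LANDMARK_VOCAB <- list(
  thorax = c("IJ", "C7", "PX", "T8"),
  scapula = c("AA", "TS", "AI"),
  markers = c("AA", "TS", "AI"),
  humerus = c("GH", "EL", "EM", paste0("HH", 1:512)))

#' Read a landmark file into shoulder records
#'
#' Accepts the CSV dialect above or a JSON array of the same records.
#' Rows are validated (columns, vocabulary, duplicates, finite coordinates)
#' and grouped into one record per (subject, side) with `reference` and
#' `elevated` poses. A shoulder whose marker set is incomplete is kept but
#' flagged downstream; a shoulder missing a whole bone or pose is dropped
#' with a warning.
#'
#' @param path CSV or JSON landmark file.
#' @param subjects_path optional CSV with columns `subject_id`, `bmi`.
#' @return list of shoulder records (as produced by [pose_cohort()], minus
#'   the `planted` element).
#' @export
read_landmarks <- function(path, subjects_path = NULL) {
  if (!file.exists(path)) sta_error("sta_io_error", "file not found: %s", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(LANDMARK_COLUMNS, names(df))
  if (length(missing_cols)) {
    sta_error("sta_io_error", "landmark file missing columns: %s",
              paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!(row$bone %in% names(LANDMARK_VOCAB))) {
      sta_error("sta_io_error", "row %d: unknown bone '%s' (allowed: %s)",
                i, row$bone, paste(names(LANDMARK_VOCAB), collapse = ", "))
    }
    if (!(row$landmark %in% LANDMARK_VOCAB[[row$bone]])) {
      allowed <- LANDMARK_VOCAB[[row$bone]]
      if (row$bone == "humerus") allowed <- c("GH", "EL", "EM", "HH<k>")
      sta_error("sta_io_error", "row %d: unknown %s landmark '%s' (allowed: %s)",
                i, row$bone, row$landmark, paste(allowed, collapse = ", "))
    }
    if (!(row$pose %in% c("reference", "elevated"))) {
      sta_error("sta_io_error", "row %d: field 'pose' must be reference|elevated, got '%s'",
                i, row$pose)
    }
    if (!(row$side %in% c("left", "right"))) {
      sta_error("sta_io_error", "row %d: field 'side' must be left|right, got '%s'",
                i, row$side)
    }
    if (any(!is.finite(c(row$x_mm, row$y_mm, row$z_mm)))) {
      sta_error("sta_io_error", "row %d: non-finite coordinate", i)
    }
  }
  dup_key <- paste(df$subject_id, df$side, df$pose, df$bone, df$landmark)
  if (anyDuplicated(dup_key)) {
    sta_error("sta_io_error", "duplicate landmark row: %s",
              dup_key[anyDuplicated(dup_key)])
  }
  bmi_map <- NULL
  if (!is.null(subjects_path)) {
    subj <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "bmi") %in% names(subj))) {
      sta_error("sta_io_error", "subjects file needs columns subject_id, bmi")
    }
    bmi_map <- stats::setNames(subj$bmi, subj$subject_id)
  }
  shoulders <- list()
  for (k in unique(paste(df$subject_id, df$side))) {
    sub <- df[paste(df$subject_id, df$side) == k, , drop = FALSE]
    sid <- sub$subject_id[1L]; side <- sub$side[1L]
    poses <- list()
    complete <- TRUE
    for (pose in c("reference", "elevated")) {
      pp <- sub[sub$pose == pose, , drop = FALSE]
      sets <- list()
      for (bone in c("thorax", "humerus", "scapula", "markers")) {
        bb <- pp[pp$bone == bone, , drop = FALSE]
        if (!nrow(bb)) { complete <- FALSE; next }
        pts <- as.matrix(bb[, c("x_mm", "y_mm", "z_mm")])
        rownames(pts) <- bb$landmark
        sets[[bone]] <- tryCatch(landmark_set(pts, bone, side),
                                 sta_validation_error = function(e) {
          if (bone == "markers") {
            # incomplete marker set: keep what is there, flag downstream
            warning("shoulder ", sid, "/", side, " (", pose, "): ",
                    conditionMessage(e), "; rows will be flagged")
            structure(pts, bone = bone, side = side,
                      class = c("landmark_set", "matrix", "array"))
          } else {
            warning("shoulder ", sid, "/", side, " (", pose, "): ",
                    conditionMessage(e), "; shoulder dropped")
            NULL
          }
        })
        if (is.null(sets[[bone]])) complete <- FALSE
      }
      poses[[pose]] <- sets
    }
    if (!complete &&
        (length(poses) < 2L ||
         !all(vapply(poses, function(p) all(c("thorax", "humerus", "scapula",
                                              "markers") %in% names(p)), TRUE)))) {
      warning("shoulder ", sid, "/", side,
              ": incomplete bones or poses; shoulder dropped")
      next
    }
    shoulders[[length(shoulders) + 1L]] <- list(
      subject_id = sid, side = side,
      bmi = if (!is.null(bmi_map)) unname(bmi_map[sid]) else NULL,
      poses = poses)
  }
  shoulders
}

#' Write a cohort to the landmark CSV dialect
#'
#' Inverse of [read_landmarks()]; synthetic cohorts written this way
#' exercise the identical ingestion path as real data. Also writes a
#' `subjects` CSV (subject_id, bmi) next to it when BMI is present.
#'
#' @param shoulders list of shoulder records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(shoulders, path) {
  rows <- list()
  for (sh in shoulders) {
    for (pose in names(sh$poses)) {
      for (bone in names(sh$poses[[pose]])) {
        lm <- sh$poses[[pose]][[bone]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sh$subject_id, side = sh$side, pose = pose,
          bone = bone, landmark = rownames(lm),
          x_mm = unclass(lm)[, 1L], y_mm = unclass(lm)[, 2L],
          z_mm = unclass(lm)[, 3L], stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  bmis <- vapply(shoulders, function(s) if (is.null(s$bmi)) NA_real_ else s$bmi,
                 numeric(1))
  if (all(is.finite(bmis))) {
    subj <- unique(data.frame(
      subject_id = vapply(shoulders, `[[`, character(1), "subject_id"),
      bmi = bmis, stringsAsFactors = FALSE))
    utils::write.csv(subj, sub("\\.csv$", "_subjects.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read an STL surface mesh (ASCII or binary) as unique vertices
#'
#' Minimal STL reader for segmented marker meshes: detects the dialect,
#' parses the triangles and returns the de-duplicated vertex list for
#' [marker_center_from_mesh()].
#'
#' @param path STL file.
#' @param digits rounding used to merge duplicated vertices (default 9).
#' @return n x 3 numeric matrix of vertices, mm.
#' @export
read_marker_mesh <- function(path, digits = 9L) {
  if (!file.exists(path)) sta_error("sta_io_error", "file not found: %s", path)
  size <- file.info(path)$size
  if (size < 15) sta_error("sta_io_error", "malformed STL (%s): file too short (%d bytes)", path, size)
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = min(512, size))
  is_ascii <- grepl("^\\s*solid", rawToChar(head[seq_len(min(80, length(head)))])) &&
    !any(head == as.raw(0L))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vlines)) {
      sta_error("sta_io_error", "malformed ASCII STL (%s): no vertex lines", path)
    }
    parts <- strsplit(trimws(vlines), "\\s+")
    bad <- which(vapply(parts, length, 0L) != 4L)
    if (length(bad)) {
      sta_error("sta_io_error", "malformed ASCII STL (%s): bad vertex line %d", path, bad[1L])
    }
    verts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  } else {
    seek(con, 80L)
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    expected <- 84 + 50 * as.numeric(ntri)
    if (!length(ntri) || ntri < 0 || expected > size) {
      sta_error("sta_io_error",
                "malformed binary STL (%s): header at byte 80 declares %s triangles but file has %d bytes",
                path, ntri, size)
    }
    verts <- matrix(NA_real_, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)   # attribute byte count
      verts[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
  }
  if (any(!is.finite(verts))) {
    sta_error("sta_io_error", "malformed STL (%s): non-finite vertex", path)
  }
  unique(round(verts, digits))
}

#' Pipeline configuration
#'
#' @param input landmark CSV/JSON path, or `NULL` to simulate.
#' @param subjects optional subjects CSV path (BMI).
#' @param simulate a [cohort_spec()] used when `input` is `NULL`.
#' @param out_dir output directory for the report bundle.
#' @param seed RNG seed for the run (overrides the simulate spec's seed).
#' @param alpha significance level for all tests.
#' @param bonferroni_m Bonferroni multiplier (fixed at 3 pairwise landmark
#'   comparisons; retained for transparency).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, subjects = NULL, simulate = NULL,
                       out_dir = tempfile("scapsta_run_"), seed = 1L,
                       alpha = 0.05, bonferroni_m = 3L) {
  if (alpha <= 0 || alpha >= 1) sta_error("sta_validation_error", "alpha must be in (0,1)")
  if (bonferroni_m < 1L) sta_error("sta_validation_error", "bonferroni_m must be >= 1")
  if (is.null(input) && is.null(simulate)) simulate <- default_study_spec(seed = seed)
  structure(list(input = input, subjects = subjects, simulate = simulate,
                 out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
                 bonferroni_m = as.integer(bonferroni_m)),
            class = "run_config")
}

round_df <- function(df, digits = 9L) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full pipeline and write the report bundle
#'
#' Ingests (or simulates) a cohort, analyzes it and writes
#' `displacements.csv`, `angles.csv`, `stats.json`, `landmarks.csv` (the
#' analyzed cohort in the landmark dialect) and `run.log` to
#' `cfg$out_dir`. Outputs are deterministic: identical config + seed gives
#' byte-identical files (the log records the config hash, seed and package
#' version, never a timestamp).
#'
#' @param cfg a [run_config()].
#' @return the [analyze_cohort()] result, invisibly, with
#'   `attr(,"out_dir")` set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "setup"
  res <- tryCatch({
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    log_lines <- c(
      paste0("scapsta ", as.character(utils::packageVersion("scapsta"))),
      paste0("seed: ", cfg$seed),
      paste0("alpha: ", cfg$alpha))
    stage <- "ingest"
    if (!is.null(cfg$input)) {
      shoulders <- read_landmarks(cfg$input, cfg$subjects)
      log_lines <- c(log_lines, paste0("input: ", basename(cfg$input)))
    } else {
      spec <- cfg$simulate
      spec$seed <- cfg$seed
      shoulders <- pose_cohort(spec)
      log_lines <- c(log_lines, paste0("simulated cohort: n=", spec$n_shoulders))
    }
    log_lines <- c(log_lines, paste0("shoulders: ", length(shoulders)))
    stage <- "analyze"
    analysis <- analyze_cohort(shoulders, alpha = cfg$alpha)
    stage <- "report"
    utils::write.csv(round_df(analysis$displacements),
                     file.path(cfg$out_dir, "displacements.csv"),
                     row.names = FALSE)
    utils::write.csv(round_df(analysis$angles),
                     file.path(cfg$out_dir, "angles.csv"), row.names = FALSE)
    write_landmarks(shoulders, file.path(cfg$out_dir, "landmarks.csv"))
    stats_out <- analysis[c("descriptives", "landmark_tests", "angle_tests",
                            "correlations", "bmi_correlations", "alpha",
                            "n_shoulders")]
    jsonlite::write_json(stats_out, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
    cfg_for_hash <- cfg; cfg_for_hash$out_dir <- NULL
    log_lines <- c(log_lines,
                   paste0("config hash: ", config_hash(cfg_for_hash)),
                   "status: ok")
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
    analysis
  }, sta_error = function(e) {
    sta_error("sta_pipeline_error", "pipeline failed in stage '%s': %s",
              stage, conditionMessage(e))
  })
  attr(res, "out_dir") <- cfg$out_dir
  invisible(res)
}

# Tiny deterministic config digest (polynomial hash over the serialized
# config); avoids a dependency on digest.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
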