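# Independent oracles and fixture builders shared across tests.

# ---- quaternions -----------------------------------------------------------

quat_to_matrix <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3L, 3L)
}

matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1L] <- (R[k, j] - R[j, k]) / s
    q[i + 1L] <- s / 4
    q[j + 1L] <- (R[j, i] + R[i, j]) / s
    q[k + 1L] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

# Quaternion-based Euler decompositions (independent of the matrix-element
# path used by the package).
quat_decompose_yxz <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  c(y = atan2(2 * (x * z + w * y), 1 - 2 * (x^2 + y^2)),
    x = asin(max(-1, min(1, -2 * (y * z - w * x)))),
    z = atan2(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2))) * 180 / pi
}

quat_decompose_yxy <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  c(y1 = atan2(2 * (x * y - w * z), 2 * (y * z + w * x)),
    x = acos(max(-1, min(1, 1 - 2 * (x^2 + z^2)))),
    y2 = atan2(2 * (x * y + w * z), 2 * (w * x - y * z))) * 180 / pi
}

# ---- rigid transforms ------------------------------------------------------

apply_rigid_lm <- function(lm, Q, t) {
  pts <- unclass(lm)
  mirrored <- attr(pts, "mirrored")
  out <- sweep(pts %*% t(Q), 2L, -t)
  rownames(out) <- rownames(pts)
  res <- landmark_set(out, bone = attr(lm, "bone"), side = attr(lm, "side"))
  if (isTRUE(mirrored)) attr(res, "mirrored") <- TRUE
  res
}

# ---- permutation oracles ---------------------------------------------------

# Exact two-sided signed-rank p by enumerating all sign assignments
# (Pratt zero handling, average ranks for ties).
wilcoxon_perm_oracle <- function(d) {
  r <- rank(abs(d))
  nz <- which(d != 0)
  v_obs <- sum(r[nz][d[nz] > 0])
  rr <- r[nz]
  m <- length(rr)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_all <- as.numeric(signs %*% rr)
  lo <- mean(v_all <= v_obs + 1e-12)
  hi <- mean(v_all >= v_obs - 1e-12)
  list(statistic = v_obs, p = min(1, 2 * min(lo, hi)))
}

# Friedman statistic computed independently (explicit rank algebra) plus the
# full within-block permutation distribution of that statistic.
friedman_perm_oracle <- function(mat) {
  stat_of <- function(m) {
    rk <- t(apply(m, 1L, rank))
    n <- nrow(m); k <- ncol(m)
    ties <- sum(apply(m, 1L, function(row) { tt <- table(row); sum(tt^3 - tt) }))
    denom <- 1 - ties / (n * k * (k^2 - 1))
    raw <- 12 / (n * k * (k + 1)) * sum(colSums(rk)^2) - 3 * n * (k + 1)
    if (denom <= 0) 0 else raw / denom
  }
  n <- nrow(mat); k <- ncol(mat)
  perms <- permutations_of(k)
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  stats <- apply(idx, 1L, function(sel) {
    m <- mat
    for (b in seq_len(n)) m[b, ] <- mat[b, perms[sel[b], ]]
    stat_of(m)
  })
  obs <- stat_of(mat)
  list(statistic = obs, p_perm = mean(stats >= obs - 1e-12))
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# ICC via stats::aov mean squares and explicit variance components.
icc_aov_oracle <- function(mat, model) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  if (model == "1,1") {
    tab <- summary(stats::aov(y ~ subject, data = df))[[1L]]
    BMS <- tab["subject", "Mean Sq"]; WMS <- tab["Residuals", "Mean Sq"]
    var_s <- (BMS - WMS) / k
    var_s / (var_s + WMS)
  } else {
    tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1L]]
    BMS <- tab["subject", "Mean Sq"]; JMS <- tab["rater", "Mean Sq"]
    EMS <- tab["Residuals", "Mean Sq"]
    var_s <- (BMS - EMS) / k
    var_r <- (JMS - EMS) / n
    var_s / (var_s + var_r + EMS)
  }
}

# ---- template fixtures -----------------------------------------------------

template_thorax_lm <- function() {
  tpl <- make_template_anatomy()
  landmark_set(tpl$thorax, "thorax", "right")
}

template_shoulder <- function(seed = 11L, n = 1L, sta = NULL, noise = 0) {
  spec <- if (is.null(sta)) {
    cohort_spec(n_shoulders = n, seed = seed, alternate_sides = FALSE)
  } else {
    cohort_spec(n_shoulders = n, seed = seed, sta = sta,
                alternate_sides = FALSE)
  }
  pose_cohort(spec)
}

# points sampled exactly on a sphere (deterministic spiral)
sphere_points <- function(center, r, n = 20L) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * i / (n + 1))
  theta <- i * pi * (3 - sqrt(5))
  sweep(r * cbind(sin(phi) * cos(theta), cos(phi), sin(phi) * sin(theta)),
        2L, -center)
}

# ---- STL fixture writers ---------------------------------------------------

icosphere_triangles <- function(center, r) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2)) * r
  v <- sweep(v, 2L, -center)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(6, 5, 10), c(5, 12, 3), c(12, 3, 11), c(7, 11, 3), c(7, 3, 4))
  list(vertices = v, faces = f)
}

write_ascii_stl <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid fixture", con)
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    writeLines(c("  facet normal 0 0 0", "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid fixture", con)
}

write_binary_stl <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    writeBin(c(0, 0, 0, as.vector(t(tri))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}
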