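# geometry_core: frame construction, sphere fit, frame transforms, mirroring

frame_invariants_ok <- function(f, tol = 1e-9) {
  R <- f$axes
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_equal(det(R), 1, tolerance = tol)
  expect_lt(max(abs(cross3(R[, 2], R[, 3]) - R[, 1])), tol)  # X = Y x Z
}

test_that("thorax frame matches the ISB definition on a sagittally planar template", {
  lm <- landmark_set(list(IJ = c(0, 400, 50), C7 = c(0, 420, -60),
                          PX = c(0, 250, 60), T8 = c(0, 260, -80)),
                     "thorax", "right")
  f <- build_thorax_frame(lm)
  expect_equal(f$origin, c(0, 400, 50))
  # all landmarks lie in the plane x = 0, so the plane normal (frame Z) is
  # +/- (1,0,0): zero components along the other two world axes
  expect_equal(abs(f$axes[1, "Z"]), 1, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(f$axes[2:3, "Z"])), 1e-9)
  # Y points up along the spine line
  mid_hi <- c(0, 410, -5); mid_lo <- c(0, 255, -10)
  expect_equal(f$axes[, "Y"], (mid_hi - mid_lo) / sqrt(sum((mid_hi - mid_lo)^2)),
               tolerance = 1e-9)
  frame_invariants_ok(f)
})

test_that("scapula frame matches the hand-computed example and rejects degenerate input", {
  f <- build_scapula_frame(AA = c(0, 0, 100), TS = c(0, 0, 0), AI = c(0, -120, 30))
  expect_equal(f$origin, c(0, 0, 100))
  expect_equal(f$axes[, "Z"], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(f$axes[, "X"], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(f$axes[, "Y"], c(0, 1, 0), tolerance = 1e-12)
  frame_invariants_ok(f)
  expect_error(build_scapula_frame(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5)),
               class = "sta_degenerate_geometry_error")
  expect_error(build_scapula_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "sta_degenerate_geometry_error")
})

test_that("humerus frame matches the hand-computed example, via GH or sphere fit", {
  lm <- landmark_set(list(GH = c(0, 300, 0), EL = c(20, 0, 0), EM = c(-20, 0, 0)),
                     "humerus", "right")
  f <- build_humerus_frame(lm)
  expect_equal(f$origin, c(0, 300, 0))
  expect_equal(f$axes[, "Y"], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(abs(f$axes[3, "X"]), 1, tolerance = 1e-12, ignore_attr = TRUE)
  frame_invariants_ok(f)
  # head given as surface points instead of GH: same frame within fit tolerance
  hh <- sphere_points(c(0, 300, 0), 25, 16L)
  rownames(hh) <- paste0("HH", seq_len(nrow(hh)))
  lm2 <- landmark_set(rbind(EL = c(20, 0, 0), EM = c(-20, 0, 0), hh),
                      "humerus", "right")
  f2 <- build_humerus_frame(lm2)
  expect_equal(f2$origin, f$origin, tolerance = 1e-8)
  expect_equal(f2$axes, f$axes, tolerance = 1e-8)
  expect_error(
    build_humerus_frame(landmark_set(list(GH = c(0, 300, 0), EL = c(0, 100, 0),
                                          EM = c(0, -100, 0)), "humerus", "right")),
    class = "sta_degenerate_geometry_error")
})

test_that("constructed frames are orthonormal and right-handed for random valid inputs", {
  set.seed(42)
  for (i in 1:25) {
    Q <- random_rotation(); t <- stats::rnorm(3, 0, 100)
    lm <- apply_rigid_lm(template_thorax_lm(), Q, t)
    frame_invariants_ok(build_thorax_frame(lm))
    tpl <- make_template_anatomy()
    sc <- sweep(tpl$scapula_local %*% t(Q), 2L, -t)
    frame_invariants_ok(build_scapula_frame(sc[1, ], sc[2, ], sc[3, ]))
  }
})

test_that("frame construction is equivariant under rigid transforms", {
  set.seed(7)
  tpl <- make_template_anatomy()
  lm0 <- template_thorax_lm()
  f0 <- build_thorax_frame(lm0)
  s0 <- build_scapula_frame(tpl$scapula_local["AA", ], tpl$scapula_local["TS", ],
                            tpl$scapula_local["AI", ])
  h0 <- build_humerus_frame(landmark_set(tpl$humerus_local, "humerus", "right"))
  for (i in 1:25) {
    Q <- random_rotation(); t <- stats::rnorm(3, 0, 250)
    f1 <- build_thorax_frame(apply_rigid_lm(lm0, Q, t))
    expect_equal(f1$origin, as.numeric(Q %*% f0$origin + t), tolerance = 1e-9)
    expect_lt(max(abs(f1$axes - Q %*% f0$axes)), 1e-9)
    sc <- sweep(tpl$scapula_local %*% t(Q), 2L, -t)
    s1 <- build_scapula_frame(sc["AA", ], sc["TS", ], sc["AI", ])
    expect_lt(max(abs(s1$axes - Q %*% s0$axes)), 1e-9)
    h1 <- build_humerus_frame(apply_rigid_lm(
      landmark_set(tpl$humerus_local, "humerus", "right"), Q, t))
    expect_lt(max(abs(h1$axes - Q %*% h0$axes)), 1e-9)
  }
})

test_that("sphere fit is exact on noiseless data and errors on degenerate input", {
  pts <- sphere_points(c(1, 2, 3), 25, 20L)
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-8)
  expect_equal(fit$radius, 25, tolerance = 1e-8)
  # 4 coplanar points
  r <- 10
  expect_error(fit_sphere(rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0))),
               class = "sta_degenerate_geometry_error")
  expect_error(fit_sphere(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               class = "sta_degenerate_geometry_error")
})

test_that("sphere fit recovers the center of a noisy hemispherical patch", {
  set.seed(123)
  i <- 1:200
  phi <- acos(1 - i / 201)          # superior hemisphere only
  theta <- i * pi * (3 - sqrt(5))
  pts <- 25 * cbind(sin(phi) * cos(theta), cos(phi), sin(phi) * sin(theta))
  pts <- sweep(pts, 2L, -c(4, -2, 7)) + matrix(stats::rnorm(600, 0, 0.5), 200L)
  fit <- fit_sphere(pts)
  expect_lt(sqrt(sum((fit$center - c(4, -2, 7))^2)), 0.5)
  # geometric (nonlinear least squares) oracle agrees closely
  fit_ref <- fit_sphere(pts, refine = TRUE)
  expect_lt(sqrt(sum((fit$center - fit_ref$center)^2)), 0.2)
})

test_that("world_to_frame / frame_to_world round-trip and preserve distances", {
  set.seed(5)
  f <- build_thorax_frame(template_thorax_lm())
  expect_equal(world_to_frame(f$origin, f), c(0, 0, 0))
  expect_equal(world_to_frame(f$origin + f$axes[, "X"], f), c(1, 0, 0),
               tolerance = 1e-12)
  for (i in 1:20) {
    p <- stats::rnorm(3, 0, 300); q <- stats::rnorm(3, 0, 300)
    expect_equal(frame_to_world(world_to_frame(p, f), f), p, tolerance = 1e-9)
    d_world <- sqrt(sum((p - q)^2))
    d_frame <- sqrt(sum((world_to_frame(p, f) - world_to_frame(q, f))^2))
    expect_equal(d_frame, d_world, tolerance = 1e-9)
  }
  # matrix form agrees with vector form
  m <- matrix(stats::rnorm(15, 0, 100), 5L)
  expect_equal(as.numeric(world_to_frame(m, f)[2, ]), world_to_frame(m[2, ], f))
})

test_that("left-right mirroring is an involution and yields right-convention frames", {
  tpl <- make_template_anatomy()
  left <- tpl$scapula_local
  left[, 3] <- -left[, 3]
  lm_left <- landmark_set(left, "scapula", "left")
  mirrored <- mirror_left_to_right(lm_left)
  expect_identical(attr(mirrored, "side"), "right")
  expect_equal(unclass(mirrored)[, 3], unclass(lm_left)[, 3] * -1)
  back <- mirror_left_to_right(mirrored)
  expect_identical(attr(back, "side"), "left")
  expect_equal(unclass(back), unclass(lm_left), ignore_attr = TRUE)
  # mirrored left shoulder gives the same frame semantics as the right original
  f_right <- build_scapula_frame(tpl$scapula_local["AA", ],
                                 tpl$scapula_local["TS", ],
                                 tpl$scapula_local["AI", ])
  f_mir <- build_scapula_frame(lm_point(mirrored, "AA"), lm_point(mirrored, "TS"),
                               lm_point(mirrored, "AI"))
  expect_equal(f_mir$axes, f_right$axes, tolerance = 1e-12)
  expect_equal(det(f_mir$axes), 1, tolerance = 1e-9)
  expect_warning(mirror_left_to_right(landmark_set(tpl$scapula_local, "scapula", "right")),
                 "right-side")
})

test_that("landmark sets validate names, duplicates and required landmarks", {
  expect_error(landmark_set(list(IJ = c(0, 0, 0), C7 = c(1, 1, 1), PX = c(2, 0, 0)),
                            "thorax", "right"),
               class = "sta_validation_error")
  pts <- rbind(AA = c(0, 0, 0), TS = c(0, 0, -110), AI = c(0, -120, -80),
               AA = c(1, 1, 1))
  expect_error(landmark_set(pts, "scapula", "right"), class = "sta_validation_error")
  expect_error(landmark_set(list(EL = c(1, 0, 0), EM = c(-1, 0, 0)),
                            "humerus", "right"),
               class = "sta_validation_error")
})
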