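test_that("build_frame produces the occlusal-plane / arch-tangent frame", {
  # centroids on the z = 0 plane: z-axis is (0, 0, +/-1)
  set.seed(91)
  u <- seq(-20, 20, length.out = 9)
  centroids <- cbind(u, 30 - 0.05 * u^2, 0)
  frame <- build_frame(centroids, c(20, 10, 0))
  expect_equal(abs(frame$z_axis[3]), 1, tolerance = 1e-9)
  B <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
  expect_equal(det(B), 1, tolerance = 1e-9)

  # symmetric parabolic arch: tangent at an end tooth matches the analytic
  # parabola tangent there, pointing away from the midline
  end <- centroids[1, ]
  frame_end <- build_frame(centroids, end)
  slope <- -0.05 * 2 * end[1]          # dv/du at u = -20
  tan_analytic <- c(1, slope, 0) / sqrt(1 + slope^2)
  # distal at u = -20 is the -u direction
  tan_analytic <- -tan_analytic
  expect_lt(max(abs(frame_end$x_axis - tan_analytic)), 1e-6)

  expect_error(build_frame(cbind(1:5, 0, 0), c(0, 0, 0)),
               class = "castmove_degeneracy_error")
  expect_error(build_frame(centroids[1:2, ], c(0, 0, 0)),
               class = "castmove_degeneracy_error")
})

test_that("build_frame orients z occlusally from crown points, equivariantly", {
  arch <- test_arch(points_per_tooth = 120L)
  refc <- ref_centroids_of(arch, 14L)
  ctr <- colMeans(tooth_points(arch, 14L))
  frame <- build_frame(refc, ctr, occlusal_points = arch$points)
  # synthetic crowns grow toward +z
  expect_gt(frame$z_axis[3], 0.99)

  # under a global rigid motion the frame moves with the cast
  set.seed(92)
  g <- random_rigid()
  frame_g <- build_frame(apply_transform(refc, g),
                         as.vector(g$R %*% ctr) + g$t,
                         occlusal_points = apply_transform(arch$points, g))
  expect_lt(max(abs(frame_g$z_axis - as.vector(g$R %*% frame$z_axis))), 1e-6)
  expect_lt(max(abs(frame_g$x_axis - as.vector(g$R %*% frame$x_axis))), 1e-6)
})

test_that("superimpose_casts recovers global cast motions from reference teeth", {
  arch <- test_arch(points_per_tooth = 100L)
  refs <- setdiff(scan_teeth(arch), c(14L, 24L))

  same <- superimpose_casts(arch, arch, refs)
  expect_lt(max(abs(same$R - diag(3))), 1e-9)
  expect_lt(max(abs(same$t)), 1e-9)

  g <- rigid_transform(rotation_about_axis("z", 12) %*%
                         rotation_about_axis("x", 5), c(3, -2, 1))
  moved <- arch
  moved$points <- apply_transform(arch$points, g)
  tf <- superimpose_casts(arch, moved, refs)
  ginv <- invert(g)
  expect_lt(rotation_diff_deg(tf$R, ginv$R), 0.01)
  expect_lt(max(abs(tf$t - ginv$t)), 0.001)

  expect_error(superimpose_casts(arch, moved, c(11L, 12L)),
               class = "castmove_anchoring_error")
})

test_that("efficacy is the signed achieved/predicted percentage", {
  expect_identical(efficacy(5, 5), 100)
  expect_equal(efficacy(-0.29, 10), -2.9, tolerance = 1e-12)
  expect_gt(efficacy(11, 10), 100)
  expect_error(efficacy(1, 0), class = "castmove_efficacy_error")
})

test_that("measure_patient runs the full pipeline and guards the reference set", {
  cfgs <- list(
    cohort_config(1L, "distalization", "attachment", c(2.2, 3.2), 0.25,
                  true_efficacy_mean = 0.884, true_efficacy_sd = 0,
                  noise_sigma = 0.020, seed = 11L),
    cohort_config(1L, "distalization", "none", c(2.0, 3.2), 0.25,
                  true_efficacy_mean = 0.869, true_efficacy_sd = 0,
                  noise_sigma = 0.020, seed = 12L))
  co <- generate_cohort(cfgs, arch = arch_spec(points_per_tooth = 150L),
                        seed = 13L)
  pid <- names(co$patients)[1]
  p <- co$patients[[pid]]
  rows <- co$manifest[co$manifest$patient_id == pid, ]
  rec <- measure_patient(p$t1, p$t2, p$clin_t2, rows)
  expect_identical(nrow(rec), 2L)
  expect_true(all(rec$primary_component == "Tx"))
  expect_equal(rec$efficacy_percent, 100 * rows$true_efficacy, tolerance = 0.02)
  # predicted movement self-consistency vs the manifest plan
  expect_equal(rec$predicted, rows$planned_total, tolerance = 0.01)

  # a moved tooth in the reference set is an anchoring error
  expect_error(
    measure_patient(p$t1, p$t2, p$clin_t2, rows,
                    reference_ids = scan_teeth(p$t1)),
    class = "castmove_anchoring_error")
})

test_that("perfect treatment scores 100% efficacy under scanner noise", {
  cfg <- cohort_config(1L, "derotation", "attachment", c(15, 20), 1.5,
                       true_efficacy_mean = 1, true_efficacy_sd = 0,
                       noise_sigma = 0.020, seed = 21L)
  co <- generate_cohort(list(cfg), arch = arch_spec(points_per_tooth = 150L),
                        seed = 22L)
  p <- co$patients[[1]]
  rec <- measure_patient(p$t1, p$t2, p$clin_t2,
                         co$manifest[co$manifest$patient_id ==
                                       names(co$patients)[1], ])
  expect_equal(rec$efficacy_percent, 100, tolerance = 0.5 / 100)
})
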