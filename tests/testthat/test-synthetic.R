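test_that("generate_arch is deterministic and correctly labelled", {
  spec <- arch_spec(seed = 1L, points_per_tooth = 60L)
  a1 <- generate_arch(spec)
  a2 <- generate_arch(spec)
  expect_identical(a1$points, a2$points)
  expect_identical(a1$labels, a2$labels)
  expect_identical(length(scan_teeth(a1)), 14L)

  a3 <- generate_arch(arch_spec(seed = 2L, points_per_tooth = 60L))
  expect_false(identical(a1$points, a3$points))

  small <- generate_arch(arch_spec(n_teeth_per_quadrant = 3L, seed = 1L,
                                   points_per_tooth = 60L))
  expect_identical(length(scan_teeth(small)), 6L)
  expect_setequal(scan_teeth(small), c(11:13, 21:23))

  # centroid lies inside the arch-curve bounding box
  ctr <- colMeans(a1$points)
  spec_dims <- arch_spec()
  expect_true(abs(ctr[1]) < spec_dims$arch_width / 2 + 10)
  expect_true(ctr[2] > -10 && ctr[2] < spec_dims$arch_depth + 10)

  expect_error(arch_spec(n_teeth_per_quadrant = 2),
               class = "castmove_config_error")
  expect_error(arch_spec(points_per_tooth = 10),
               class = "castmove_config_error")
  expect_error(arch_spec(arch_width = -1), class = "castmove_config_error")
})

test_that("apply_movement transforms only the targeted tooth", {
  arch <- test_arch(points_per_tooth = 80L)
  refc <- ref_centroids_of(arch, c(14L, 24L))
  ctr <- colMeans(tooth_points(arch, 14L))
  frame <- build_frame(refc, ctr, occlusal_points = arch$points)

  zero <- apply_movement(arch, ground_truth_movement(
    14L, movement_components(), ctr), frame)
  expect_identical(zero$points, arch$points)

  tx <- apply_movement(arch, ground_truth_movement(
    14L, movement_components(Tx = 1.5), ctr), frame)
  untouched <- arch$labels != 14L
  expect_identical(tx$points[untouched, ], arch$points[untouched, ])
  shift <- colMeans(tooth_points(tx, 14L)) - ctr
  expect_equal(shift, 1.5 * frame$x_axis, tolerance = 1e-9)

  # rotation about the tooth centroid keeps the centroid fixed
  rot <- apply_movement(arch, ground_truth_movement(
    14L, movement_components(Rz = 15), ctr), frame)
  expect_equal(colMeans(tooth_points(rot, 14L)), ctr, tolerance = 1e-9)
  expect_false(identical(tooth_points(rot, 14L), tooth_points(arch, 14L)))

  expect_error(apply_movement(arch, ground_truth_movement(
    48L, movement_components(Tx = 1), ctr), frame),
    class = "castmove_lookup_error")
})

test_that("scan noise is calibrated, label-preserving and seeded", {
  arch <- generate_arch(arch_spec(points_per_tooth = 720L, seed = 9L))
  n <- nrow(arch$points)
  expect_gte(n, 10000L)

  noisy <- add_scan_noise(arch, 0.020, seed = 4L)
  expect_identical(noisy$labels, arch$labels)
  disp <- noisy$points - arch$points
  rms <- sqrt(mean(rowSums(disp^2)))
  expect_lt(abs(rms - 0.020 * sqrt(3)) / (0.020 * sqrt(3)), 0.05)
  expect_lt(max(abs(apply(disp, 2, sd) - 0.020) / 0.020), 0.05)

  expect_identical(add_scan_noise(arch, 0, seed = 4L)$points, arch$points)
  expect_identical(add_scan_noise(arch, 0.02, seed = 4L)$points, noisy$points)
  other <- add_scan_noise(arch, 0.02, seed = 5L)
  expect_false(identical(other$points, noisy$points))
  expect_identical(other$labels, noisy$labels)

  expect_error(add_scan_noise(arch, -0.1, seed = 1L),
               class = "castmove_config_error")
})

test_that("cohort generation honours the split-mouth design and truncation", {
  cfgs <- default_cohort_configs(count = 1L, seed = 2L)
  arch <- arch_spec(points_per_tooth = 80L)
  co <- generate_cohort(cfgs, arch = arch, seed = 2L)
  expect_identical(nrow(co$manifest), 6L)
  expect_identical(length(co$patients), 3L)
  # one moved tooth per hemiarch
  for (pid in unique(co$manifest$patient_id)) {
    teeth <- co$manifest$moved_tooth_id[co$manifest$patient_id == pid]
    expect_identical(length(teeth), 2L)
    expect_setequal(teeth %/% 10L, c(1L, 2L))
  }
  expect_true(all(co$manifest$true_efficacy >= -0.25 &
                    co$manifest$true_efficacy <= 1.25))
  expect_true(all(co$manifest$n_aligners ==
                    ceiling(co$manifest$planned_total /
                              co$manifest$staging_per_aligner)))

  # determinism of the full generator
  co2 <- generate_cohort(cfgs, arch = arch, seed = 2L)
  expect_identical(co2$manifest, co$manifest)
  expect_identical(co2$patients[[1]]$t2$points, co$patients[[1]]$t2$points)

  # perfect treatment with zero noise reproduces ClinT2 exactly
  perfect <- cohort_config(1L, "distalization", "none", c(2.0, 3.2), 0.25,
                           true_efficacy_mean = 1, true_efficacy_sd = 0,
                           noise_sigma = 0, seed = 3L)
  cop <- generate_cohort(list(perfect), arch = arch, seed = 3L)
  expect_equal(cop$patients[[1]]$t2$points, cop$patients[[1]]$clin_t2$points)

  expect_error(cohort_config(1L, "torque", "attachment", c(10, 20), 1.5,
                             0.5, 0.2),
               class = "castmove_config_error")  # staging above 1 deg cap
  expect_error(cohort_config(1L, "nonsense", "none", c(1, 2), 0.2, 0.5, 0.2),
               class = "castmove_config_error")
})

test_that("noiseless measurement inverts apply_movement to numerical precision", {
  arch <- test_arch(points_per_tooth = 150L)
  refc <- ref_centroids_of(arch, c(14L, 24L, 11L, 16L))
  cases <- list(list(14L, movement_components(Rz = 17.8)),
                list(24L, movement_components(Rz = 20.1)),
                list(11L, movement_components(Ry = 16.1)),
                list(16L, movement_components(Tx = 2.7)),
                list(14L, movement_components(Tx = 0.4, Ty = -0.2, Tz = 0.3,
                                              Rx = 2, Ry = -3, Rz = 8)))
  for (case in cases) {
    id <- case[[1]]
    p1 <- tooth_points(arch, id)
    ctr <- colMeans(p1)
    frame <- build_frame(refc, ctr, occlusal_points = arch$points)
    moved <- apply_movement(arch, ground_truth_movement(id, case[[2]], ctr),
                            frame)
    meas <- measure_movement(p1, tooth_points(moved, id), frame)
    expect_lt(max(abs(meas - case[[2]])), 1e-6)
  }
})
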