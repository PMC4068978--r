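test_that("kabsch recovers exact transforms on paired points", {
  set.seed(11)
  src <- matrix(rnorm(30), 10, 3)

  same <- kabsch(src, src)
  expect_lt(max(abs(same$R - diag(3))), 1e-12)
  expect_lt(max(abs(same$t)), 1e-12)

  shift <- kabsch(src, sweep(src, 2, c(1, 0, 0), "+"))
  expect_lt(max(abs(shift$R - diag(3))), 1e-12)
  expect_equal(shift$t, c(1, 0, 0), tolerance = 1e-12)

  # 4 non-coplanar points under a 90 degree z-rotation
  quad <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Rz <- rotation_about_axis("z", 90)
  fit <- kabsch(quad, quad %*% t(Rz))
  expect_lt(max(abs(fit$R - Rz)), 1e-9)
})

test_that("kabsch equals the brute-force rigid-fit minimizer on small instances", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    src <- matrix(rnorm(3 * n), n, 3)
    tf_true <- random_rigid()
    tgt <- apply_transform(src, tf_true) + matrix(rnorm(3 * n, sd = 0.05), n, 3)
    fit <- kabsch(src, tgt)
    oracle <- brute_force_rigid_fit(src, tgt)
    expect_lt(abs(rigid_fit_mse(fit, src, tgt) - oracle$mse), 1e-6)
    expect_lt(rotation_diff_deg(fit$R, oracle$transform$R), 0.1)
  }
})

test_that("kabsch rejects degenerate configurations", {
  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               class = "castmove_degeneracy_error")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), class = "castmove_degeneracy_error")
})

test_that("nearest_neighbors is exact and breaks ties toward the lower index", {
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0))
  hit <- nearest_neighbors(ref, rbind(c(2, 0, 0)))
  expect_identical(hit$index, 2L)
  expect_identical(hit$distance, 0)

  tie <- nearest_neighbors(rbind(c(1, 0, 0), c(-1, 0, 0)), rbind(c(0, 0, 0)))
  expect_identical(tie$index, 1L)

  # brute-force oracle on 200 random points
  set.seed(31)
  reference <- matrix(runif(600, -10, 10), 200, 3)
  queries <- matrix(runif(600, -10, 10), 200, 3)
  nn <- nearest_neighbors(reference, queries)
  d2 <- function(q) rowSums(sweep(reference, 2, q)^2)
  brute <- vapply(seq_len(nrow(queries)),
                  function(i) which.min(d2(queries[i, ])), integer(1))
  expect_identical(nn$index, brute)
  brute_d <- sqrt(vapply(seq_len(nrow(queries)),
                         function(i) min(d2(queries[i, ])), numeric(1)))
  expect_equal(nn$distance, brute_d, tolerance = 1e-12)

  expect_error(nearest_neighbors(matrix(0, 0, 3), queries),
               class = "castmove_config_error")
})

test_that("icp converges on clean and outlier-contaminated clouds", {
  set.seed(41)
  cloud <- matrix(runif(3000, -5, 5), 1000, 3)

  trivial <- icp(cloud, cloud)
  expect_lt(trivial$rms, 1e-9)
  expect_lte(trivial$iterations, 2L)
  expect_lt(max(abs(trivial$transform$R - diag(3))), 1e-9)

  tf_true <- rigid_transform(rotation_about_axis("z", 5), c(0.5, 0, 0))
  fit <- icp(cloud, apply_transform(cloud, tf_true))
  expect_lt(rotation_diff_deg(fit$transform$R, tf_true$R), 0.01)
  expect_lt(max(abs(fit$transform$t - tf_true$t)), 0.001)

  contaminated <- cloud
  out_idx <- sample(nrow(cloud), 100)
  contaminated[out_idx, ] <- matrix(runif(300, -20, 20), 100, 3)
  fit2 <- icp(contaminated, apply_transform(cloud, tf_true),
              params = icp_params(trim_fraction = 0.15))
  expect_lt(rotation_diff_deg(fit2$transform$R, tf_true$R), 0.1)
  expect_lt(max(abs(fit2$transform$t - tf_true$t)), 0.01)

  expect_error(icp(cloud[1:5, ], cloud), class = "castmove_degeneracy_error")
})

test_that("trimmed ICP RMS is monotonically non-increasing", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(50:150, 1)
    src <- matrix(rnorm(3 * n, sd = 3), n, 3)
    tgt <- apply_transform(src, random_rigid(max_trans = 1)) +
      matrix(rnorm(3 * n, sd = 0.1), n, 3)
    init <- rigid_transform(diag(3), colMeans(tgt) - colMeans(src))
    fit <- icp(src, tgt, init = init,
               params = icp_params(trim_fraction = 0.1, max_iterations = 50))
    expect_true(all(diff(fit$rms_trace) <= 1e-9))
  }
})

test_that("merge_views reassembles an arch from transformed views", {
  set.seed(61)
  arch <- test_arch(points_per_tooth = 80L)
  cloud <- arch$points

  one <- merge_views(list(cloud), list(rigid_transform()))
  expect_equal(one, cloud)

  two <- merge_views(list(cloud, cloud),
                     list(rigid_transform(), rigid_transform()),
                     refine = FALSE)
  expect_identical(nrow(two), 2L * nrow(cloud))

  # 4 views under known motions; mapping back by the inverses must land on
  # the original up to ICP refinement residual
  tfs <- replicate(4, random_rigid(max_trans = 2), simplify = FALSE)
  views <- lapply(tfs, function(tf) apply_transform(cloud, tf))
  merged <- merge_views(views, lapply(tfs, invert))
  nn <- nearest_neighbors(cloud, merged)
  expect_lt(sqrt(mean(nn$distance^2)), 0.01)

  expect_error(merge_views(list(cloud), list()),
               class = "castmove_config_error")
})
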