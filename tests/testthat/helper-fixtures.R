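# Shared fixtures and independent oracles, all built in code.

# random proper rotation via QR decomposition of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

random_rigid <- function(max_trans = 5) {
  rigid_transform(random_rotation(), runif(3, -max_trans, max_trans))
}

# Independent brute-force rigid-fit oracle: optimal translation is the
# centroid match for any rotation, so search rotations only — a coarse
# Euler grid followed by Nelder-Mead refinement of the mean squared error.
brute_force_rigid_fit <- function(source, target) {
  cs <- colMeans(source)
  ct <- colMeans(target)
  S <- sweep(source, 2, cs)
  Tm <- sweep(target, 2, ct)
  obj <- function(ang) {
    R <- castmove:::euler_to_rotation(ang[1], ang[2], ang[3])
    mean(rowSums((S %*% t(R) - Tm)^2))
  }
  grid <- seq(-160, 180, by = 20)
  best <- c(0, 0, 0)
  best_val <- obj(best)
  for (a in grid) for (b in grid) for (c_ in grid) {
    v <- obj(c(a, b, c_))
    if (v < best_val) {
      best_val <- v
      best <- c(a, b, c_)
    }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  R <- castmove:::euler_to_rotation(opt$par[1], opt$par[2], opt$par[3])
  list(transform = rigid_transform(R, ct - as.vector(R %*% cs)),
       mse = opt$value)
}

rigid_fit_mse <- function(tf, source, target) {
  mean(rowSums((apply_transform(source, tf) - target)^2))
}

# small arch reused by movement tests (cheap to build)
test_arch <- function(seed = 3, points_per_tooth = 200L) {
  generate_arch(arch_spec(points_per_tooth = points_per_tooth, seed = seed))
}

ref_centroids_of <- function(scan, moved_ids) {
  refs <- setdiff(scan_teeth(scan), moved_ids)
  t(vapply(refs, function(id) colMeans(tooth_points(scan, id)), numeric(3)))
}

# angular difference between two rotation matrices, degrees
rotation_diff_deg <- function(R1, R2) {
  castmove:::rad2deg(acos(min(1, max(-1, (sum(diag(t(R1) %*% R2)) - 1) / 2))))
}

# tiny binary STL writer (test fixture only): triangle soup
write_binary_stl <- function(triangles, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(length(triangles)), con, size = 4, endian = "little")
  for (tri in triangles) {
    writeBin(c(0, 0, 0, as.vector(t(tri))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}
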