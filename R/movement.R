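# Patient coordinate frame, reference-teeth superimposition, per-tooth
# 6-DOF measurement and achieved-vs-planned efficacy.
#
# The movement vocabulary is clinical: for each analyzed movement the
# primary component is fixed by its group — molar distalization is a
# translation along the frame x-axis (mm), incisor torque a rotation about
# the y-axis (deg), premolar derotation a rotation about the z-axis (deg).

PRIMARY_COMPONENT <- c(distalization = "Tx", torque = "Ry", derotation = "Rz")

#' Patient arch coordinate frame
#'
#' A right-handed orthonormal frame anchored at the moved tooth:
#' x points distally along the arch, z occlusally, y completes the
#' right-handed system (bucco-lingual).
#'
#' @param origin 3-vector, mm.
#' @param x_axis,y_axis,z_axis Unit 3-vectors, pairwise orthogonal,
#'   `det([x y z]) = +1`.
#' @return Object of class `arch_frame`.
#' @export
arch_frame <- function(origin, x_axis, y_axis, z_axis) {
  origin <- as.numeric(origin)
  B <- cbind(as.numeric(x_axis), as.numeric(y_axis), as.numeric(z_axis))
  cm_assert(length(origin) == 3L && all(is.finite(origin)) &&
              all(is.finite(B)), "frame entries must be finite",
            "validation_error")
  cm_assert(max(abs(crossprod(B) - diag(3))) < 1e-9,
            "frame axes must be orthonormal", "validation_error")
  cm_assert(abs(det(B) - 1) < 1e-9, "frame must be right-handed",
            "validation_error")
  structure(list(origin = origin, x_axis = B[, 1], y_axis = B[, 2],
                 z_axis = B[, 3]),
            class = "arch_frame")
}

frame_basis <- function(frame) {
  cbind(frame$x_axis, frame$y_axis, frame$z_axis)
}

#' Build the patient arch frame from reference-tooth centroids
#'
#' The z-axis is the unit normal of the least-squares plane through the
#' reference centroids (the occlusal plane), signed toward the occlusal
#' side; the x-axis is the tangent of a quadratic arch curve fitted
#' through the centroids, evaluated at the arch position nearest the moved
#' tooth and signed distally (away from the arch midline); y = z cross x.
#' The origin is the moved tooth's centroid.
#'
#' The occlusal sign is resolved from `occlusal_points` when supplied: the
#' crown walls taper toward the cusps, so the signed-distance distribution
#' of crown points about the centroid plane is skewed toward the occlusal
#' side, and the normal is oriented along the positive skew. This rule is
#' equivariant under rigid motion of the cast. Without points the normal
#' with the largest positive component is chosen (a documented
#' orientation convention, not data-driven).
#'
#' @param reference_centroids Matrix (>= 3 x 3, mm) of non-collinear
#'   reference tooth centroids.
#' @param moved_tooth_centroid 3-vector, mm.
#' @param occlusal_points Optional crown point cloud used to orient the
#'   z-axis (typically all tooth points of the T1 cast).
#' @return An [arch_frame()].
#' @export
build_frame <- function(reference_centroids, moved_tooth_centroid,
                        occlusal_points = NULL) {
  C <- as_point_matrix(reference_centroids, "reference_centroids")
  if (nrow(C) < 3L)
    cm_stop("at least 3 reference centroids are required", "degeneracy_error")
  mt <- as.numeric(moved_tooth_centroid)
  cm_assert(length(mt) == 3L && all(is.finite(mt)),
            "moved_tooth_centroid must be a finite 3-vector", "config_error")
  c0 <- colMeans(C)
  Cc <- sweep(C, 2L, c0)
  eg <- eigen(crossprod(Cc), symmetric = TRUE)
  if (eg$values[2] <= max(eg$values[1], 1) * 1e-12)
    cm_stop("reference centroids are collinear; arch frame is undefined",
            "degeneracy_error")
  z <- eg$vectors[, 3]
  if (!is.null(occlusal_points)) {
    # crowns taper toward the cusps: the in-plane radial spread of crown
    # points about their tooth decreases toward the occlusal side. Assign
    # each point to its nearest reference centroid and orient z against
    # the height/spread covariance. Equivariant under rigid motion.
    P <- as_point_matrix(occlusal_points, "occlusal_points")
    nn <- nearest_neighbors(C, P)
    dvec <- P - C[nn$index, , drop = FALSE]
    s <- as.vector(dvec %*% z)
    r2 <- rowSums(dvec^2) - s^2
    cv <- mean((s - mean(s)) * (r2 - mean(r2)))
    if (cv > 0) z <- -z
  } else {
    k <- which.max(abs(z))
    if (z[k] < 0) z <- -z
  }
  e1 <- eg$vectors[, 1]
  e2 <- eg$vectors[, 2]
  u <- as.vector(Cc %*% e1)
  v <- as.vector(Cc %*% e2)
  fit <- lm.fit(cbind(1, u, u^2), v)
  cf <- fit$coefficients
  u_star <- sum((mt - c0) * e1)
  slope <- cf[2] + 2 * cf[3] * u_star
  tangent <- e1 + slope * e2
  tangent <- tangent - sum(tangent * z) * z
  tangent <- tangent / sqrt(sum(tangent^2))
  # distal = away from the arch midline (the fitted parabola's apex)
  s <- if (abs(cf[3]) > 1e-9) sign(u_star + cf[2] / (2 * cf[3]))
       else sign(u_star - mean(u))
  if (s == 0) s <- 1
  if (s < 0) tangent <- -tangent
  x <- tangent
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  arch_frame(mt, x, y, z)
}

#' Superimpose two casts on their untreated reference teeth
#'
#' Estimates the rigid transform mapping `cast_t2` into `cast_t1`'s frame
#' by trimmed ICP restricted to the points of the reference teeth — the
#' teeth not planned to move in either hemiarch, which act as the
#' corresponding structure between timepoints. Initialization is centroid
#' alignment of the reference points.
#'
#' @param cast_t1,cast_t2 [labeled_scan()] objects sharing a labelling.
#' @param reference_ids FDI numbers of the reference teeth; must exclude
#'   every clinically moved tooth and have at least 3 members present in
#'   both scans.
#' @param params [icp_params()].
#' @return A [rigid_transform()] mapping `cast_t2` points into `cast_t1`.
#' @export
superimpose_casts <- function(cast_t1, cast_t2, reference_ids,
                              params = icp_params()) {
  cm_assert(inherits(cast_t1, "labeled_scan") &&
              inherits(cast_t2, "labeled_scan"),
            "casts must be labeled_scan objects", "config_error")
  shared <- intersect(intersect(reference_ids, scan_teeth(cast_t1)),
                      scan_teeth(cast_t2))
  if (length(shared) < 3L)
    cm_stop(sprintf(
      "superimposition needs >= 3 shared reference teeth, found %d",
      length(shared)), "anchoring_error")
  src <- tooth_points(cast_t2, shared)
  tgt <- tooth_points(cast_t1, shared)
  init <- rigid_transform(diag(3), colMeans(tgt) - colMeans(src))
  icp(src, tgt, init = init, params = params)$transform
}

#' Decompose a rigid transform into movement components in a frame
#'
#' The rotation is re-expressed in the frame basis `B = [x y z]` as
#' `R' = B' R B` and factored with the fixed-axes x–y–z convention
#' (`R' = Rz %*% Ry %*% Rx`); the translation components are the
#' frame-basis coordinates of the displacement of the frame origin. Near
#' gimbal lock (|Ry| = 90 deg) Rx is set to 0 by convention and a warning
#' is issued.
#'
#' @param transform A [rigid_transform()] in world coordinates.
#' @param frame An [arch_frame()]; its origin is the rotation centre the
#'   translation components refer to.
#' @return A [movement_components()] vector (mm / degrees).
#' @export
decompose <- function(transform, frame) {
  cm_assert(inherits(transform, "rigid_transform"),
            "transform must be a rigid_transform", "config_error")
  cm_assert(inherits(frame, "arch_frame"), "frame must be an arch_frame",
            "config_error")
  B <- frame_basis(frame)
  Rp <- t(B) %*% transform$R %*% B
  ang <- rotation_to_euler(Rp)
  if (isTRUE(attr(ang, "gimbal_lock")))
    warning("gimbal lock (|Ry| = 90 deg): Rx set to 0 by convention")
  disp <- as.vector(transform$R %*% frame$origin) + transform$t - frame$origin
  tv <- as.vector(t(B) %*% disp)
  movement_components(Tx = tv[1], Ty = tv[2], Tz = tv[3],
                      Rx = ang[["rx"]], Ry = ang[["ry"]], Rz = ang[["rz"]])
}

#' Measure the 6-DOF movement of one tooth
#'
#' Registers the tooth's T1 points onto its (already superimposed) T2
#' points by trimmed ICP initialized at centroid alignment, and decomposes
#' the recovered transform in the patient frame about the frame origin
#' (the T1 tooth centroid).
#'
#' Unlike cast-to-cast superimposition, both clouds here are the same
#' segmented tooth, so every point has a true counterpart and the default
#' parameters disable trimming (trimming away the highest-residual points
#' would remove exactly the cusp features that drive rotation recovery).
#'
#' Initialization: clinically planned derotations reach 30 degrees and
#' more, beyond the convergence basin of ICP started at plain centroid
#' alignment. The registration is therefore started twice — once from
#' centroid alignment and once from principal-axes alignment of the two
#' clouds (axis signs fixed by third moments) — and the fit with the
#' lower final RMS is kept. Both starts are deterministic.
#'
#' @param tooth_t1 T1 points of the tooth (>= 10 x 3, mm).
#' @param tooth_t2_in_t1_frame The same tooth's points at T2, already
#'   mapped into the T1 cast frame by [superimpose_casts()].
#' @param frame The [arch_frame()] anchored at the tooth.
#' @param params [icp_params()]; default untrimmed.
#' @return A [movement_components()] vector.
#' @export
measure_movement <- function(tooth_t1, tooth_t2_in_t1_frame, frame,
                             params = icp_params(trim_fraction = 0)) {
  src <- as_point_matrix(tooth_t1, "tooth_t1")
  tgt <- as_point_matrix(tooth_t2_in_t1_frame, "tooth_t2_in_t1_frame")
  if (nrow(src) < 10L || nrow(tgt) < 10L)
    cm_stop("tooth clouds need >= 10 points", "degeneracy_error")
  inits <- list(
    rigid_transform(diag(3), colMeans(tgt) - colMeans(src)),
    pca_alignment(src, tgt))
  fits <- lapply(inits, function(init) icp(src, tgt, init = init,
                                           params = params))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rms"))]]
  decompose(best$transform, frame)
}

# Correspondence-free coarse alignment: map the source cloud's principal
# axes onto the target's. Axis signs are fixed by the sign of the third
# central moment along each axis; if the resulting bases are left-handed
# the axis with the weakest moment is flipped.
pca_alignment <- function(src, tgt) {
  oriented_axes <- function(P) {
    c0 <- colMeans(P)
    Pc <- sweep(P, 2L, c0)
    E <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)$vectors
    m3 <- vapply(1:3, function(k) mean((Pc %*% E[, k])^3), numeric(1))
    for (k in 1:3) if (m3[k] < 0) {
      E[, k] <- -E[, k]
      m3[k] <- -m3[k]
    }
    if (det(E) < 0) {
      k <- which.min(abs(m3))
      E[, k] <- -E[, k]
    }
    list(center = c0, axes = E)
  }
  a <- oriented_axes(src)
  b <- oriented_axes(tgt)
  R <- b$axes %*% t(a$axes)
  # guard against numerical drift off the rotation manifold
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  rigid_transform(R, b$center - as.vector(R %*% a$center))
}

#' Treatment efficacy of one movement
#'
#' The signed percentage of the planned movement that was achieved,
#' `100 * achieved / predicted`. May be negative (movement opposite to
#' plan) or exceed 100 (overshoot).
#'
#' @param achieved,predicted Scalars in the same unit (mm or degrees);
#'   `predicted` must be nonzero.
#' @return Percent.
#' @export
efficacy <- function(achieved, predicted) {
  cm_assert(is.numeric(achieved) && is.numeric(predicted) &&
              length(achieved) == 1L && length(predicted) == 1L &&
              is.finite(achieved) && is.finite(predicted),
            "achieved and predicted must be finite scalars", "config_error")
  if (predicted == 0)
    cm_stop("efficacy is undefined for a zero predicted movement",
            "efficacy_error")
  100 * achieved / predicted
}

record_columns <- function() {
  c("patient_id", "group", "subgroup", "moved_tooth_id", "primary_component",
    "predicted", "achieved", "efficacy_percent", "planned_total",
    "staging_per_aligner", "compliance_hours",
    paste0("achieved_", c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")),
    paste0("predicted_", c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")))
}

#' Measure all movements of one patient
#'
#' Runs the full pipeline for one patient: superimposes T2 and ClinT2 onto
#' T1 via the untreated reference teeth, builds the arch frame at each
#' moved tooth, measures achieved (T2 - T1) and predicted (ClinT2 - T1)
#' components with the identical machinery, and scores efficacy on the
#' group's primary component. Measuring the prediction from the ClinT2
#' scan (rather than trusting the manifest) lets systematic pipeline bias
#' cancel in the efficacy ratio.
#'
#' @param t1,t2,clin_t2 [labeled_scan()] objects sharing the labelling.
#' @param rows Manifest rows (see [read_manifest()]) for this patient's
#'   movement(s).
#' @param reference_ids Reference teeth; defaults to every tooth of `t1`
#'   not named as moved in `rows`. Supplying a set containing a moved
#'   tooth is an anchoring error.
#' @param params [icp_params()] for the cast-to-cast superimposition
#'   (trimmed by default).
#' @param measure_params [icp_params()] for the per-tooth registration
#'   (untrimmed by default; see [measure_movement()]).
#' @return Data frame with one efficacy record per movement: identifiers,
#'   the primary predicted/achieved values, `efficacy_percent`, and all
#'   six achieved and predicted components.
#' @export
measure_patient <- function(t1, t2, clin_t2, rows, reference_ids = NULL,
                            params = icp_params(),
                            measure_params = icp_params(trim_fraction = 0)) {
  cm_assert(is.data.frame(rows) && nrow(rows) >= 1L,
            "rows must be a non-empty manifest data frame", "config_error")
  moved <- unique(rows$moved_tooth_id)
  if (is.null(reference_ids)) {
    reference_ids <- setdiff(scan_teeth(t1), moved)
  } else if (length(intersect(reference_ids, moved)) > 0L) {
    cm_stop(sprintf(
      "reference set contains clinically moved tooth/teeth: %s",
      paste(intersect(reference_ids, moved), collapse = ", ")),
      "anchoring_error")
  }
  tf_t2 <- superimpose_casts(t1, t2, reference_ids, params)
  tf_clin <- superimpose_casts(t1, clin_t2, reference_ids, params)
  ref_centroids <- t(vapply(reference_ids, function(id)
    colMeans(tooth_points(t1, id)), numeric(3)))
  occl <- t1$points[t1$labels > 0L, , drop = FALSE]

  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    id <- row$moved_tooth_id
    p1 <- tooth_points(t1, id)
    frame <- build_frame(ref_centroids, colMeans(p1), occlusal_points = occl)
    ach <- measure_movement(
      p1, apply_transform(tooth_points(t2, id), tf_t2), frame, measure_params)
    pred <- measure_movement(
      p1, apply_transform(tooth_points(clin_t2, id), tf_clin), frame,
      measure_params)
    pc <- PRIMARY_COMPONENT[[row$group]]
    rec <- data.frame(
      patient_id = row$patient_id, group = row$group, subgroup = row$subgroup,
      moved_tooth_id = id, primary_component = pc,
      predicted = pred[[pc]], achieved = ach[[pc]],
      efficacy_percent = efficacy(ach[[pc]], pred[[pc]]),
      planned_total = row$planned_total,
      staging_per_aligner = row$staging_per_aligner,
      compliance_hours = row$compliance_hours_per_day,
      stringsAsFactors = FALSE)
    for (k in names(ach)) rec[[paste0("achieved_", k)]] <- ach[[k]]
    for (k in names(pred)) rec[[paste0("predicted_", k)]] <- pred[[k]]
    out[[i]] <- rec
  }
  do.call(rbind, out)
}

#' Measure a whole simulated or loaded cohort
#'
#' @param patients Named list of per-patient lists with elements `t1`,
#'   `t2`, `clin_t2` (as returned by [generate_cohort()]).
#' @param manifest Manifest data frame covering the patients.
#' @param params [icp_params()].
#' @return Row-bound efficacy records from [measure_patient()].
#' @export
measure_cohort <- function(patients, manifest, params = icp_params()) {
  validate_manifest(manifest)
  ids <- unique(manifest$patient_id)
  cm_assert(all(ids %in% names(patients)),
            "every manifest patient must be present in `patients`",
            "config_error")
  do.call(rbind, lapply(ids, function(pid) {
    p <- patients[[pid]]
    measure_patient(p$t1, p$t2, p$clin_t2,
                    manifest[manifest$patient_id == pid, , drop = FALSE],
                    params = params)
  }))
}
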