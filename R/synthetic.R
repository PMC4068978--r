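# Synthetic dental arches with known ground-truth tooth movements.
#
# Crowns are tapered superellipsoid shells placed on a parabolic arch
# curve: faceted (high-exponent) cross-sections for incisors, rounded ones
# for premolars (a rounded tooth shape is what makes clinical derotation
# hard), with a smooth bucco-lingual/mesial asymmetry so every crown has a
# unique rotational signature for registration. Shape realism is
# deliberately secondary: what the pipeline consumes is correct labels and
# exact rigid-body ground truth.

TOOTH_CLASSES <- c("incisor", "incisor", "canine", "premolar", "premolar",
                   "molar", "molar")

tooth_class <- function(position) {
  if (position <= length(TOOTH_CLASSES)) TOOTH_CLASSES[position] else "molar"
}

#' Specification of a synthetic dental arch
#'
#' @param n_teeth_per_quadrant Teeth per quadrant (>= 3, default 7:
#'   2 incisors, 1 canine, 2 premolars, 2 molars).
#' @param arch_width Molar-to-molar arch width, mm.
#' @param arch_depth Sagittal depth from molars to incisal midline, mm.
#' @param crown_height Crown height, mm.
#' @param crown_radii Named list of per-class semi-axes
#'   `c(mesiodistal, buccolingual)` in mm for `incisor`, `canine`,
#'   `premolar`, `molar`.
#' @param points_per_tooth Surface points sampled per crown (>= 50).
#' @param seed Integer seed making the sampled cloud reproducible.
#' @return List of class `arch_spec`.
#' @export
arch_spec <- function(n_teeth_per_quadrant = 7L,
                      arch_width = 50,
                      arch_depth = 40,
                      crown_height = 8,
                      crown_radii = list(incisor = c(3.4, 1.9),
                                         canine = c(3.6, 2.8),
                                         premolar = c(3.4, 3.9),
                                         molar = c(4.9, 5.2)),
                      points_per_tooth = 300L,
                      seed = 1L) {
  cm_assert(n_teeth_per_quadrant >= 3, "n_teeth_per_quadrant must be >= 3",
            "config_error")
  cm_assert(all(c(arch_width, arch_depth, crown_height) > 0),
            "arch dimensions must be positive", "config_error")
  cm_assert(is.list(crown_radii) &&
              all(c("incisor", "canine", "premolar", "molar") %in%
                    names(crown_radii)) &&
              all(unlist(crown_radii) > 0),
            "crown_radii must give positive semi-axes for each tooth class",
            "config_error")
  cm_assert(points_per_tooth >= 50, "points_per_tooth must be >= 50",
            "config_error")
  structure(list(n_teeth_per_quadrant = as.integer(n_teeth_per_quadrant),
                 arch_width = arch_width, arch_depth = arch_depth,
                 crown_height = crown_height, crown_radii = crown_radii,
                 points_per_tooth = as.integer(points_per_tooth),
                 seed = as.integer(seed)),
            class = "arch_spec")
}

# superellipse cross-section exponents per tooth class
CROWN_EXPONENT <- c(incisor = 4, canine = 2.5, premolar = 2.5, molar = 3)
CROWN_TAPER <- 0.35       # occlusal taper of the crown walls
BUCCAL_BULGE <- 0.15      # smooth asymmetries breaking rotational symmetry
MESIAL_SKEW <- 0.07
CAP_FRACTION <- 0.35      # fraction of points on the occlusal surface

# occlusal relief: cusp/ridge pattern of the occlusal surface, as a
# fraction of crown height. The phase puts the incisal edge along the
# mesio-distal axis for incisors/canines and the paired cusps
# bucco-lingually for premolars/molars; the sin term makes the buccal
# cusp dominant. Without this relief the crown walls are nearly surfaces
# of revolution and carry no usable rotational signature.
CAP_RELIEF <- list(incisor = c(depth = 0.45, phase = 0),
                   canine = c(depth = 0.40, phase = 0),
                   premolar = c(depth = 0.35, phase = pi),
                   molar = c(depth = 0.30, phase = pi))

# sample one crown in its local frame: x = mesio-distal, y = buccal,
# z = occlusal, gingival margin at z = 0
sample_crown <- function(n, semi_axes, exponent, height, relief) {
  theta <- runif(n, 0, 2 * pi)
  on_cap <- runif(n) < CAP_FRACTION
  z_wall <- runif(n, 0, height)
  rho <- ifelse(on_cap, sqrt(runif(n)), 1)
  e <- 2 / exponent
  xs <- semi_axes[1] * abs(cos(theta))^e * sign(cos(theta))
  ys <- semi_axes[2] * abs(sin(theta))^e * sign(sin(theta))
  asym <- 1 + BUCCAL_BULGE * sin(theta) + MESIAL_SKEW * cos(theta)
  cusp <- 0.5 + 0.35 * cos(2 * theta - relief[["phase"]]) - 0.25 * sin(theta)
  z_cap <- height * (1 - relief[["depth"]] * rho^2 * cusp)
  z <- ifelse(on_cap, z_cap, z_wall)
  taper <- 1 - CROWN_TAPER * pmin(z, height) / height
  cbind(xs * asym * taper * rho, ys * asym * taper * rho, z)
}

arch_curve_y <- function(u, spec) {
  spec$arch_depth * (1 - (2 * u / spec$arch_width)^2)
}

arch_tooth_positions <- function(spec) {
  nq <- spec$n_teeth_per_quadrant
  spacing <- (spec$arch_width / 2) / nq
  out <- NULL
  for (quadrant in c(1L, 2L)) {
    for (pos in seq_len(nq)) {
      u <- (pos - 0.5) * spacing * if (quadrant == 1L) -1 else 1
      out <- rbind(out, data.frame(label = 10L * quadrant + pos,
                                   quadrant = quadrant, position = pos,
                                   u = u, v = arch_curve_y(u, spec)))
    }
  }
  out
}

#' Generate a synthetic upper dental arch
#'
#' Places `2 * n_teeth_per_quadrant` labelled crowns on a parabolic arch
#' curve in the z = 0 plane, occlusal surfaces toward +z, FDI quadrant 1 on
#' one side of the midline and quadrant 2 on the other. Deterministic for a
#' given `spec` (including its seed).
#'
#' @param spec An [arch_spec()].
#' @param patient_id,timepoint Metadata for the returned scan.
#' @return A [labeled_scan()].
#' @export
generate_arch <- function(spec = arch_spec(), patient_id = "synthetic",
                          timepoint = "T1") {
  cm_assert(inherits(spec, "arch_spec"), "spec must be an arch_spec()",
            "config_error")
  layout <- arch_tooth_positions(spec)
  interior <- c(0, spec$arch_depth * 0.4)
  with_seed(spec$seed, {
    pts <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      row <- layout[i, ]
      cls <- tooth_class(row$position)
      local_pts <- sample_crown(spec$points_per_tooth,
                                spec$crown_radii[[cls]],
                                CROWN_EXPONENT[[cls]], spec$crown_height,
                                CAP_RELIEF[[cls]])
      # local frame: x along the arch tangent, y buccal (outward), z up
      slope <- -8 * spec$arch_depth * row$u / spec$arch_width^2
      tangent <- c(1, slope) / sqrt(1 + slope^2)
      normal <- c(slope, -1) / sqrt(1 + slope^2)
      if (sum(normal * (c(row$u, row$v) - interior)) < 0) normal <- -normal
      center <- c(row$u, row$v, 0)
      world <- cbind(
        center[1] + local_pts[, 1] * tangent[1] + local_pts[, 2] * normal[1],
        center[2] + local_pts[, 1] * tangent[2] + local_pts[, 2] * normal[2],
        local_pts[, 3])
      pts[[i]] <- world
    }
    labeled_scan(do.call(rbind, pts),
                 rep(layout$label, each = spec$points_per_tooth),
                 patient_id = patient_id, timepoint = timepoint)
  })
}

#' Ground-truth movement of one tooth
#'
#' @param tooth_id FDI tooth number.
#' @param components A [movement_components()] vector.
#' @param center 3-vector, mm: the rotation centre (by convention the
#'   centroid of the tooth's pre-treatment points).
#' @return List of class `ground_truth_movement`.
#' @export
ground_truth_movement <- function(tooth_id, components, center) {
  cm_assert(inherits(components, "movement_components"),
            "components must be movement_components()", "config_error")
  center <- as.numeric(center)
  cm_assert(length(center) == 3L && all(is.finite(center)),
            "center must be a finite 3-vector", "config_error")
  structure(list(tooth_id = as.integer(tooth_id), components = components,
                 center = center),
            class = "ground_truth_movement")
}

# transform realizing movement components about `center` in `frame` axes
movement_to_transform <- function(components, frame, center) {
  B <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  Rp <- euler_to_rotation(components[["Rx"]], components[["Ry"]],
                          components[["Rz"]])
  Rg <- B %*% Rp %*% t(B)
  tv <- as.vector(B %*% c(components[["Tx"]], components[["Ty"]],
                          components[["Tz"]]))
  rigid_transform(Rg, center - as.vector(Rg %*% center) + tv)
}

#' Apply a ground-truth movement to one tooth of a scan
#'
#' Rotates the named tooth by (Rx, Ry, Rz) about the frame axes at the
#' movement's centre (fixed-axes x–y–z order), then translates it by
#' (Tx, Ty, Tz) along the frame axes. All other points are returned
#' bit-identical.
#'
#' @param scan A [labeled_scan()].
#' @param movement A [ground_truth_movement()]; its tooth must be in `scan`.
#' @param frame An [arch_frame()] supplying the axes.
#' @return The modified [labeled_scan()].
#' @export
apply_movement <- function(scan, movement, frame) {
  cm_assert(inherits(scan, "labeled_scan"), "scan must be a labeled_scan",
            "config_error")
  cm_assert(inherits(movement, "ground_truth_movement"),
            "movement must be a ground_truth_movement()", "config_error")
  if (!movement$tooth_id %in% scan$labels)
    cm_stop(sprintf("tooth %d not present in scan", movement$tooth_id),
            "lookup_error")
  if (all(movement$components == 0)) return(scan)
  tf <- movement_to_transform(movement$components, frame, movement$center)
  sel <- scan$labels == movement$tooth_id
  scan$points[sel, ] <- apply_transform(scan$points[sel, , drop = FALSE], tf)
  scan
}

#' Add isotropic Gaussian scanner noise
#'
#' Perturbs every point by zero-mean Gaussian noise of standard deviation
#' `sigma` per coordinate, emulating a laser scanner with an accuracy of
#' roughly `sigma` (default use: 0.020 mm, i.e. 20 micrometres). Labels are
#' preserved; deterministic given the seed.
#'
#' @param scan A [labeled_scan()].
#' @param sigma Per-coordinate noise SD, mm (>= 0).
#' @param seed Integer seed.
#' @return The perturbed [labeled_scan()].
#' @export
add_scan_noise <- function(scan, sigma, seed) {
  cm_assert(inherits(scan, "labeled_scan"), "scan must be a labeled_scan",
            "config_error")
  cm_assert(is.numeric(sigma) && length(sigma) == 1L && is.finite(sigma) &&
              sigma >= 0, "sigma must be a single value >= 0", "config_error")
  if (sigma == 0) return(scan)
  n <- nrow(scan$points)
  with_seed(seed, {
    scan$points <- scan$points + matrix(rnorm(3L * n, sd = sigma), n, 3L)
  })
  scan
}
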