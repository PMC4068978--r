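# Cohort-level simulation: split-mouth patients with one moved tooth per
# hemiarch, per-subgroup planned magnitudes and staging, true efficacy
# drawn from a truncated normal, and independent scanner noise on every
# scan. The default configurations reproduce the conditions of the
# published split-mouth aligner study the summary tables in reference.R
# come from.

STAGING_CAP <- c(derotation = 2.0, torque = 1.0, distalization = 0.25)
MOVED_POSITION <- c(torque = 1L, derotation = 4L, distalization = 6L)

#' Configuration of one simulated subgroup
#'
#' @param count Number of movements to simulate for this subgroup (>= 1).
#' @param group Movement group: `"torque"`, `"derotation"` or
#'   `"distalization"`.
#' @param subgroup Auxiliary condition: `"attachment"`, `"none"` or
#'   `"power_ridge"`.
#' @param planned_magnitude_range Interval the planned primary magnitude is
#'   drawn from uniformly (degrees for rotations, mm for distalization).
#' @param staging_per_aligner Programmed movement per aligner. Capped at
#'   the protocol limits: 2 deg/aligner for derotation, 1 deg/aligner for
#'   torque, 0.25 mm/aligner for distalization.
#' @param true_efficacy_mean,true_efficacy_sd Mean and SD (as fractions,
#'   1 = 100%) of the per-patient true efficacy, drawn from a normal
#'   truncated to \[-0.25, 1.25\] so that wrong-direction and overshoot
#'   outcomes occur, as observed clinically.
#' @param noise_sigma Per-coordinate scanner noise SD, mm (default 0.020,
#'   i.e. the ~20 micrometre accuracy of a cast laser scanner).
#' @param compliance_hours_per_day Recorded wear time (default the
#'   prescribed 22 h/day).
#' @param seed Integer seed for this subgroup's draws.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(count, group, subgroup, planned_magnitude_range,
                          staging_per_aligner, true_efficacy_mean,
                          true_efficacy_sd, noise_sigma = 0.020,
                          compliance_hours_per_day = 22, seed = 1L) {
  cm_assert(length(count) == 1L && count >= 1, "count must be >= 1",
            "config_error")
  cm_assert(group %in% GROUPS,
            sprintf("group must be one of: %s (got '%s')",
                    paste(GROUPS, collapse = ", "), group), "config_error")
  cm_assert(subgroup %in% SUBGROUPS,
            sprintf("subgroup must be one of: %s (got '%s')",
                    paste(SUBGROUPS, collapse = ", "), subgroup),
            "config_error")
  rng <- as.numeric(planned_magnitude_range)
  cm_assert(length(rng) == 2L && all(is.finite(rng)) && rng[1] > 0 &&
              rng[1] <= rng[2],
            "planned_magnitude_range must be a positive increasing interval",
            "config_error")
  cm_assert(staging_per_aligner > 0 &&
              staging_per_aligner <= STAGING_CAP[[group]],
            sprintf("staging for %s must lie in (0, %g] per aligner",
                    group, STAGING_CAP[[group]]), "config_error")
  cm_assert(true_efficacy_sd >= 0, "true_efficacy_sd must be >= 0",
            "config_error")
  cm_assert(noise_sigma >= 0, "noise_sigma must be >= 0", "config_error")
  cm_assert(compliance_hours_per_day > 0 && compliance_hours_per_day <= 24,
            "compliance_hours_per_day must lie in (0, 24]", "config_error")
  structure(list(count = as.integer(count), group = group,
                 subgroup = subgroup,
                 planned_magnitude_range = rng,
                 staging_per_aligner = staging_per_aligner,
                 true_efficacy_mean = true_efficacy_mean,
                 true_efficacy_sd = true_efficacy_sd,
                 noise_sigma = noise_sigma,
                 compliance_hours_per_day = compliance_hours_per_day,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# efficacy outcomes outside [-0.25, 1.25] are clinically implausible;
# the truncation still admits negative and >100% efficacies
TRUNC_LO <- -0.25
TRUNC_HI <- 1.25

rtrunc_norm <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmin(TRUNC_HI, pmax(TRUNC_LO, mean)), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= TRUNC_LO & x <= TRUNC_HI])
  }
  out[seq_len(n)]
}

#' Default study-condition subgroup configurations
#'
#' The six subgroup configurations of the emulated clinical study
#' (premolar derotation, molar distalization, upper incisor torque; each
#' with and without an auxiliary). Planned-magnitude ranges are uniform
#' intervals chosen to reproduce the study's mean planned movements
#' (17.8/20.1 deg derotation, 2.7/2.6 mm distalization, 16.1/15.9 deg
#' torque); stagings are the study's mean stagings, capped at the
#' protocol limits; true efficacies are the published subgroup means/SDs
#' (see [reference_efficacy_table()]).
#'
#' @param count Movements per subgroup (default 10, as in the study design).
#' @param noise_sigma Scanner noise SD, mm.
#' @param seed Base seed; each subgroup derives its own stream.
#' @return List of six [cohort_config()] objects.
#' @export
default_cohort_configs <- function(count = 10L, noise_sigma = 0.020,
                                   seed = 1L) {
  ref <- reference_efficacy_table()
  spec <- list(
    list("derotation", "attachment", c(10.0, 25.6), 1.1),
    list("derotation", "none", c(10.2, 30.0), 1.2),
    list("distalization", "attachment", c(2.2, 3.2), 0.2),
    list("distalization", "none", c(2.0, 3.2), 0.2),
    list("torque", "attachment", c(10.0, 22.2), 1.0),
    list("torque", "power_ridge", c(10.0, 21.8), 1.0))
  lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    r <- ref[ref$group == s[[1]] & ref$subgroup == s[[2]], ]
    cohort_config(count = count, group = s[[1]], subgroup = s[[2]],
                  planned_magnitude_range = s[[3]],
                  staging_per_aligner = s[[4]],
                  true_efficacy_mean = r$mean_accuracy / 100,
                  true_efficacy_sd = r$sd,
                  noise_sigma = noise_sigma,
                  seed = derive_seed(seed, "subgroup", s[[1]], s[[2]]))
  })
}

planned_components <- function(group, magnitude) {
  switch(group,
    distalization = movement_components(Tx = magnitude),
    torque = movement_components(Ry = magnitude),
    derotation = movement_components(Rz = magnitude))
}

scale_components <- function(components, factor) {
  movement_components(Tx = components[["Tx"]] * factor,
                      Ty = components[["Ty"]] * factor,
                      Tz = components[["Tz"]] * factor,
                      Rx = components[["Rx"]] * factor,
                      Ry = components[["Ry"]] * factor,
                      Rz = components[["Rz"]] * factor)
}

#' Generate a synthetic split-mouth cohort
#'
#' Builds one T1/T2/ClinT2 scan triplet per patient. Subgroup
#' configurations of the same movement group are paired split-mouth style:
#' each patient receives one moved tooth per hemiarch, the first subgroup
#' on a randomly drawn side and the second on the other, all other teeth
#' static. Per movement, the planned primary magnitude is drawn uniformly
#' from the configured range, the ClinT2 cast carries the full planned
#' movement, and the T2 cast carries `true_efficacy x planned` with the
#' true efficacy drawn from the configured truncated normal. Independent
#' Gaussian scanner noise is then added to all three scans.
#'
#' @param configs List of [cohort_config()] objects (typically
#'   [default_cohort_configs()]). All must share `noise_sigma`.
#' @param arch [arch_spec()] for the underlying arches.
#' @param seed Base seed for arch sampling, side assignment, magnitude and
#'   efficacy draws, and noise streams.
#' @return List with `patients` (named list of `list(t1, t2, clin_t2)`),
#'   `ground_truth` (list of [ground_truth_movement()] with the planned
#'   components), and `manifest` (one row per movement, including the
#'   drawn `true_efficacy`).
#' @export
generate_cohort <- function(configs, arch = arch_spec(), seed = 1L) {
  if (inherits(configs, "cohort_config")) configs <- list(configs)
  cm_assert(is.list(configs) && length(configs) >= 1L &&
              all(vapply(configs, inherits, logical(1), "cohort_config")),
            "configs must be a list of cohort_config objects", "config_error")
  sigmas <- vapply(configs, `[[`, numeric(1), "noise_sigma")
  cm_assert(length(unique(sigmas)) == 1L,
            "all configs must share the same noise_sigma", "config_error")
  noise_sigma <- sigmas[1]
  nq <- arch$n_teeth_per_quadrant
  for (cfg in configs)
    cm_assert(MOVED_POSITION[[cfg$group]] <= nq,
              sprintf("arch has too few teeth per quadrant for %s",
                      cfg$group), "config_error")

  patients <- list()
  ground_truth <- list()
  manifest <- NULL

  for (grp in GROUPS) {
    grp_cfgs <- Filter(function(cfg) cfg$group == grp, configs)
    if (length(grp_cfgs) == 0L) next
    cm_assert(length(grp_cfgs) <= 2L,
              sprintf("at most two subgroup configs per group (%s)", grp),
              "config_error")
    n_pat <- max(vapply(grp_cfgs, `[[`, integer(1), "count"))
    for (k in seq_len(n_pat)) {
      pid <- sprintf("%s_%02d", grp, k)
      pseed <- derive_seed(seed, "patient", grp, k)
      base <- generate_arch(
        arch_spec(n_teeth_per_quadrant = arch$n_teeth_per_quadrant,
                  arch_width = arch$arch_width, arch_depth = arch$arch_depth,
                  crown_height = arch$crown_height,
                  crown_radii = arch$crown_radii,
                  points_per_tooth = arch$points_per_tooth,
                  seed = derive_seed(pseed, "arch")),
        patient_id = pid, timepoint = "T1")
      # which subgroup config sits on which hemiarch (split-mouth)
      first_side <- with_seed(derive_seed(pseed, "side"), sample(c(1L, 2L), 1L))
      active <- Filter(function(ic) grp_cfgs[[ic]]$count >= k,
                       seq_along(grp_cfgs))
      sides <- if (first_side == 1L) c(1L, 2L) else c(2L, 1L)
      moved_ids <- vapply(seq_along(active), function(j)
        10L * sides[j] + MOVED_POSITION[[grp]], integer(1))
      ref_ids <- setdiff(scan_teeth(base), moved_ids)
      ref_centroids <- t(vapply(ref_ids, function(id)
        colMeans(tooth_points(base, id)), numeric(3)))
      occl <- base$points

      t2 <- base; t2$timepoint <- "T2"
      clin <- base; clin$timepoint <- "ClinT2"
      for (j in seq_along(active)) {
        cfg <- grp_cfgs[[active[j]]]
        id <- moved_ids[j]
        dseed <- derive_seed(cfg$seed, "draw", pid, id)
        draws <- with_seed(dseed, list(
          magnitude = runif(1, cfg$planned_magnitude_range[1],
                            cfg$planned_magnitude_range[2]),
          eff = rtrunc_norm(1, cfg$true_efficacy_mean, cfg$true_efficacy_sd)))
        center <- colMeans(tooth_points(base, id))
        frame <- build_frame(ref_centroids, center, occlusal_points = occl)
        planned <- planned_components(grp, draws$magnitude)
        gt <- ground_truth_movement(id, planned, center)
        clin <- apply_movement(clin, gt, frame)
        t2 <- apply_movement(
          t2, ground_truth_movement(id, scale_components(planned, draws$eff),
                                    center), frame)
        ground_truth[[length(ground_truth) + 1L]] <- gt
        manifest <- rbind(manifest, data.frame(
          patient_id = pid, group = grp, subgroup = cfg$subgroup,
          moved_tooth_id = id,
          planned_Tx = planned[["Tx"]], planned_Ty = planned[["Ty"]],
          planned_Tz = planned[["Tz"]], planned_Rx = planned[["Rx"]],
          planned_Ry = planned[["Ry"]], planned_Rz = planned[["Rz"]],
          planned_total = draws$magnitude,
          staging_per_aligner = cfg$staging_per_aligner,
          n_aligners = ceiling(draws$magnitude / cfg$staging_per_aligner),
          compliance_hours_per_day = cfg$compliance_hours_per_day,
          true_efficacy = draws$eff,
          stringsAsFactors = FALSE))
      }
      t1 <- add_scan_noise(base, noise_sigma, derive_seed(pseed, "noise", "T1"))
      t2 <- add_scan_noise(t2, noise_sigma, derive_seed(pseed, "noise", "T2"))
      clin <- add_scan_noise(clin, noise_sigma,
                             derive_seed(pseed, "noise", "ClinT2"))
      patients[[pid]] <- list(t1 = t1, t2 = t2, clin_t2 = clin)
    }
  }
  list(patients = patients, ground_truth = ground_truth,
       manifest = validate_manifest(manifest))
}
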