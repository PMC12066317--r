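#' Toy label atlas: mirrored tripartite STNs plus two cortical boxes
#'
#' Builds an MNI-like RAS-mm phantom on a cubic grid centered on the
#' world origin: two mirrored ellipsoidal subthalamic nuclei (half-length
#' `stn_half_length_mm` along a dorsolateral-to-ventromedial long axis,
#' transverse half-width `stn_half_width_mm`), each split into three
#' equal-thirds sublabels along that axis - sensorimotor (dorsal third),
#' associative (middle), limbic (ventral third) - plus an anterior/
#' superior "PFC-like" box and a posterior/superior "SMC-like" box as
#' cortical streamline targets.
#'
#' @param grid_shape Integer length-3 grid dimensions (>= 40 voxels each).
#' @param voxel_size_mm Isotropic voxel edge length in mm (<= 1).
#' @param stn_half_length_mm Semi-axis of the STN along its long axis.
#' @param stn_half_width_mm Transverse semi-axis.
#' @param tilt_deg Tilt of the STN long axis from vertical, in the x-z
#'   plane (dorsal end more lateral).
#' @return A `label_atlas` with legend entries
#'   `STN_<side>_{sensorimotor,associative,limbic}`, `PFC_box`,
#'   `SMC_box`, and region groups `STN_left`, `STN_right`.
#' @export
make_toy_atlas <- function(grid_shape = c(64, 64, 64), voxel_size_mm = 0.5,
                           stn_half_length_mm = 4, stn_half_width_mm = 1.75,
                           tilt_deg = 20) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 40))
    stop("grid must be at least 40 voxels per axis")
  if (voxel_size_mm > 1)
    stop("voxel size too coarse (> 1 mm)")
  third <- 2 * stn_half_length_mm / 3
  if (third / voxel_size_mm < 3)
    stop("voxel size too coarse to resolve STN sublabels (< 3 voxels per third)")
  # affine: world origin at the grid center
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  vol <- image_volume(array(0L, grid_shape), aff, space = "MNI-like")
  w <- grid_world_coords(vol)
  lab <- integer(nrow(w))

  theta <- tilt_deg * pi / 180
  geom <- list(
    stn_center = list(left = c(-6, 0, -2), right = c(6, 0, -2)),
    # long axis, ventral->dorsal; dorsal end more lateral on each side
    stn_axis = list(left = c(-sin(theta), 0, cos(theta)),
                    right = c(sin(theta), 0, cos(theta))),
    stn_half_length_mm = stn_half_length_mm,
    stn_half_width_mm = stn_half_width_mm,
    pfc_box = list(lo = c(-13, 6, 5), hi = c(13, 13, 12)),
    smc_box = list(lo = c(-13, -13, 5), hi = c(13, -6, 12)))

  next_label <- 0L
  legend <- integer(0)
  for (side in c("left", "right")) {
    ctr <- geom$stn_center[[side]]
    ax <- geom$stn_axis[[side]]
    p1 <- w[, 1] - ctr[1]; p2 <- w[, 2] - ctr[2]; p3 <- w[, 3] - ctr[3]
    t_ax <- p1 * ax[1] + p2 * ax[2] + p3 * ax[3]
    perp2 <- p1^2 + p2^2 + p3^2 - t_ax^2
    inside <- (t_ax / stn_half_length_mm)^2 + perp2 / stn_half_width_mm^2 <= 1
    cuts <- stn_half_length_mm / 3
    for (part in c("sensorimotor", "associative", "limbic")) {
      next_label <- next_label + 1L
      sel <- switch(part,
                    sensorimotor = inside & t_ax >= cuts,
                    associative = inside & t_ax > -cuts & t_ax < cuts,
                    limbic = inside & t_ax <= -cuts)
      lab[sel] <- next_label
      legend[paste0("STN_", side, "_", part)] <- next_label
    }
  }
  for (box in c("PFC_box", "SMC_box")) {
    b <- if (box == "PFC_box") geom$pfc_box else geom$smc_box
    next_label <- next_label + 1L
    sel <- w[, 1] >= b$lo[1] & w[, 1] <= b$hi[1] &
           w[, 2] >= b$lo[2] & w[, 2] <= b$hi[2] &
           w[, 3] >= b$lo[3] & w[, 3] <= b$hi[3]
    lab[sel] <- next_label
    legend[box] <- next_label
  }
  vol$data <- array(lab, grid_shape)
  label_atlas(vol, legend,
              region_groups = list(
                STN_left = unname(legend[paste0("STN_left_", c("sensorimotor", "associative", "limbic"))]),
                STN_right = unname(legend[paste0("STN_right_", c("sensorimotor", "associative", "limbic"))])),
              geometry = geom)
}

#' Place a four-contact electrode through one STN
#'
#' The lead runs vertically (along +z) through the ventral tip of the
#' chosen STN. With `dorsoventral_offset_mm = 0`, contact 0 (the most
#' distal) sits at the ventral STN border; positive offsets shift all
#' contacts dorsally by that many mm. Contacts are spaced
#' `spacing_mm` center-to-center. A uniform in-plane jitter of at most
#' `jitter_mm` (drawn from the current RNG) translates the whole lead.
#'
#' @param atlas A toy atlas from [make_toy_atlas()] (its stored geometry
#'   is used for placement).
#' @param hemisphere `"left"` or `"right"`.
#' @param dorsoventral_offset_mm Shift of the whole lead along +z.
#' @param active_contact Active contact index 0-3.
#' @param amplitude_v,frequency_hz,pulse_width_us Stimulation setting.
#' @param jitter_mm Maximum absolute in-plane (x, y) jitter; 0 disables.
#' @param patient_id Patient identifier.
#' @param spacing_mm Contact center-to-center spacing.
#' @return One-row electrode data frame (see [dbs_cohort()]).
#' @export
make_electrode <- function(atlas, hemisphere, dorsoventral_offset_mm = 0,
                           active_contact = 1L, amplitude_v = 2.5,
                           frequency_hz = 130, pulse_width_us = 60,
                           jitter_mm = 0.5, patient_id = "P01",
                           spacing_mm = 2) {
  geom <- atlas$geometry
  if (is.null(geom)) stop("atlas carries no generator geometry")
  ctr <- unlist(geom$stn_center[[hemisphere]])
  ax <- unlist(geom$stn_axis[[hemisphere]])
  tip <- ctr - geom$stn_half_length_mm * ax  # ventral STN border
  jit <- if (jitter_mm > 0) stats::runif(2, -jitter_mm, jitter_mm) else c(0, 0)
  base <- tip + c(jit, dorsoventral_offset_mm)
  cc <- t(vapply(0:3, function(k) base + c(0, 0, k * spacing_mm), numeric(3)))
  lim <- apply(abs(voxel_to_world(atlas$volume,
                                  rbind(c(0, 0, 0), dim(atlas$volume$data) - 1))),
               2, max)
  if (any(abs(cc[1, ]) > lim) )
    stop("electrode trajectory misses the grid")
  df <- data.frame(patient_id = patient_id, hemisphere = hemisphere,
                   stringsAsFactors = FALSE)
  df[contact_cols] <- as.list(as.vector(t(cc)))
  df$active_contact <- as.integer(active_contact)
  df$amplitude_v <- amplitude_v
  df$frequency_hz <- frequency_hz
  df$pulse_width_us <- pulse_width_us
  df$mode <- "monopolar"
  df
}

#' Synthetic two-bundle tractogram
#'
#' Bundle A ("PFC bundle"): smooth polylines from ventral/limbic STN
#' voxels (either side) to random points in the PFC-like box. Bundle B
#' ("SMC bundle"): from dorsal/sensorimotor STN voxels to the SMC-like
#' box. Each streamline is a quadratic Bezier sampled at `n_points`
#' vertices. Bundle membership is the fiber order: the first
#' `n_fibers_per_bundle` fibers are bundle A.
#'
#' @param atlas A toy atlas.
#' @param n_fibers_per_bundle Number of streamlines per bundle (>= 10).
#' @param n_points Vertices per streamline.
#' @return A `tractogram` with `2 * n_fibers_per_bundle` streamlines and
#'   a `bundle` attribute (character vector "PFC"/"SMC" per fiber).
#' @export
make_tractogram <- function(atlas, n_fibers_per_bundle = 200, n_points = 25) {
  if (n_fibers_per_bundle < 10)
    stop("need at least 10 fibers per bundle")
  vol <- atlas$volume
  seeds <- list(
    PFC = grid_world_coords_at(vol, c(region_voxels(atlas, "STN_left_limbic"),
                                      region_voxels(atlas, "STN_right_limbic"))),
    SMC = grid_world_coords_at(vol, c(region_voxels(atlas, "STN_left_sensorimotor"),
                                      region_voxels(atlas, "STN_right_sensorimotor"))))
  boxes <- list(PFC = atlas$geometry$pfc_box, SMC = atlas$geometry$smc_box)
  tt <- seq(0, 1, length.out = n_points)
  sl <- list(); bundle <- character(0)
  for (b in c("PFC", "SMC")) {
    sp <- seeds[[b]]
    box <- boxes[[b]]
    lo <- unlist(box$lo); hi <- unlist(box$hi)
    for (f in seq_len(n_fibers_per_bundle)) {
      p0 <- sp[sample.int(nrow(sp), 1), ]
      p2 <- lo + stats::runif(3) * (hi - lo)
      p1 <- (p0 + p2) / 2 + stats::rnorm(3, 0, 1.5)
      curve <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
        outer(tt^2, p2)
      sl[[length(sl) + 1L]] <- curve
      bundle <- c(bundle, b)
    }
  }
  out <- tractogram(sl)
  attr(out, "bundle") <- bundle
  out
}

grid_world_coords_at <- function(vol, lin_idx) {
  d <- dim(vol$data)
  i0 <- lin_idx - 1L
  ijk <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  voxel_to_world(vol, ijk)
}

scenario_weights <- function(scenario) {
  switch(scenario,
         ventral_effect = list(voxel = 8, pfc = 0.5, smc = -5, noise_sd = 1),
         tract_only = list(voxel = 0, pfc = 4, smc = -4, noise_sd = 1),
         null = list(voxel = 0, pfc = 0, smc = 0, noise_sd = 1),
         stop("unknown scenario: ", scenario))
}

#' Simulate clinical outcomes from planted ground truth
#'
#' Generative inverse of the analysis stages. For patient i the planted
#' HAMA change is
#' `change_i = w_v * |VTA_i ∩ sweet sphere| / |sphere| +
#'  w_PFC * connected_frac(i, PFC) + w_SMC * connected_frac(i, SMC) + e_i`
#' with `e_i ~ Normal(0, noise_sd)`; `connected_frac(i, b)` is the
#' fraction of bundle-b streamlines intersecting patient i's bilateral
#' VTA. HAMD shares the planted drivers at 80% weight with independent
#' noise. Baselines are drawn from plausible ranges (HAMA ~ U[5, 15]);
#' post = max(pre - change, 0). UPDRS-III/PDQ-39 improve by a fraction
#' of baseline plus noise, and LEDD drops to about 31% of baseline, so
#' cohort summary tables look like a real 6-month series.
#'
#' @param skeleton List/`dbs_cohort` with `atlas`, `electrodes`,
#'   `tractogram` (clinical may be absent).
#' @param ground_truth List with `sweet_center`, `sweet_radius`,
#'   `voxel_effect_weight`, `tract_effect_weights` (named `PFC`, `SMC`),
#'   `noise_sd`; bundle membership is taken from the tractogram's
#'   `bundle` attribute or `ground_truth$fiber_bundle`.
#' @param e_threshold_v_per_mm,contact_radius_mm VTA model parameters.
#' @return Clinical data frame (one row per patient).
#' @export
simulate_outcomes <- function(skeleton, ground_truth,
                              e_threshold_v_per_mm = 0.2,
                              contact_radius_mm = 0.635) {
  gt <- ground_truth
  atlas <- skeleton$atlas
  vol <- atlas$volume
  ids <- unique(skeleton$electrodes$patient_id)
  fake <- list(atlas = atlas, electrodes = skeleton$electrodes,
               clinical = data.frame(patient_id = ids))
  vtas <- patient_vta_voxels(fake, "both", e_threshold_v_per_mm,
                             contact_radius_mm)
  w <- grid_world_coords(vol)
  ctr <- unlist(gt$sweet_center)
  d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
  sphere <- which(d2 <= gt$sweet_radius^2)
  overlap_frac <- vapply(vtas, function(v)
    length(intersect(v, sphere)) / length(sphere), numeric(1))

  wts <- unlist(gt$tract_effect_weights)
  tract_term <- numeric(length(ids))
  if (any(wts != 0) && skeleton$tractogram$count > 0) {
    bundle <- attr(skeleton$tractogram, "bundle") %||% gt$fiber_bundle
    conn <- streamline_vta_connectivity(skeleton$tractogram, vtas, vol)
    for (b in names(wts)) {
      rows <- which(bundle == b)
      if (length(rows))
        tract_term <- tract_term +
          wts[[b]] * colSums(conn[rows, , drop = FALSE]) / length(rows)
    }
  }
  n <- length(ids)
  eps <- stats::rnorm(n, 0, gt$noise_sd)
  change_hama <- gt$voxel_effect_weight * overlap_frac + tract_term + eps
  change_hamd <- 0.8 * (gt$voxel_effect_weight * overlap_frac + tract_term) +
    stats::rnorm(n, 0, gt$noise_sd)

  hama_pre <- stats::runif(n, 5, 15)
  hamd_pre <- stats::runif(n, 6, 14)
  updrs3_pre <- stats::runif(n, 30, 60)
  pdq39_pre <- stats::runif(n, 40, 90)
  ledd_pre <- exp(stats::rnorm(n, log(725), 0.35))
  clinical <- data.frame(
    patient_id = ids,
    updrs3_pre = updrs3_pre,
    updrs3_post = pmax(updrs3_pre - (0.35 * updrs3_pre + stats::rnorm(n, 0, 4)), 0),
    pdq39_pre = pdq39_pre,
    pdq39_post = pmax(pdq39_pre - (0.25 * pdq39_pre + stats::rnorm(n, 0, 5)), 0),
    hama_pre = hama_pre,
    hama_post = pmax(hama_pre - change_hama, 0),
    hamd_pre = hamd_pre,
    hamd_post = pmax(hamd_pre - change_hamd, 0),
    ledd_pre = ledd_pre,
    ledd_post = ledd_pre * 0.31 * exp(stats::rnorm(n, 0, 0.15)),
    stringsAsFactors = FALSE)
  rownames(clinical) <- NULL
  clinical
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Scenarios: `"ventral_effect"` plants a sweet sphere in the
#' ventrocentral left STN (positive voxel weight) together with a
#' positive PFC-bundle and negative SMC-bundle tract effect, so cohort
#' change scores straddle zero; `"tract_only"` plants only the signed
#' bundle effects; `"null"` sets every effect weight to zero.
#'
#' @param n_patients Number of patients (>= 8; two electrodes each).
#' @param scenario One of `"ventral_effect"`, `"null"`, `"tract_only"`.
#' @param seed Integer RNG seed; regeneration from the same
#'   (scenario, seed) is bit-identical.
#' @param noise_sd Outcome noise SD; `NULL` uses the scenario default (1).
#' @param n_fibers_per_bundle Streamlines per bundle.
#' @param grid_shape,voxel_size_mm Atlas grid.
#' @return A `dbs_cohort` with a `ground_truth` block.
#' @export
generate_cohort <- function(n_patients = 56,
                            scenario = c("ventral_effect", "null", "tract_only"),
                            seed = 7, noise_sd = NULL,
                            n_fibers_per_bundle = 200,
                            grid_shape = c(64, 64, 64), voxel_size_mm = 0.5) {
  scenario <- match.arg(scenario)
  if (n_patients < 8) stop("need at least 8 patients")
  set.seed(seed)
  wts <- scenario_weights(scenario)
  if (!is.null(noise_sd)) wts$noise_sd <- noise_sd
  atlas <- make_toy_atlas(grid_shape, voxel_size_mm)
  geom <- atlas$geometry
  sweet_center <- unlist(geom$stn_center$left) -
    2 * unlist(geom$stn_axis$left)
  gt <- list(scenario = scenario, rng_seed = seed,
             sweet_center = sweet_center, sweet_radius = 2.5,
             voxel_effect_weight = wts$voxel,
             tract_effect_weights = list(PFC = wts$pfc, SMC = wts$smc),
             noise_sd = wts$noise_sd)

  ids <- sprintf("P%03d", seq_len(n_patients))
  el <- do.call(rbind, lapply(ids, function(pid) {
    do.call(rbind, lapply(c("left", "right"), function(h) {
      make_electrode(atlas, h,
                     dorsoventral_offset_mm = stats::runif(1, 0, 6),
                     active_contact = sample(0:2, 1),
                     amplitude_v = max(0.5, stats::rnorm(1, 2.5, 0.31)),
                     frequency_hz = stats::rnorm(1, 128.62, 18.74),
                     pulse_width_us = stats::rnorm(1, 64.29, 6.64),
                     jitter_mm = 0.5, patient_id = pid)
    }))
  }))
  tract <- make_tractogram(atlas, n_fibers_per_bundle)
  gt$fiber_bundle <- attr(tract, "bundle")
  skeleton <- list(atlas = atlas, electrodes = el, tractogram = tract)
  clinical <- simulate_outcomes(skeleton, gt)
  dbs_cohort(atlas, el, clinical, tract, ground_truth = gt)
}
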