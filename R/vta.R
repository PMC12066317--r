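#' Electric-field magnitude of a monopolar point-source contact
#'
#' Quasi-static homogeneous-medium model centered at the active contact:
#' `|E|(r) = U * r_c / r^2` for `r >= r_c`, where `U` is the stimulation
#' amplitude in volts and `r_c` the contact radius in mm; inside the
#' contact (`r < r_c`) the field is clamped to `|E|(r_c) = U / r_c`.
#' Units are V/mm. This analytic field stands behind the same
#' thresholding semantics as finite-element VTA models: the binary VTA
#' is the region where `|E|` exceeds a fixed activation threshold.
#' Pulse width and frequency are carried on the electrode record but do
#' not enter this field model.
#'
#' @param electrode One-row electrode record (see [dbs_cohort()]).
#' @param points n x 3 matrix of world-mm points.
#' @param contact_radius_mm Contact radius r_c in mm.
#' @return Numeric vector of |E| values (V/mm) at `points`.
#' @export
field_magnitude <- function(electrode, points, contact_radius_mm = 0.635) {
  if (electrode$mode[1] != "monopolar")
    stop("unsupported stimulation mode: ", electrode$mode[1],
         " (only monopolar is modelled)")
  u <- electrode$amplitude_v[1]
  cc <- unname(electrode_contacts(electrode)[electrode$active_contact[1] + 1L, ])
  points <- rbind_coords(points)
  r <- sqrt((points[, 1] - cc[1])^2 + (points[, 2] - cc[2])^2 +
            (points[, 3] - cc[3])^2)
  r <- pmax(r, contact_radius_mm)
  unname(u * contact_radius_mm / r^2)
}

#' Analytic VTA radius of the point-source model
#'
#' Radius at which the point-source field falls to the activation
#' threshold: `r* = sqrt(U * r_c / E_th)`.
#'
#' @param amplitude_v Stimulation amplitude U (volts).
#' @param e_threshold_v_per_mm Activation threshold (V/mm).
#' @param contact_radius_mm Contact radius (mm).
#' @return Radius in mm (0 when the amplitude is 0).
#' @export
vta_radius <- function(amplitude_v, e_threshold_v_per_mm = 0.2,
                       contact_radius_mm = 0.635) {
  sqrt(amplitude_v * contact_radius_mm / e_threshold_v_per_mm)
}

#' Estimate a binary VTA on a voxel grid
#'
#' Voxels whose center field magnitude meets or exceeds the activation
#' threshold (default 0.2 V/mm) form the VTA. For the point-source model
#' this approximates a ball of radius [vta_radius()] around the active
#' contact.
#'
#' @param electrode One-row electrode record.
#' @param grid `image_volume` (or `label_atlas`) defining the voxel grid.
#' @param e_threshold_v_per_mm Activation threshold in V/mm.
#' @param contact_radius_mm Contact radius in mm.
#' @return An object of class `vta_mask`: linear voxel indices into the
#'   grid (`voxels`), `volume_mm3`, `patient_id`, `hemisphere`,
#'   `threshold_v_per_mm`, `grid_dim`.
#' @export
estimate_vta <- function(electrode, grid, e_threshold_v_per_mm = 0.2,
                         contact_radius_mm = 0.635) {
  if (inherits(grid, "label_atlas")) grid <- grid$volume
  d <- dim(grid$data)
  cc <- electrode_contacts(electrode)[electrode$active_contact[1] + 1L, ]
  ijk_c <- world_to_voxel(grid, cc)[1, ]
  if (any(ijk_c < -0.5) || any(ijk_c > d - 0.5))
    stop("active contact lies outside the grid for patient ",
         electrode$patient_id[1], " (", electrode$hemisphere[1], ")")
  u <- electrode$amplitude_v[1]
  rstar <- vta_radius(u, e_threshold_v_per_mm, contact_radius_mm)
  vox <- integer(0)
  if (u > 0) {
    margin <- rstar / min(voxel_size(grid)) + 1
    lo <- pmax(floor(ijk_c - margin), 0)
    hi <- pmin(ceiling(ijk_c + margin), d - 1)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    ijk <- cbind(rep.int(ii, length(jj) * length(kk)),
                 rep.int(rep(jj, each = length(ii)), length(kk)),
                 rep(kk, each = length(ii) * length(jj)))
    xyz <- voxel_to_world(grid, ijk)
    e <- field_magnitude(electrode, xyz, contact_radius_mm)
    keep <- e >= e_threshold_v_per_mm
    vox <- as.integer(1 + ijk[keep, 1] + d[1] * (ijk[keep, 2] + d[2] * ijk[keep, 3]))
    vox <- sort(vox)
  }
  structure(list(voxels = vox, grid_dim = d,
                 volume_mm3 = length(vox) * voxel_volume_mm3(grid),
                 patient_id = electrode$patient_id[1],
                 hemisphere = electrode$hemisphere[1],
                 threshold_v_per_mm = e_threshold_v_per_mm),
            class = "vta_mask")
}

#' Render a VTA mask as a binary image volume
#' @param vta A `vta_mask`.
#' @param grid The `image_volume` the mask was computed on.
#' @return Binary `image_volume`.
#' @export
vta_as_image <- function(vta, grid) {
  if (inherits(grid, "label_atlas")) grid <- grid$volume
  a <- array(0L, dim(grid$data))
  a[vta$voxels] <- 1L
  image_volume(a, grid$affine, space = grid$space)
}

#' Quantify VTA overlap with atlas regions
#'
#' One row per region: intersection volume in cubic mm and the fraction
#' of the region's volume covered. Regions are all legend entries plus
#' any composite region groups (e.g. whole left/right STN).
#'
#' @param vta A `vta_mask` computed on the atlas grid.
#' @param atlas A `label_atlas`.
#' @return Data frame with columns `patient_id`, `hemisphere`,
#'   `region_label`, `overlap_mm3`, `overlap_fraction_of_region`.
#' @export
overlap_with_atlas <- function(vta, atlas) {
  if (!identical(vta$grid_dim, dim(atlas$volume$data)))
    stop("VTA and atlas grids differ; compute the VTA on the atlas grid")
  vv <- voxel_volume_mm3(atlas$volume)
  labels <- atlas$volume$data[vta$voxels]
  regions <- c(as.list(atlas$legend), atlas$region_groups)
  region_sizes <- tabulate(atlas$volume$data[atlas$volume$data > 0],
                           nbins = max(unlist(regions)))
  rows <- lapply(names(regions), function(nm) {
    labs <- regions[[nm]]
    inter <- sum(labels %in% labs)
    size <- sum(region_sizes[labs])
    data.frame(patient_id = vta$patient_id, hemisphere = vta$hemisphere,
               region_label = nm, overlap_mm3 = inter * vv,
               overlap_fraction_of_region = if (size > 0) inter / size else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap table for a whole cohort
#'
#' @param cohort A `dbs_cohort`.
#' @param e_threshold_v_per_mm Activation threshold in V/mm.
#' @param contact_radius_mm Contact radius in mm.
#' @return Data frame of per-(patient, hemisphere, region) overlaps.
#' @export
cohort_overlap_table <- function(cohort, e_threshold_v_per_mm = 0.2,
                                 contact_radius_mm = 0.635) {
  el <- cohort$electrodes
  do.call(rbind, lapply(seq_len(nrow(el)), function(i) {
    vta <- estimate_vta(el[i, ], cohort$atlas, e_threshold_v_per_mm,
                        contact_radius_mm)
    overlap_with_atlas(vta, cohort$atlas)
  }))
}

#' Active-contact world coordinates
#'
#' @param cohort A `dbs_cohort` (or an electrode data frame).
#' @return Data frame with `patient_id`, `hemisphere`, `x`, `y`, `z` of
#'   the active contact.
#' @export
active_contact_coordinates <- function(cohort) {
  el <- if (inherits(cohort, "dbs_cohort")) cohort$electrodes else cohort
  coords <- t(vapply(seq_len(nrow(el)), function(i)
    electrode_contacts(el[i, ])[el$active_contact[i] + 1L, ], numeric(3)))
  data.frame(patient_id = el$patient_id, hemisphere = el$hemisphere,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

#' Per-patient VTA voxel sets (union of both hemispheres)
#'
#' @param cohort A `dbs_cohort`.
#' @param hemisphere `"both"` (union, default), `"left"` or `"right"`.
#' @param e_threshold_v_per_mm Activation threshold in V/mm.
#' @param contact_radius_mm Contact radius in mm.
#' @return Named list (by patient id) of sorted linear voxel indices
#'   into the atlas grid.
#' @export
patient_vta_voxels <- function(cohort, hemisphere = "both",
                               e_threshold_v_per_mm = 0.2,
                               contact_radius_mm = 0.635) {
  el <- cohort$electrodes
  if (hemisphere != "both") el <- el[el$hemisphere == hemisphere, ]
  ids <- unique(cohort$clinical$patient_id)
  out <- lapply(ids, function(pid) {
    rows <- which(el$patient_id == pid)
    vox <- lapply(rows, function(i)
      estimate_vta(el[i, ], cohort$atlas, e_threshold_v_per_mm,
                   contact_radius_mm)$voxels)
    sort(unique(unlist(vox)))
  })
  names(out) <- ids
  out
}
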