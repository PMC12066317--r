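#' @title Cohort dataset: atlas + electrodes + clinical scores + tractogram
#'
#' @description
#' The unit every analysis stage consumes. Electrode records are one row
#' per (patient, hemisphere): four ordered contact coordinates (contact 0
#' most distal/ventral), the active contact index (0-3) and the
#' stimulation setting (amplitude in volts, frequency in Hz, pulse width
#' in microseconds, monopolar mode). Clinical records are one row per
#' patient with pre/post scores per scale; the change convention is
#' `change = pre - post`, so positive change means improvement on scales
#' where lower is better (HAMA, HAMD, UPDRS-III, PDQ-39, LEDD).
#'
#' @param atlas A `label_atlas`.
#' @param electrodes Data frame of electrode records (see Details).
#' @param clinical Data frame of clinical records.
#' @param tractogram A `tractogram`.
#' @param ground_truth Optional list describing planted effects
#'   (synthetic cohorts only).
#' @details Electrode columns: `patient_id`, `hemisphere` ("left"/"right"),
#'   `c0x,c0y,c0z,...,c3x,c3y,c3z`, `active_contact`, `amplitude_v`,
#'   `frequency_hz`, `pulse_width_us`, `mode`.
#'   Clinical columns: `patient_id` plus `<scale>_pre`/`<scale>_post` for
#'   scales `updrs3`, `pdq39`, `hama`, `hamd`, `ledd`.
#' @return An object of class `dbs_cohort`.
#' @export
dbs_cohort <- function(atlas, electrodes, clinical, tractogram,
                       ground_truth = NULL) {
  obj <- structure(list(atlas = atlas, electrodes = electrodes,
                        clinical = clinical, tractogram = tractogram,
                        ground_truth = ground_truth),
                   class = "dbs_cohort")
  validate_cohort(obj)
  obj
}

#' @export
print.dbs_cohort <- function(x, ...) {
  cat(sprintf("<dbs_cohort> %d patients, %d electrode records, %d streamlines\n",
              nrow(x$clinical), nrow(x$electrodes), x$tractogram$count))
  if (!is.null(x$ground_truth))
    cat("  synthetic cohort, scenario:", x$ground_truth$scenario, "\n")
  invisible(x)
}

contact_cols <- as.vector(t(outer(paste0("c", 0:3), c("x", "y", "z"), paste0)))

#' Contact coordinates of one electrode record
#' @param row One-row slice of the electrode data frame.
#' @return 4 x 3 matrix of world-mm contact coordinates (contact 0 first).
#' @export
electrode_contacts <- function(row) {
  matrix(as.numeric(row[1, contact_cols]), nrow = 4, byrow = TRUE,
         dimnames = list(paste0("contact", 0:3), c("x", "y", "z")))
}

#' Validate cross-file cohort invariants
#'
#' Collects every violation (not just the first) and raises a single
#' error listing all of them.
#'
#' @param cohort A `dbs_cohort` (or list with the same fields).
#' @param lead_spacing_mm Expected center-to-center contact spacing.
#' @return TRUE invisibly on success.
#' @export
validate_cohort <- function(cohort, lead_spacing_mm = 2) {
  el <- cohort$electrodes
  cl <- cohort$clinical
  bad <- character()
  need <- c("patient_id", "hemisphere", contact_cols, "active_contact",
            "amplitude_v", "frequency_hz", "pulse_width_us", "mode")
  miss <- setdiff(need, names(el))
  if (length(miss))
    bad <- c(bad, paste("electrode table missing columns:",
                        paste(miss, collapse = ", ")))
  if (!length(miss)) {
    only_el <- setdiff(el$patient_id, cl$patient_id)
    only_cl <- setdiff(cl$patient_id, el$patient_id)
    if (length(only_el))
      bad <- c(bad, paste("patients with electrodes but no clinical record:",
                          paste(unique(only_el), collapse = ", ")))
    if (length(only_cl))
      bad <- c(bad, paste("patients with clinical record but no electrodes:",
                          paste(unique(only_cl), collapse = ", ")))
    key <- paste(el$patient_id, el$hemisphere)
    if (anyDuplicated(key))
      bad <- c(bad, paste("duplicate (patient, hemisphere) rows:",
                          paste(unique(key[duplicated(key)]), collapse = ", ")))
    n_hemi <- table(el$patient_id)
    if (any(n_hemi != 2))
      bad <- c(bad, paste("patients without exactly one record per hemisphere:",
                          paste(names(n_hemi)[n_hemi != 2], collapse = ", ")))
    if (any(el$amplitude_v < 0))
      bad <- c(bad, paste("negative amplitude for:",
                          paste(el$patient_id[el$amplitude_v < 0], collapse = ", ")))
    if (any(!el$active_contact %in% 0:3))
      bad <- c(bad, "active_contact outside 0-3")
    if (any(el$mode != "monopolar"))
      bad <- c(bad, "unsupported stimulation mode (only monopolar)")
    for (i in seq_len(nrow(el))) {
      cc <- electrode_contacts(el[i, ])
      d <- diff(cc)
      span <- sqrt(rowSums(d^2))
      if (any(abs(span - lead_spacing_mm) > 0.2))
        bad <- c(bad, sprintf("electrode %s/%s: contact spacing deviates from %g mm",
                              el$patient_id[i], el$hemisphere[i], lead_spacing_mm))
      if (nrow(cc) == 4) {
        u <- d / span
        if (max(abs(sweep(u, 2, u[1, ]))) > 0.05)
          bad <- c(bad, sprintf("electrode %s/%s: contacts not collinear",
                                el$patient_id[i], el$hemisphere[i]))
      }
    }
  }
  if (anyDuplicated(cl$patient_id))
    bad <- c(bad, "duplicate patient_id in clinical table")
  if (length(bad))
    stop("cohort validation failed:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

#' Per-patient change scores for one scale
#'
#' @param clinical Clinical data frame.
#' @param scale Scale name, e.g. `"HAMA"` (case-insensitive; maps to the
#'   `<scale>_pre`/`<scale>_post` columns).
#' @param measure `"change"` (pre - post) or `"improvement"`
#'   (percent improvement rate).
#' @return Named numeric vector, one value per patient.
#' @export
clinical_outcome <- function(clinical, scale = "HAMA", measure = "change") {
  s <- tolower(gsub("[^A-Za-z0-9]", "", scale))
  s <- sub("^updrsiii$", "updrs3", s)
  pre <- clinical[[paste0(s, "_pre")]]
  post <- clinical[[paste0(s, "_post")]]
  if (is.null(pre) || is.null(post))
    stop("scale not present in clinical table: ", scale)
  out <- switch(measure,
                change = pre - post,
                improvement = improvement_rate(pre, post),
                stop("unknown measure: ", measure))
  names(out) <- clinical$patient_id
  out
}

#' Write a cohort to a run directory
#'
#' Writes atlas NIfTI, electrodes CSV, clinical CSV, tractogram TCK,
#' optional ground-truth JSON, an atlas legend JSON, and a YAML config
#' manifest naming them all.
#'
#' @param cohort A `dbs_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path to the written config file.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(cohort$atlas$volume, file.path(dir, "atlas.nii.gz"),
              datatype = "int16")
  legend <- list(legend = as.list(cohort$atlas$legend),
                 region_groups = cohort$atlas$region_groups,
                 geometry = cohort$atlas$geometry)
  jsonlite::write_json(legend, file.path(dir, "atlas_legend.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(cohort$electrodes, file.path(dir, "electrodes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  write_tractogram(cohort$tractogram, file.path(dir, "tractogram.tck"))
  cfg <- list(atlas = "atlas.nii.gz", atlas_legend = "atlas_legend.json",
              electrodes = "electrodes.csv", clinical = "clinical.csv",
              tractogram = "tractogram.tck", space = cohort$atlas$volume$space)
  if (!is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    cfg$ground_truth <- "ground_truth.json"
  }
  path <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(cfg, path)
  path
}

#' Read a cohort from a config manifest
#'
#' @param config_path Path to a YAML (or JSON) config naming the atlas,
#'   electrode CSV, clinical CSV and tractogram; paths are resolved
#'   relative to the config file.
#' @return A validated `dbs_cohort`.
#' @export
read_cohort <- function(config_path) {
  if (!file.exists(config_path)) stop("config not found: ", config_path)
  cfg <- if (grepl("\\.json$", config_path)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else yaml::read_yaml(config_path)
  base <- dirname(config_path)
  p <- function(f) file.path(base, f)
  vol <- read_image(p(cfg$atlas), space = cfg$space %||% "MNI-like")
  vol$data <- array(as.integer(round(vol$data)), dim(vol$data))
  lg <- jsonlite::read_json(p(cfg$atlas_legend), simplifyVector = TRUE)
  atlas <- label_atlas(vol, legend = unlist(lg$legend),
                       region_groups = lapply(lg$region_groups, as.integer),
                       geometry = lg$geometry)
  electrodes <- utils::read.csv(p(cfg$electrodes), stringsAsFactors = FALSE)
  clinical <- utils::read.csv(p(cfg$clinical), stringsAsFactors = FALSE)
  gt <- NULL
  if (!is.null(cfg$ground_truth))
    gt <- jsonlite::read_json(p(cfg$ground_truth), simplifyVector = TRUE)
  dbs_cohort(atlas, electrodes, clinical, tractogram = read_tractogram(p(cfg$tractogram)),
             ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
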