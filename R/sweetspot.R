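#' N-image: per-voxel VTA coverage counts
#'
#' @param vtas List of per-patient linear voxel index vectors (each the
#'   union of that patient's bilateral VTAs, or a single hemisphere).
#' @param grid `image_volume` (or `label_atlas`) defining the grid.
#' @return `image_volume` of integer counts.
#' @export
build_n_image <- function(vtas, grid) {
  if (inherits(grid, "label_atlas")) grid <- grid$volume
  counts <- n_image_counts(vtas, prod(dim(grid$data)))
  image_volume(array(counts, dim(grid$data)), grid$affine, grid$space)
}

n_image_counts <- function(vtas, nvox) {
  if (length(vtas) == 0) return(integer(nvox))
  tabulate(unlist(vtas, use.names = FALSE), nbins = nvox)
}

#' Coverage filter: exclude poorly covered voxels
#'
#' A voxel is kept iff its VTA count is at least
#' `ceiling(fraction * n_vtas)` (i.e. voxels covered by less than the
#' coverage fraction of VTAs are excluded).
#'
#' @param n_image `image_volume` of counts (or an integer vector).
#' @param n_vtas Number of VTAs entering the N-image.
#' @param fraction Coverage fraction in (0, 1); default 0.2.
#' @return Logical `image_volume` (or vector, matching the input type).
#' @export
coverage_filter <- function(n_image, n_vtas, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  need <- ceiling(fraction * n_vtas)
  if (inherits(n_image, "image_volume")) {
    image_volume(n_image$data >= need, n_image$affine, n_image$space)
  } else n_image >= need
}

# Core index-space fit shared by the map builder and cross-validation.
# Returns kept voxel indices plus per-kept-voxel count, mean, p, q, label.
sweetspot_fit <- function(vtas, changes, nvox, coverage_fraction = 0.2,
                          alpha = 0.05) {
  n <- length(vtas)
  stopifnot(length(changes) == n)
  counts <- n_image_counts(vtas, nvox)
  kept <- which(counts >= ceiling(coverage_fraction * n))
  m <- length(kept)
  if (m == 0)
    return(list(kept = integer(0), counts = counts, mean = numeric(0),
                p = numeric(0), q = numeric(0), label = integer(0),
                n_vtas = n, alpha = alpha,
                coverage_fraction = coverage_fraction))
  # patient-coverage matrix restricted to kept voxels
  cov <- matrix(FALSE, n, m)
  g <- logical(nvox)
  for (i in seq_len(n)) {
    g[vtas[[i]]] <- TRUE
    cov[i, ] <- g[kept]
    g[vtas[[i]]] <- FALSE
  }
  # group kept voxels sharing the same covering-patient pattern: the test
  # and mean are identical within a group, so compute each pattern once
  grp <- pattern_groups(cov)
  mean_v <- numeric(m); p_v <- numeric(m)
  for (members in split(seq_len(m), grp)) {
    x <- changes[cov[, members[1]]]
    mean_v[members] <- mean(x)
    p_v[members] <- signed_rank_test(x)$p_value
  }
  q_v <- stats::p.adjust(p_v, method = "BH")
  lab <- integer(m)
  lab[q_v <= alpha & mean_v > 0] <- 1L
  lab[q_v <= alpha & mean_v < 0] <- -1L
  list(kept = kept, counts = counts, mean = mean_v, p = p_v, q = q_v,
       label = lab, n_vtas = n, alpha = alpha,
       coverage_fraction = coverage_fraction)
}

# collision-free pattern grouping: chunk the n patient bits into <= 30-bit
# words, lexicographically sort the word tuples and cut at value changes
pattern_groups <- function(cov) {
  n <- nrow(cov); m <- ncol(cov)
  starts <- seq(1, n, by = 30)
  K <- vapply(starts, function(s) {
    rows <- s:min(s + 29, n)
    as.vector(2^(seq_along(rows) - 1) %*% cov[rows, , drop = FALSE])
  }, numeric(m))
  K <- matrix(K, nrow = m)
  ord <- do.call(order, lapply(seq_len(ncol(K)), function(j) K[, j]))
  Ko <- K[ord, , drop = FALSE]
  new <- c(TRUE, rowSums(abs(Ko[-1, , drop = FALSE] -
                             Ko[-m, , drop = FALSE])) > 0)
  grp <- integer(m)
  grp[ord] <- cumsum(new)
  grp
}

#' Mean effect map
#'
#' Voxel value = mean outcome change over the patients whose VTA covers
#' that voxel; NaN outside the kept mask.
#'
#' @param vtas List of per-patient voxel index vectors.
#' @param changes Outcome change per patient.
#' @param kept_mask Logical `image_volume` from [coverage_filter()].
#' @return `image_volume` of mean changes.
#' @export
mean_effect_map <- function(vtas, changes, kept_mask) {
  nvox <- prod(dim(kept_mask$data))
  sums <- numeric(nvox); counts <- numeric(nvox)
  for (i in seq_along(vtas)) {
    v <- vtas[[i]]
    sums[v] <- sums[v] + changes[i]
    counts[v] <- counts[v] + 1
  }
  out <- rep(NaN, nvox)
  kv <- which(as.vector(kept_mask$data))
  stopifnot(all(counts[kv] > 0))
  out[kv] <- sums[kv] / counts[kv]
  image_volume(array(out, dim(kept_mask$data)), kept_mask$affine,
               kept_mask$space)
}

#' Voxel-wise Wilcoxon signed-rank p-map
#'
#' Per kept voxel, a two-sided signed-rank test of the covering
#' patients' change scores against zero (see [signed_rank_test()] for
#' the exact/approximate branches and zero/tie conventions). A voxel
#' whose covering changes are all zero gets p = 1.
#'
#' @inheritParams mean_effect_map
#' @return `image_volume` of p-values (NaN outside the kept mask).
#' @export
voxelwise_signed_rank <- function(vtas, changes, kept_mask) {
  nvox <- prod(dim(kept_mask$data))
  kv <- which(as.vector(kept_mask$data))
  out <- rep(NaN, nvox)
  if (length(kv)) {
    cov <- matrix(FALSE, length(vtas), length(kv))
    g <- logical(nvox)
    for (i in seq_along(vtas)) {
      g[vtas[[i]]] <- TRUE
      cov[i, ] <- g[kv]
      g[vtas[[i]]] <- FALSE
    }
    grp <- pattern_groups(cov)
    for (members in split(seq_along(kv), grp))
      out[kv[members]] <- signed_rank_test(changes[cov[, members[1]]])$p_value
  }
  image_volume(array(out, dim(kept_mask$data)), kept_mask$affine,
               kept_mask$space)
}

#' Benjamini-Hochberg FDR correction of a p-map
#'
#' Step-up q-values computed over the kept (non-NaN) voxels only.
#'
#' @param p_map `image_volume` of p-values (NaN outside the kept mask).
#' @return `image_volume` of q-values.
#' @export
fdr_correct <- function(p_map) {
  p <- as.vector(p_map$data)
  kv <- which(!is.nan(p))
  q <- rep(NaN, length(p))
  q[kv] <- stats::p.adjust(p[kv], method = "BH")
  image_volume(array(q, dim(p_map$data)), p_map$affine, p_map$space)
}

#' Classify voxels as sweet, sour or non-significant
#'
#' sweet (+1): q <= alpha and mean change > 0; sour (-1): q <= alpha and
#' mean change < 0; otherwise 0; NaN outside the kept mask.
#'
#' @param mean_effect,q_map Aligned `image_volume`s.
#' @param alpha FDR level; default 0.05.
#' @return `image_volume` of labels.
#' @export
classify_sweet_sour <- function(mean_effect, q_map, alpha = 0.05) {
  m <- as.vector(mean_effect$data); q <- as.vector(q_map$data)
  lab <- rep(NaN, length(m))
  keep <- !is.nan(q)
  lab[keep] <- 0
  lab[keep & q <= alpha & m > 0] <- 1
  lab[keep & q <= alpha & m < 0] <- -1
  image_volume(array(lab, dim(mean_effect$data)), mean_effect$affine,
               mean_effect$space)
}

#' Build the full set of sweet-spot maps for a cohort
#'
#' Runs the whole voxel-wise pipeline: N-image, coverage filter, mean
#' effect map, signed-rank p-map, BH q-map and sweet/sour labels.
#'
#' @param cohort A `dbs_cohort`.
#' @param outcome Scale name (e.g. `"HAMA"`).
#' @param coverage_fraction Coverage threshold fraction; default 0.2.
#' @param alpha FDR level; default 0.05.
#' @param measure `"change"` (default) or `"improvement"`.
#' @param hemisphere `"both"`, `"left"` or `"right"` (which VTAs make up
#'   a patient's mask).
#' @param vtas Optional precomputed [patient_vta_voxels()] result.
#' @return A `sweetspot_maps` list of `image_volume`s (`n_image`,
#'   `kept`, `mean_effect`, `p_map`, `q_map`, `label_map`) plus
#'   parameters and voxel counts.
#' @export
build_sweetspot_maps <- function(cohort, outcome = "HAMA",
                                 coverage_fraction = 0.2, alpha = 0.05,
                                 measure = "change", hemisphere = "both",
                                 vtas = NULL) {
  grid <- cohort$atlas$volume
  if (is.null(vtas)) vtas <- patient_vta_voxels(cohort, hemisphere)
  changes <- clinical_outcome(cohort$clinical, outcome, measure)
  changes <- changes[names(vtas)]
  fit <- sweetspot_fit(vtas, changes, prod(dim(grid$data)),
                       coverage_fraction, alpha)
  expand <- function(vals, fill = NaN) {
    out <- rep(fill, prod(dim(grid$data)))
    out[fit$kept] <- vals
    image_volume(array(out, dim(grid$data)), grid$affine, grid$space)
  }
  structure(list(
    n_image = image_volume(array(fit$counts, dim(grid$data)), grid$affine,
                           grid$space),
    kept = expand(TRUE, FALSE),
    mean_effect = expand(fit$mean),
    p_map = expand(fit$p),
    q_map = expand(fit$q),
    label_map = expand(fit$label),
    n_sweet = sum(fit$label == 1), n_sour = sum(fit$label == -1),
    n_kept = length(fit$kept), outcome = outcome, alpha = alpha,
    coverage_fraction = coverage_fraction, fit = fit),
    class = "sweetspot_maps")
}

#' @export
print.sweetspot_maps <- function(x, ...) {
  cat(sprintf("<sweetspot_maps> outcome %s: %d kept voxels, %d sweet, %d sour (alpha = %g)\n",
              x$outcome, x$n_kept, x$n_sweet, x$n_sour, x$alpha))
  invisible(x)
}

#' Predict a held-out patient's outcome from a trained map
#'
#' Mean of the trained mean-effect map over the VTA's intersection with
#' significant (sweet or sour) voxels; falls back to the mean over the
#' VTA's intersection with all kept voxels when no significant voxel is
#' covered, and to 0 (flagged) when the VTA misses the kept mask
#' entirely.
#'
#' @param fit A trained fit (the `fit` element of
#'   [build_sweetspot_maps()] output, or `sweetspot_fit` result).
#' @param vta_voxels Linear voxel indices of the held-out patient's VTA.
#' @return List with `prediction` and `flag`.
#' @export
predict_from_map <- function(fit, vta_voxels) {
  if (!is.null(fit$fit)) fit <- fit$fit
  pos <- match(vta_voxels, fit$kept)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0)
    return(list(prediction = 0, flag = "outside_kept_mask"))
  sig <- pos[fit$label[pos] != 0]
  if (length(sig))
    return(list(prediction = mean(fit$mean[sig]), flag = "ok"))
  list(prediction = mean(fit$mean[pos]), flag = "no_significant_overlap")
}

#' Cross-validated sweet-spot outcome prediction
#'
#' Per fold, the maps (including the coverage filter, recomputed on the
#' training N) are rebuilt from the training patients only and each
#' held-out patient is predicted with [predict_from_map()]. The
#' per-patient VTAs are geometric objects independent of outcomes, so
#' they are computed once and shared across folds.
#'
#' Predictions are expressed relative to each fold's training-set mean
#' change. The raw map prediction contains the training grand mean as an
#' additive component; in leave-one-out folds that component shifts by
#' `-x_i / (n - 1)` with the held-out observation, which by itself
#' induces a spurious negative predicted-observed correlation under the
#' null. Centering by the training mean removes that artifact and leaves
#' genuine spatial signal untouched (patients whose VTA misses the kept
#' mask predict 0, i.e. "no deviation from the training mean").
#'
#' @inheritParams crossvalidate_fibers
#' @param coverage_fraction,alpha Map-building parameters.
#' @param hemisphere VTA laterality config.
#' @return A `cv_result`.
#' @export
crossvalidate_sweetspot <- function(cohort, outcome = "HAMA",
                                    scheme = c("loocv", "kfold"), k = 10,
                                    seed = 1, coverage_fraction = 0.2,
                                    alpha = 0.05, measure = "change",
                                    hemisphere = "both",
                                    cor_method = "pearson", vtas = NULL) {
  scheme <- match.arg(scheme)
  grid <- cohort$atlas$volume
  if (is.null(vtas)) vtas <- patient_vta_voxels(cohort, hemisphere)
  changes <- clinical_outcome(cohort$clinical, outcome, measure)
  changes <- changes[names(vtas)]
  n <- length(vtas)
  if (n < 8) stop("need at least 8 patients for cross-validation")
  nvox <- prod(dim(grid$data))
  folds <- make_folds(n, scheme, k, seed)
  pred <- numeric(n); flags <- character(n)
  for (f in unique(folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- sweetspot_fit(vtas[train], changes[train], nvox,
                         coverage_fraction, alpha)
    train_mean <- mean(changes[train])
    for (i in test) {
      pr <- predict_from_map(fit, vtas[[i]])
      pred[i] <- if (pr$flag == "outside_kept_mask") 0 else
        pr$prediction - train_mean
      flags[i] <- pr$flag
    }
  }
  cv_result(pred, changes, folds, scheme, k, seed, cor_method)
}
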