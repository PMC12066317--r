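#' 3-D image volume with a voxel-to-world affine
#'
#' Lightweight container for every gridded quantity in the pipeline:
#' label atlases, VTA masks, N-images, mean-effect/p/q/label maps.
#' The affine maps 0-based voxel indices to world coordinates in
#' RAS millimetres (x: left->right, y: posterior->anterior,
#' z: ventral->dorsal, so "more ventral" means smaller z).
#' Masks and overlaps are defined on voxel centers.
#'
#' @param data 3-D numeric (or logical/integer) array.
#' @param affine 4x4 invertible matrix mapping `c(i, j, k, 1)` (0-based)
#'   to world mm.
#' @param space free-text tag for the world frame, e.g. `"MNI-like"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, affine, space = "MNI-like") {
  if (length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), "-D data")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("affine is not invertible")
  structure(list(data = data, affine = affine, space = space),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], x$space))
  invisible(x)
}

#' Voxel edge lengths in mm
#' @param vol An `image_volume`.
#' @return Numeric length-3 vector of voxel sizes.
#' @export
voxel_size <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Volume of one voxel in cubic mm
#' @param vol An `image_volume`.
#' @export
voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Map 0-based voxel indices to world mm
#'
#' @param vol An `image_volume`.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind_coords(ijk)
  xyz <- cbind(ijk, 1) %*% t(vol$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Map world mm to (fractional, 0-based) voxel indices
#' @param vol An `image_volume`.
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind_coords(xyz)
  ijk <- cbind(xyz, 1) %*% t(solve(vol$affine))
  ijk[, 1:3, drop = FALSE]
}

rbind_coords <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' World coordinates of every voxel center
#'
#' @param vol An `image_volume`.
#' @return A `prod(dim)` x 3 matrix, rows ordered like the flattened array
#'   (first index fastest, matching R's linear indexing).
#' @export
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(vol, ijk)
}

#' Convert world points to linear (1-based) voxel indices
#'
#' Points are assigned to the voxel whose center is nearest (rounding of
#' the fractional index). Points falling outside the grid get NA.
#'
#' @param vol An `image_volume`.
#' @param xyz n x 3 matrix of world mm points.
#' @return Integer vector of linear indices into `vol$data` (NA outside).
#' @export
world_to_linear_index <- function(vol, xyz) {
  d <- dim(vol$data)
  ijk <- round(world_to_voxel(vol, xyz))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
        ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
  idx <- rep(NA_integer_, nrow(ijk))
  idx[ok] <- as.integer(1 + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3]))
  idx
}

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param space Space tag to attach.
#' @return An `image_volume`.
#' @export
read_image <- function(path, space = "MNI-like") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  dat <- as.array(img)
  if (length(dim(dat)) != 3L)
    stop("expected 3-D volume in ", path, ", got ", length(dim(dat)), "-D")
  dat <- array(as.vector(dat), dim(dat)) # drop RNifti header attributes
  image_volume(dat, aff, space = space)
}

#' Write a NIfTI volume
#'
#' Data are stored as float32 (or int16 when `datatype = "int16"`),
#' so round-trips preserve values to single precision.
#'
#' @param vol An `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype, `"float"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(vol, path, datatype = "float") {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- voxel_size(vol)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Label atlas: an integer image volume plus a legend
#'
#' @param volume `image_volume` of integer labels (0 = background).
#' @param legend Named integer vector mapping region names to label values.
#' @param region_groups Optional named list of label vectors for composite
#'   regions (e.g. a whole nucleus as the union of its sublabels).
#' @param geometry Optional list of generator geometry (used by the
#'   synthetic cohort module for electrode placement).
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(volume, legend, region_groups = list(), geometry = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  labs <- sort(unique(as.vector(volume$data)))
  labs <- labs[labs != 0]
  unknown <- setdiff(labs, unname(legend))
  if (length(unknown))
    stop("atlas labels not in legend: ", paste(unknown, collapse = ", "))
  structure(list(volume = volume, legend = legend,
                 region_groups = region_groups, geometry = geometry),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("<label_atlas> regions:", paste(names(x$legend), collapse = ", "), "\n")
  invisible(x)
}

#' Linear voxel indices of one atlas region
#'
#' @param atlas A `label_atlas`.
#' @param region Region name (legend entry or region-group name).
#' @return Integer vector of linear indices into the atlas array.
#' @export
region_voxels <- function(atlas, region) {
  if (region %in% names(atlas$region_groups)) {
    labs <- atlas$region_groups[[region]]
  } else if (region %in% names(atlas$legend)) {
    labs <- atlas$legend[[region]]
  } else stop("unknown region: ", region)
  which(array(atlas$volume$data %in% labs, dim(atlas$volume$data)))
}
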