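#' Tractogram: a list of streamline polylines in world mm
#'
#' @param streamlines List of n x 3 numeric matrices, each with >= 2 rows
#'   of finite world-mm coordinates.
#' @return An object of class `tractogram` with fields `streamlines` and
#'   `count`.
#' @export
tractogram <- function(streamlines) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L) stop("streamline points must be 3-D")
    if (nrow(s) < 2L) stop("streamline with fewer than 2 points")
    if (!all(is.finite(s))) stop("streamline contains non-finite points")
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, count = length(streamlines)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- if (x$count) range(vapply(x$streamlines, nrow, 1L)) else c(0L, 0L)
  cat(sprintf("<tractogram> %d streamlines, %d-%d points each\n",
              x$count, np[1], np[2]))
  invisible(x)
}

#' Read a tractogram (TCK or TRK)
#'
#' TCK (MRtrix) streamlines are stored directly in world mm. TRK
#' (TrackVis) streamlines are stored in corner-anchored voxel-mm and are
#' converted to world mm with the header's `vox_to_ras` matrix on read,
#' so both formats yield the same RAS-mm frame.
#'
#' @param path Path to a `.tck` or `.trk` file.
#' @return A `tractogram`.
#' @export
read_tractogram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tck", "trk"))
    stop("unknown tractogram extension: .", ext)
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext == "tck") read_tck(path) else read_trk(path)
}

#' Write a tractogram (TCK or TRK)
#'
#' @param t A `tractogram`.
#' @param path Output path; format chosen by extension (`.tck`/`.trk`).
#' @param reference Optional `image_volume` supplying the voxel grid for
#'   TRK headers; a 1 mm identity grid is used when absent.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, reference = NULL) {
  stopifnot(inherits(t, "tractogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = write_tck(t, path),
         trk = write_trk(t, path, reference),
         stop("unknown tractogram extension: .", ext))
  invisible(path)
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(magic, "mrtrix tracks"))
    stop("corrupt TCK header (missing magic line) in ", path)
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("corrupt TCK header (no END) in ", path)
    if (identical(line, "END")) break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) {
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "file") offset <- as.integer(sub("^\\.\\s*", "", val))
      if (key == "datatype") datatype <- val
    }
  }
  if (is.na(offset)) stop("corrupt TCK header (no file offset) in ", path)
  if (datatype != "Float32LE")
    stop("unsupported TCK datatype: ", datatype)
  seek(con, where = offset, origin = "start")
  nbytes <- file.info(path)$size - offset
  raw <- readBin(con, "numeric", n = nbytes / 4L, size = 4L, endian = "little")
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  sep <- is.nan(pts[, 1]) | is.infinite(pts[, 1])
  grp <- cumsum(sep) - as.integer(sep) # group id per row, separators excluded
  keep <- !sep
  if (!any(keep)) return(tractogram(list()))
  sl <- split.data.frame(pts[keep, , drop = FALSE], grp[keep])
  tractogram(unname(lapply(sl, as.matrix)))
}

write_tck <- function(t, path) {
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", t$count),
           "timestamp: 0")
  # the 'file' line states its own byte offset; iterate once to settle it
  make_hdr <- function(off) paste0(c(hdr, sprintf("file: . %d", off), "END"),
                                   "\n", collapse = "")
  off <- nchar(make_hdr(0), type = "bytes")
  off <- nchar(make_hdr(off), type = "bytes") # width may grow by a digit
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(make_hdr(off), con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
}

trk_rasmm_affine <- function(vox_to_ras, voxel_size) {
  # TRK point p (voxel-mm, corner-anchored): ijk = p / voxel_size - 0.5
  shift <- diag(4); shift[1:3, 4] <- -0.5
  vox_to_ras %*% shift %*% diag(c(1 / voxel_size, 1))
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6L)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("corrupt TRK header (bad magic) in ", path)
  readBin(con, "integer", n = 3L, size = 2L, endian = "little") # dim
  voxel_size <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little") # origin
  n_scalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  readBin(con, "raw", n = 200L)
  n_props <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  readBin(con, "raw", n = 200L)
  vox_to_ras <- matrix(readBin(con, "numeric", n = 16L, size = 4L,
                               endian = "little"), 4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("corrupt TRK header (hdr_size != 1000) in ", path)
  if (version >= 2L && any(vox_to_ras[4, ] != c(0, 0, 0, 1)))
    stop("corrupt TRK header (bad vox_to_ras) in ", path)
  if (all(vox_to_ras == 0)) { # legacy file: assume scaled identity
    vox_to_ras <- diag(c(voxel_size, 1))
  }
  aff <- trk_rasmm_affine(vox_to_ras, voxel_size)
  sl <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!length(np)) break
    vals <- readBin(con, "numeric", n = np * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0)
      readBin(con, "numeric", n = n_props, size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    xyz <- cbind(m, 1) %*% t(aff)
    i <- i + 1L
    sl[[i]] <- xyz[, 1:3, drop = FALSE]
  }
  tractogram(sl[seq_len(i)])
}

write_trk <- function(t, path, reference = NULL) {
  if (is.null(reference)) {
    vox_to_ras <- diag(4)
    voxel_size <- c(1, 1, 1)
    dims <- c(1L, 1L, 1L)
  } else {
    vox_to_ras <- reference$affine
    voxel_size <- voxel_size(reference)
    dims <- dim(reference$data)
  }
  aff <- trk_rasmm_affine(vox_to_ras, voxel_size)
  inv <- solve(aff)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little") # origin
  writeBin(0L, con, size = 2L, endian = "little")         # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")         # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(vox_to_ras)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                  # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  writeBin(raw(2L + 6L), con)                             # pad1 + invert flags
  writeBin(as.integer(t$count), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")         # version
  writeBin(1000L, con, size = 4L, endian = "little")      # hdr_size
  for (s in t$streamlines) {
    p <- cbind(s, 1) %*% t(inv)
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.vector(t(p[, 1:3, drop = FALSE])), con, size = 4L,
             endian = "little")
  }
}
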