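# Minimal NIfTI-1 reader/writer. Implemented in base R because no NIfTI
# package ships with the target environment. Supports .nii and .nii.gz,
# scalar 3D images, the common datatypes, scl slope/intercept scaling, and
# sform/qform affines. Written files always carry an sform equal to the
# canonical diagonal affine (spacing on the diagonal, origin in the last
# column).

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = 512 * 1024^2)
  if (length(raw) < 352) stop("not a NIfTI-1 file (too short): ", path)
  rc <- rawConnection(raw, "rb")
  on.exit(close(rc), add = TRUE)
  endian <- .Platform$endian
  sizeof_hdr <- readBin(rc, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- if (endian == "little") "big" else "little"
    seek(rc, 0)
    sizeof_hdr <- readBin(rc, "integer", 1, size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad header size): ", path)
  }
  seek(rc, 40)
  dims <- readBin(rc, "integer", 8, size = 2, endian = endian)
  seek(rc, 70)
  datatype <- readBin(rc, "integer", 1, size = 2, endian = endian)
  seek(rc, 76)
  pixdim <- readBin(rc, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(rc, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(rc, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(rc, "double", 1, size = 4, endian = endian)
  seek(rc, 252)
  qform_code <- readBin(rc, "integer", 1, size = 2, endian = endian)
  sform_code <- readBin(rc, "integer", 1, size = 2, endian = endian)
  quatern <- readBin(rc, "double", 3, size = 4, endian = endian)
  qoffset <- readBin(rc, "double", 3, size = 4, endian = endian)
  srow <- matrix(readBin(rc, "double", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  seek(rc, 344)
  magic <- readBin(rc, "raw", 4)
  if (!rawToChar(magic[1:3]) %in% c("n+1", "ni1")) {
    stop("not a NIfTI-1 file (bad magic): ", path)
  }

  ndim <- dims[1]
  shape <- dims[2:(ndim + 1)]
  if (ndim > 3 && any(shape[4:ndim] > 1)) {
    stop("only 3D scalar images are supported (file is ", ndim, "D): ", path)
  }
  shape3 <- c(shape, 1L, 1L)[1:3]
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)

  n <- prod(shape3)
  seek(rc, as.integer(round(vox_offset)))
  if (dt$what == "integer" && !dt$signed) {
    bytes <- readBin(rc, "raw", n * dt$size)
    if (dt$size == 1L) {
      data <- as.numeric(as.integer(bytes))
    } else {
      u <- readBin(bytes, "integer", n, size = dt$size, signed = FALSE,
                   endian = endian)
      data <- as.numeric(u)
    }
  } else {
    data <- readBin(rc, dt$what, n, size = dt$size, endian = endian)
    data <- as.numeric(data)
  }
  if (length(data) < n) stop("truncated NIfTI data: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }

  affine <- nifti_affine(sform_code, srow, qform_code, quatern, qoffset, pixdim)
  list(values = array(data, shape3), affine = affine, datatype = datatype)
}

nifti_affine <- function(sform_code, srow, qform_code, quatern, qoffset, pixdim) {
  if (sform_code > 0) {
    return(rbind(srow, c(0, 0, 0, 1)))
  }
  sp <- pixdim[2:4]
  sp[sp == 0] <- 1
  if (qform_code > 0) {
    b <- quatern[1]; c_ <- quatern[2]; d <- quatern[3]
    a2 <- max(0, 1 - b^2 - c_^2 - d^2)
    a <- sqrt(a2)
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), nrow = 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    M <- R %*% diag(c(sp[1], sp[2], qfac * sp[3]))
    return(rbind(cbind(M, qoffset), c(0, 0, 0, 1)))
  }
  rbind(cbind(diag(sp), c(0, 0, 0)), c(0, 0, 0, 1))
}

# Reorient a raw (values, affine) pair to the canonical R/A/S axis order.
# Requires a near-axis-aligned affine; oblique acquisitions are rejected.
canonicalize_nifti <- function(values, affine, tol = 1e-3) {
  M <- affine[1:3, 1:3]
  scale <- sqrt(colSums(M^2))
  if (any(scale <= 0)) stop("degenerate affine (zero-length axis)")
  perm <- integer(3)
  sign <- numeric(3)
  for (j in 1:3) {
    w <- which.max(abs(M[, j]))
    if (abs(M[w, j]) / scale[j] < 1 - tol) {
      stop("oblique volumes are not supported (grid axes must align with ",
           "anatomical axes)")
    }
    perm[j] <- w
    sign[j] <- sign(M[w, j])
  }
  if (anyDuplicated(perm)) stop("invalid affine: axes are not independent")

  ord <- match(1:3, perm)           # source grid axis feeding canonical axis a
  values <- aperm(values, ord)
  scale <- scale[ord]
  sign <- sign[ord]
  d <- dim(values)
  idx0 <- c(0, 0, 0)                # source index of new voxel (0,0,0), per new axis
  for (a in 1:3) {
    if (sign[a] < 0) {
      values <- switch(a,
                       values[d[1]:1, , , drop = FALSE],
                       values[, d[2]:1, , drop = FALSE],
                       values[, , d[3]:1, drop = FALSE])
      idx0[a] <- d[a] - 1
    }
  }
  src_idx <- numeric(3)
  src_idx[ord] <- idx0              # back to source axis order
  origin <- (affine %*% c(src_idx, 1))[1:3]
  list(values = values, spacing = scale, origin = as.numeric(origin))
}

#' Read a CT volume or label map from NIfTI
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`), reorients the grid to the
#' canonical R/A/S axis order, and returns the corresponding container.
#' `read_labelmap()` additionally checks that the voxel values are binary.
#'
#' @param path path to a NIfTI-1 file with a 3D scalar image.
#' @return An [oto_volume()] (HU values) or [oto_labelmap()].
#' @export
read_volume <- function(path) {
  raw <- read_nifti_raw(path)
  if (!all(is.finite(raw$values))) {
    stop("volume contains ", sum(!is.finite(raw$values)),
         " non-finite voxel(s): ", path)
  }
  can <- canonicalize_nifti(raw$values, raw$affine)
  oto_volume(can$values, spacing = can$spacing, origin = can$origin)
}

#' @rdname read_volume
#' @export
read_labelmap <- function(path) {
  raw <- read_nifti_raw(path)
  can <- canonicalize_nifti(raw$values, raw$affine)
  m <- round(can$values)
  if (!all(m %in% c(0, 1))) stop("label map file has non-binary values: ", path)
  oto_labelmap(m, spacing = can$spacing, origin = can$origin)
}

#' Write a CT volume or label map to NIfTI
#'
#' Volumes are written as float64 so that HU values round-trip exactly to
#' reading tolerance; label maps are written as uint8 with values \{0, 1\}.
#' The affine encodes spacing and origin on the canonical axes. A `.gz`
#' suffix triggers gzip compression.
#'
#' @param x an [oto_volume()] or [oto_labelmap()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_label <- inherits(x, "oto_labelmap")
  vals <- grid_values(x)
  d <- dim(vals)
  datatype <- if (is_label) 2L else 64L
  bitpix <- if (is_label) 8L else 64L

  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  con <- tryCatch(
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb"),
    error = function(e) stop("cannot open for writing: ", path),
    warning = function(w) stop("cannot open for writing: ", path)
  )
  on.exit(close(con))

  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                                   # sizeof_hdr
  wraw(35)                                      # data_type..regular
  wi(0L, 1)                                     # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(c(0L, datatype, bitpix, 0L), 2)            # intent_code, datatype, bitpix, slice_start
  wf(c(1, x$spacing, 1, 1, 1, 1))               # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2)                                     # slice_end
  wi(c(0L, 2L), 1)                              # slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wraw(80 + 24)                                 # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0))                                # quatern b, c, d
  wf(c(0, 0, 0))                                # qoffset
  wf(c(x$spacing[1], 0, 0, x$origin[1]))        # srow_x
  wf(c(0, x$spacing[2], 0, x$origin[2]))        # srow_y
  wf(c(0, 0, x$spacing[3], x$origin[3]))        # srow_z
  wraw(16)                                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  wraw(4)                                      # extension flag
  if (is_label) {
    writeBin(as.raw(as.integer(vals)), con)
  } else {
    writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  }
  invisible(path)
}
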