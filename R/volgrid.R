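#' Core grid containers
#'
#' CT data live on regular 3D grids in a canonical anatomical frame:
#' axis 1 runs left to right (R), axis 2 posterior to anterior (A), axis 3
#' inferior to superior (S). A voxel's world position is its center:
#' `world = origin + index * spacing` with 0-based indices, spacing in mm.
#'
#' `oto_volume()` wraps a Hounsfield-unit (or unitless, after windowing)
#' scalar grid; `oto_labelmap()` wraps a binary mask on the same kind of
#' grid; `grid_spec()` describes a target grid for resampling.
#'
#' @param values 3D numeric array of voxel values (HU for raw CT).
#' @param mask 3D array with values in \{0, 1\}.
#' @param spacing numeric length-3, voxel size in mm per axis (> 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param orientation character length-3 axis labels; the canonical frame
#'   is `c("R", "A", "S")` and the first axis must be the left-right axis.
#' @return An object of class `oto_volume` / `oto_labelmap`.
#' @examples
#' v <- oto_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' dim(v$values)
#' @export
oto_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = c("R", "A", "S")) {
  values <- as_grid_array(values)
  check_grid_meta(spacing, origin, orientation)
  if (!all(is.finite(values))) {
    stop("volume contains ", sum(!is.finite(values)), " non-finite voxel(s)")
  }
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), orientation = orientation),
    class = "oto_volume"
  )
}

#' @rdname oto_volume
#' @export
oto_labelmap <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = c("R", "A", "S")) {
  mask <- as_grid_array(mask)
  check_grid_meta(spacing, origin, orientation)
  storage.mode(mask) <- "integer"
  if (!all(mask == 0L | mask == 1L)) {
    stop("label map values must be 0 or 1")
  }
  structure(
    list(mask = mask, spacing = as.numeric(spacing),
         origin = as.numeric(origin), orientation = orientation),
    class = "oto_labelmap"
  )
}

#' @param shape integer length-3, voxels per axis (>= 1).
#' @rdname oto_volume
#' @export
grid_spec <- function(shape, spacing) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("grid shape must be 3 components >= 1")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid spacing must be 3 positive components")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing)),
            class = "oto_gridspec")
}

as_grid_array <- function(x) {
  if (is.null(dim(x))) stop("grid values must be a 3D array")
  if (length(dim(x)) != 3L) stop("grid values must be a 3D array")
  if (any(dim(x) < 1L)) stop("grid must have >= 1 voxel per axis")
  x
}

check_grid_meta <- function(spacing, origin, orientation) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite components (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be 3 finite components (mm)")
  }
  if (length(orientation) != 3L || orientation[1] != "R") {
    stop("orientation must label 3 axes with the left-right axis first ",
         "(canonical frame is R, A, S)")
  }
  invisible(TRUE)
}

grid_shape <- function(x) {
  dim(if (inherits(x, "oto_labelmap")) x$mask else x$values)
}

grid_values <- function(x) {
  if (inherits(x, "oto_labelmap")) x$mask else x$values
}

set_grid_values <- function(x, values) {
  if (inherits(x, "oto_labelmap")) {
    x$mask <- values
    storage.mode(x$mask) <- "integer"
  } else {
    x$values <- values
  }
  x
}

#' Do two grid objects share shape, spacing, origin and orientation?
#' @param a,b `oto_volume` or `oto_labelmap` objects.
#' @param tol numeric tolerance on spacing/origin (mm).
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_shape(a), grid_shape(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol) &&
    identical(a$orientation, b$orientation)
}

stop_unless_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(what, " must share the same grid")
  invisible(TRUE)
}

#' @export
print.oto_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<oto_volume> %d x %d x %d, spacing %s mm, origin (%s), [%s]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", "),
              paste(x$orientation, collapse = "")))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.oto_labelmap <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<oto_labelmap> %d x %d x %d, spacing %s mm, %d foreground voxel(s)\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              sum(x$mask)))
  invisible(x)
}

#' Resample a volume or label map onto a target grid
#'
#' The target grid shares the input's origin; values are interpolated at the
#' target voxel centers. `continuous` mode interpolates trilinearly (for HU
#' volumes), `nearest` picks the nearest input voxel and is mandatory for
#' label maps so masks stay binary. Target voxel centers outside the input
#' field of view are filled with air (-1000 HU) for volumes and 0 for masks.
#'
#' @param x an `oto_volume` or `oto_labelmap`.
#' @param target a [grid_spec()].
#' @param mode `"continuous"` or `"nearest"`; label maps force `"nearest"`.
#' @return An object of the same class as `x` on the target grid.
#' @examples
#' v <- oto_volume(array(100, c(8, 8, 8)), spacing = c(1, 1, 1))
#' r <- resample(v, grid_spec(c(4, 4, 4), c(2, 2, 2)))
#' unique(as.vector(r$values))
#' @export
resample <- function(x, target, mode = c("continuous", "nearest")) {
  if (!inherits(target, "oto_gridspec")) stop("target must be a grid_spec")
  is_label <- inherits(x, "oto_labelmap")
  mode <- match.arg(mode)
  if (is_label) mode <- "nearest"
  vals <- grid_values(x)
  fill <- if (is_label) 0 else -1000
  out <- cpp_resample(as.numeric(vals), dim(vals), x$spacing, x$origin,
                      target$shape, target$spacing, x$origin,
                      mode == "nearest", fill)
  out <- array(out, target$shape)
  if (is_label) {
    oto_labelmap(out, spacing = target$spacing, origin = x$origin,
                 orientation = x$orientation)
  } else {
    oto_volume(out, spacing = target$spacing, origin = x$origin,
               orientation = x$orientation)
  }
}

# Target grid covering x's field of view at the given isotropic spacing.
iso_grid_spec <- function(x, spacing_mm) {
  if (!is.finite(spacing_mm) || spacing_mm <= 0) {
    stop("working spacing must be positive")
  }
  shape <- pmax(1L, as.integer(ceiling(grid_shape(x) * x$spacing / spacing_mm)))
  grid_spec(shape, rep(spacing_mm, 3))
}

#' Mirror a grid object across the left-right axis
#'
#' Reverses the grid along the canonical left-right axis (axis 1), turning a
#' left-sided dataset into its right-sided mirror image. Applying it twice
#' is the identity.
#'
#' @param x an `oto_volume` or `oto_labelmap` with canonical orientation.
#' @return The mirrored object, same class and grid metadata.
#' @export
flip_lr <- function(x) {
  if (is.null(x$orientation) || x$orientation[1] != "R") {
    stop("flip_lr requires canonical orientation metadata (left-right axis first)")
  }
  vals <- grid_values(x)
  d <- dim(vals)
  set_grid_values(x, vals[d[1]:1, , , drop = FALSE])
}
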