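#' Dice similarity coefficient
#'
#' `2 |A∩B| / (|A| + |B|)` between two binary masks on a shared grid. By
#' convention two empty masks score 1 and exactly one empty mask scores 0.
#'
#' @param a,b [oto_labelmap()] objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_unless_same_grid(a, b, "masks")
  dice_counts(sum(a$mask == 1L & b$mask == 1L), sum(a$mask), sum(b$mask))
}

dice_counts <- function(n_both, n_a, n_b) {
  if (n_a + n_b == 0) return(1)
  2 * n_both / (n_a + n_b)
}

# World-mm coordinates (rows) of the boundary voxels of a mask: mask voxels
# with at least one face neighbor outside the mask (grid border counts as
# outside).
boundary_coords <- function(label) {
  d <- grid_shape(label)
  b <- cpp_boundary(as.integer(label$mask), d)
  idx <- which(b == 1L) - 1L
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  cbind(label$origin[1] + i * label$spacing[1],
        label$origin[2] + j * label$spacing[2],
        label$origin[3] + k * label$spacing[3])
}

#' Average Hausdorff distance (mm)
#'
#' Symmetric average of the two directed mean nearest-neighbor surface
#' distances between the boundary voxels of two masks:
#' `AHD = (mean_a min_b d(a,b) + mean_b min_a d(a,b)) / 2`, with Euclidean
#' distances between voxel centers in world mm (spacing-aware). Boundary
#' voxels are mask voxels with a face neighbor outside the mask; using
#' surfaces rather than full volumes makes the metric the mean contour
#' error, the clinically meaningful quantity.
#'
#' @param a,b non-empty [oto_labelmap()] objects on the same grid.
#' @return Distance in mm (>= 0).
#' @export
average_hausdorff <- function(a, b) {
  stop_unless_same_grid(a, b, "masks")
  if (sum(a$mask) == 0L || sum(b$mask) == 0L) {
    stop("average_hausdorff is undefined for empty masks")
  }
  pa <- boundary_coords(a)
  pb <- boundary_coords(b)
  dab <- cpp_min_dists(pa, pb)
  dba <- cpp_min_dists(pb, pa)
  (mean(dab) + mean(dba)) / 2
}

#' Volumetric similarity (%)
#'
#' `100 * volume(pred) / volume(ref)` using voxel volumes, so masks on
#' grids with different spacing compare correctly. Values above 100
#' indicate over-segmentation.
#'
#' @param pred predicted [oto_labelmap()].
#' @param ref reference [oto_labelmap()]; must be non-empty.
#' @return Percentage (> 0).
#' @export
volumetric_similarity <- function(pred, ref) {
  if (sum(ref$mask) == 0L) {
    stop("volumetric_similarity is undefined for an empty reference")
  }
  100 * (sum(pred$mask) * prod(pred$spacing)) /
    (sum(ref$mask) * prod(ref$spacing))
}

#' Evaluate one prediction/reference pair
#'
#' Bundles Dice, average Hausdorff distance and volumetric similarity with
#' the wall time of the prediction. Degenerate cases do not error: an empty
#' prediction against a non-empty reference yields Dice 0 with AHD and
#' volumetric similarity reported as `NA` (undefined).
#'
#' @param pred predicted [oto_labelmap()].
#' @param ref reference [oto_labelmap()] on the same grid.
#' @param seconds wall time of the prediction (s), `NA` if not measured.
#' @return An object of class `oto_metrics`: list with `dsc`, `ahd_mm`,
#'   `volsim_pct`, `seconds`.
#' @export
evaluate_pair <- function(pred, ref, seconds = NA_real_) {
  stop_unless_same_grid(pred, ref, "pred and ref")
  d <- dice(pred, ref)
  ahd <- if (sum(pred$mask) > 0L && sum(ref$mask) > 0L) {
    average_hausdorff(pred, ref)
  } else {
    NA_real_
  }
  vs <- if (sum(pred$mask) > 0L && sum(ref$mask) > 0L) {
    volumetric_similarity(pred, ref)
  } else {
    NA_real_   # a 0% ratio is reported as undefined, not as a valid volume
  }
  structure(list(dsc = d, ahd_mm = ahd, volsim_pct = vs, seconds = seconds),
            class = "oto_metrics")
}

#' @export
as.data.frame.oto_metrics <- function(x, ...) {
  data.frame(dsc = x$dsc, ahd_mm = x$ahd_mm, volsim_pct = x$volsim_pct,
             seconds = x$seconds)
}

#' @export
print.oto_metrics <- function(x, ...) {
  cat(sprintf("<oto_metrics> DSC %.4f | AHD %s mm | volume %s%% | %.2f s\n",
              x$dsc,
              if (is.na(x$ahd_mm)) "undefined" else sprintf("%.4f", x$ahd_mm),
              if (is.na(x$volsim_pct)) "undefined" else sprintf("%.1f", x$volsim_pct),
              if (is.na(x$seconds)) NA else x$seconds))
  invisible(x)
}

#' Aggregate a list of metric reports as mean (SD)
#'
#' SD uses the sample (n-1) convention, matching the usual mean (SD)
#' presentation of segmentation benchmarks.
#'
#' @param reports list of `oto_metrics` objects.
#' @return data.frame with one row per metric: mean, sd, n (non-NA count).
#' @export
aggregate_reports <- function(reports) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  metrics <- c("dsc", "ahd_mm", "volsim_pct", "seconds")
  out <- lapply(metrics, function(m) {
    v <- df[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)))
  })
  do.call(rbind, out)
}
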