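#' HU range and per-structure refinement policy
#'
#' `hu_range()` is an inclusive Hounsfield-unit interval.
#' `structure_spec()` bundles the refinement policy for one anatomical
#' structure: the tissue HU range its voxels must satisfy, the island
#' (small disconnected component) policy, the growth iteration cap and the
#' growth connectivity.
#'
#' Growth uses face (6-) connectivity by default so one-voxel-thin bone
#' septa are not leaked through diagonally; island analysis uses
#' all-neighbor (26-) connectivity so diagonal contact does not split a
#' structure into spurious islands. Both are configurable.
#'
#' @param lo,hi inclusive HU bounds, `lo <= hi`.
#' @param name structure token: one of `inner_ear`, `ossicles`,
#'   `facial_nerve`, `sigmoid_sinus`, `otic_capsule`.
#' @param refine_range an `hu_range`.
#' @param island_policy either `list(type = "keep_largest")` or
#'   `list(type = "min_size", min_size = n)`.
#' @param max_grow_iterations growth cap (>= 0); at 0.25 mm spacing the
#'   default 50 bounds growth to about 12.5 mm reach.
#' @param grow_connectivity `"faces"` (6) or `"all_neighbors"` (26).
#' @return An `hu_range` / `structure_spec` object.
#' @export
hu_range <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    stop("hu_range requires finite lo <= hi")
  }
  structure(list(lo = lo, hi = hi), class = "hu_range")
}

#' @rdname hu_range
#' @export
structure_spec <- function(name, refine_range,
                           island_policy = list(type = "keep_largest"),
                           max_grow_iterations = 50L,
                           grow_connectivity = c("faces", "all_neighbors")) {
  known <- c("inner_ear", "ossicles", "facial_nerve", "sigmoid_sinus",
             "otic_capsule")
  if (!name %in% known) {
    stop("unknown structure '", name, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  if (!inherits(refine_range, "hu_range")) stop("refine_range must be an hu_range")
  if (!island_policy$type %in% c("keep_largest", "min_size")) {
    stop("island_policy type must be keep_largest or min_size")
  }
  if (identical(island_policy$type, "min_size") &&
      (is.null(island_policy$min_size) || island_policy$min_size < 1)) {
    stop("min_size island policy requires min_size >= 1")
  }
  if (max_grow_iterations < 0) stop("max_grow_iterations must be >= 0")
  grow_connectivity <- match.arg(grow_connectivity)
  structure(list(name = name, refine_range = refine_range,
                 island_policy = island_policy,
                 max_grow_iterations = as.integer(max_grow_iterations),
                 grow_connectivity = grow_connectivity),
            class = "structure_spec")
}

conn_code <- function(connectivity) {
  switch(connectivity, faces = 6L, all_neighbors = 26L,
         stop("unknown connectivity: ", connectivity))
}

#' Default per-structure refinement table
#'
#' Soft-tissue range -400..550 HU for inner ear and facial nerve, bone
#' range 100..2500 HU for ossicles, compact-bone range 650..2500 HU for the
#' otic capsule. The sigmoid sinus range is not documented anywhere
#' authoritative; the soft-tissue range is used as an assumption and can be
#' overridden.
#'
#' @return Named list of [structure_spec()] objects.
#' @export
default_structure_specs <- function() {
  list(
    inner_ear     = structure_spec("inner_ear", hu_range(-400, 550)),
    facial_nerve  = structure_spec("facial_nerve", hu_range(-400, 550)),
    ossicles      = structure_spec("ossicles", hu_range(100, 2500)),
    sigmoid_sinus = structure_spec("sigmoid_sinus", hu_range(-400, 550)),
    otic_capsule  = structure_spec("otic_capsule", hu_range(650, 2500))
  )
}

#' HU-constrained margin refinement (shrink then grow)
#'
#' Maximizes a predicted segmentation's margins within the structure's
#' tissue HU range: labeled voxels whose HU falls outside the range are
#' removed (shrink), then unlabeled in-range voxels connected to the
#' current label are added iteratively (grow) until convergence or the
#' iteration cap. Every output voxel has HU inside the range. Shrinking
#' first prevents out-of-range voxels from seeding growth. Idempotent once
#' growth has converged.
#'
#' @param label an [oto_labelmap()] (e.g. a binarized prediction).
#' @param volume the paired [oto_volume()] in raw HU.
#' @param spec a [structure_spec()].
#' @return The refined [oto_labelmap()].
#' @export
hu_constrained_refine <- function(label, volume, spec) {
  stop_unless_same_grid(label, volume, "label and volume")
  rng <- spec$refine_range
  inrange <- (volume$values >= rng$lo & volume$values <= rng$hi) * 1L
  seed <- label$mask * inrange
  grown <- cpp_grow(as.integer(seed), as.integer(inrange), dim(label$mask),
                    conn_code(spec$grow_connectivity),
                    spec$max_grow_iterations)
  oto_labelmap(array(grown, dim(label$mask)), spacing = label$spacing,
               origin = label$origin, orientation = label$orientation)
}

#' Remove small disconnected islands from a mask
#'
#' Connected components are computed with all-neighbor (26) connectivity.
#' `keep_largest` retains exactly the largest component (ties broken by the
#' component containing the smallest linear voxel index); `min_size`
#' retains every component with at least `min_size` voxels.
#'
#' @param label an [oto_labelmap()].
#' @param policy `list(type = "keep_largest")` or
#'   `list(type = "min_size", min_size = n)`.
#' @return The filtered [oto_labelmap()].
#' @export
remove_islands <- function(label, policy = list(type = "keep_largest")) {
  m <- label$mask
  if (sum(m) == 0L) return(label)
  lab <- cpp_cc_label(as.integer(m), dim(m), 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- if (identical(policy$type, "keep_largest")) {
    which.max(sizes)  # first maximum = lowest component id = smallest min index
  } else if (identical(policy$type, "min_size")) {
    which(sizes >= policy$min_size)
  } else {
    stop("unknown island policy: ", policy$type)
  }
  out <- array(as.integer(lab %in% keep & lab > 0L), dim(m))
  oto_labelmap(out, spacing = label$spacing, origin = label$origin,
               orientation = label$orientation)
}

#' Full post-prediction refinement pipeline
#'
#' Resamples the CT volume (trilinear) and the predicted mask (nearest) to
#' an isotropic working grid (default 0.25 mm), applies
#' [hu_constrained_refine()] then [remove_islands()], and resamples the
#' refined mask back onto the input grid. Probability volumes are binarized
#' at 0.5 first. The whole chain is deterministic.
#'
#' Before growing, connected components smaller than `pre_island_min_size`
#' voxels (on the working grid) are discarded: scattered single-voxel false
#' positives would otherwise seed growth and be amplified into large
#' in-range regions. The structure's own island policy is applied after
#' growth as specified.
#'
#' @param prob_or_label an [oto_volume()] of probabilities or an
#'   [oto_labelmap()].
#' @param volume the paired CT [oto_volume()] in raw HU.
#' @param spec a [structure_spec()].
#' @param working_spacing isotropic working voxel size in mm.
#' @param pre_island_min_size minimum component size (voxels) kept before
#'   growth; 1 disables the pre-pass.
#' @return A refined [oto_labelmap()] on the input grid.
#' @export
refine_pipeline <- function(prob_or_label, volume, spec, working_spacing = 0.25,
                            pre_island_min_size = 10L) {
  label <- if (inherits(prob_or_label, "oto_labelmap")) {
    prob_or_label
  } else {
    binarize(prob_or_label, 0.5)
  }
  stop_unless_same_grid(label, volume, "label and volume")
  target <- iso_grid_spec(volume, working_spacing)
  vol_w <- resample(volume, target, "continuous")
  lab_w <- resample(label, target, "nearest")
  if (pre_island_min_size > 1L) {
    lab_w <- remove_islands(lab_w, list(type = "min_size",
                                        min_size = pre_island_min_size))
  }
  ref_w <- hu_constrained_refine(lab_w, vol_w, spec)
  ref_w <- remove_islands(ref_w, spec$island_policy)
  back <- grid_spec(grid_shape(label), label$spacing)
  resample(ref_w, back, "nearest")
}

#' Derive the otic capsule from a refined inner-ear label
#'
#' The otic capsule is the compact-bone shell enclosing the inner ear; it
#' is recovered by growing outward from the inner-ear margin through voxels
#' whose HU lies in the compact-bone range (default 650..2500 HU). With
#' `max_iterations = 0` only the first shell (in-range voxels adjacent to
#' the inner ear) is returned. The result is always disjoint from the
#' inner-ear label.
#'
#' @param inner_ear a refined inner-ear [oto_labelmap()].
#' @param volume the paired CT [oto_volume()] in raw HU.
#' @param range compact-bone [hu_range()].
#' @param max_iterations growth cap (>= 0).
#' @param connectivity `"faces"` or `"all_neighbors"`.
#' @return The otic-capsule [oto_labelmap()]; empty (with a warning) when
#'   `inner_ear` is empty.
#' @export
derive_otic_capsule <- function(inner_ear, volume, range = hu_range(650, 2500),
                                max_iterations = 50L,
                                connectivity = c("faces", "all_neighbors")) {
  stop_unless_same_grid(inner_ear, volume, "inner_ear and volume")
  connectivity <- match.arg(connectivity)
  empty <- oto_labelmap(array(0L, grid_shape(inner_ear)),
                        spacing = inner_ear$spacing, origin = inner_ear$origin,
                        orientation = inner_ear$orientation)
  if (sum(inner_ear$mask) == 0L) {
    warning("derive_otic_capsule: empty inner-ear label, returning empty capsule")
    return(empty)
  }
  cc <- conn_code(connectivity)
  d <- grid_shape(inner_ear)
  inrange <- (volume$values >= range$lo & volume$values <= range$hi) &
    inner_ear$mask == 0L
  ring <- cpp_dilate(as.integer(inner_ear$mask), d, 1L, cc)
  seeds <- as.integer(ring == 1L & inner_ear$mask == 0L & inrange)
  grown <- cpp_grow(seeds, as.integer(inrange), d, cc, as.integer(max_iterations))
  oto_labelmap(array(grown, d), spacing = inner_ear$spacing,
               origin = inner_ear$origin, orientation = inner_ear$orientation)
}
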