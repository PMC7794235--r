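#' Phantom generator settings
#'
#' Configures the procedural temporal-bone CT phantom: a fluid-filled
#' labyrinth (vestibule + spiral cochlear tube + three orthogonal
#' semicircular-canal arcs) wrapped in a compact-bone capsule shell, small
#' compact-bone ossicle bodies suspended in an air-filled middle-ear
#' cavity, a thin soft-tissue facial-nerve canal, a wide soft-tissue
#' sigmoid-sinus channel at the posterior face, all embedded in trabecular
#' bone with additive Gaussian HU noise.
#'
#' Tissue HU means are realistic CT values (air -1000, fluid 20, soft 40,
#' trabecular 600, compact 1500), chosen so the standard refinement
#' thresholds partition the tissues as intended: fluid and soft tissue fall
#' in -400..550, compact bone in 650..2500, and trabecular bone sits in the
#' 550..650 gap excluded from both the soft-tissue and compact ranges — the
#' contrast the HU-constrained refinement relies on.
#'
#' @param grid a [grid_spec()]; default 64^3 voxels at 0.25 mm.
#' @param seed integer; the phantom is deterministic given the seed.
#' @param noise_sd additive Gaussian noise SD in HU (default 20, a typical
#'   high-resolution CT noise level).
#' @param tissue_hu named numeric: mean HU for `air`, `fluid`, `soft`,
#'   `trabecular`, `compact`; must be ordered air < fluid <= soft <
#'   trabecular < compact.
#' @param geometry named list of structure dimensions in mm (see defaults).
#' @param side `"right"` or `"left"`; a left phantom is the mirror image of
#'   the right phantom with the same seed.
#' @param corruption optional `list(erode_voxels =, noise_flip_rate =)`
#'   passed to [corrupt_label()] by callers producing degraded labels.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = grid_spec(c(64L, 64L, 64L), c(0.25, 0.25, 0.25)),
                           seed = 1L, noise_sd = 20,
                           tissue_hu = c(air = -1000, fluid = 20, soft = 40,
                                         trabecular = 600, compact = 1500),
                           geometry = list(), side = c("right", "left"),
                           corruption = NULL) {
  side <- match.arg(side)
  g <- modifyList(default_phantom_geometry(), geometry)
  th <- tissue_hu
  need <- c("air", "fluid", "soft", "trabecular", "compact")
  if (!all(need %in% names(th))) stop("tissue_hu must name: ", paste(need, collapse = ", "))
  if (!(th["air"] < th["fluid"] && th["fluid"] <= th["soft"] &&
        th["soft"] < th["trabecular"] && th["trabecular"] < th["compact"])) {
    stop("tissue_hu must be ordered air < fluid <= soft < trabecular < compact")
  }
  radii <- c(g$canal_radius_mm, g$capsule_thickness_mm, g$nerve_radius_mm,
             g$sinus_radius_mm, unlist(g$ossicle_radii_mm))
  if (any(radii <= 0)) stop("all radii/thicknesses must be > 0")
  if (any(radii < min(grid$spacing))) {
    stop("geometry not representable: radius below voxel spacing")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(grid = grid, seed = as.integer(seed), noise_sd = noise_sd,
                 tissue_hu = th, geometry = g, side = side,
                 corruption = corruption),
            class = "phantom_config")
}

default_phantom_geometry <- function() {
  list(
    labyrinth_offset_mm = c(-2.8, 0.5, 0.3),   # from volume center
    vestibule_radii_mm  = c(1.5, 1.1, 1.1),
    cochlea_radius_mm   = 1.6,                 # outermost spiral radius
    cochlea_tube_mm     = 0.55,
    canal_ring_mm       = 2.6,                 # semicircular canal ring radius
    canal_radius_mm     = 0.4,                 # canal tube radius
    capsule_thickness_mm = 0.5,
    cavity_offset_mm    = c(4.2, 1.0, 0.2),
    cavity_radii_mm     = c(2.5, 2.2, 2.6),
    ossicle_radii_mm    = list(c(0.9, 0.6, 0.5), c(0.7, 0.5, 0.45),
                               c(0.5, 0.4, 0.35)),
    nerve_radius_mm     = 0.5,
    nerve_amplitude_mm  = 1.5,
    sinus_radius_mm     = 1.5
  )
}

ellipsoid_mask <- function(shape, spacing, center, radii) {
  ax <- ((seq_len(shape[1]) - 1) * spacing[1] - center[1])^2 / radii[1]^2
  ay <- ((seq_len(shape[2]) - 1) * spacing[2] - center[2])^2 / radii[2]^2
  az <- ((seq_len(shape[3]) - 1) * spacing[3] - center[3])^2 / radii[3]^2
  outer(outer(ax, ay, "+"), az, "+") <= 1
}

tube_mask <- function(shape, spacing, points, radius) {
  m <- cpp_stamp_spheres(shape, spacing, c(0, 0, 0), points, radius)
  array(m, shape)
}

#' Generate one temporal-bone CT phantom
#'
#' Builds the scene described in [phantom_config()] and returns the noisy
#' HU volume together with exact, noise-free ground-truth label maps
#' (`inner_ear`, `otic_capsule`, `ossicles`, `facial_nerve`,
#' `sigmoid_sinus`), pairwise disjoint. The capsule is, by construction,
#' the compact shell of the configured thickness around the inner ear. A
#' left-sided phantom is exactly the mirror of the right-sided phantom with
#' the same seed.
#'
#' @param config a [phantom_config()].
#' @return A list with `volume` (an [oto_volume()]), `labels` (named list
#'   of [oto_labelmap()]), `side`, and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config")
  shape <- config$grid$shape
  sp <- config$grid$spacing
  ext <- shape * sp
  ctr <- ext / 2
  g <- config$geometry
  th <- config$tissue_hu

  lab_c <- ctr + g$labyrinth_offset_mm
  cav_c <- ctr + g$cavity_offset_mm
  # a structure rasterized up against the grid border has been clipped:
  # report the geometry as too large rather than return truncated anatomy
  check_fit <- function(mask, margin_vox, name) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("phantom geometry degenerate (empty): ", name)
    lo <- apply(idx, 2, min)
    hi <- apply(idx, 2, max)
    if (any(lo <= margin_vox) || any(hi > shape - margin_vox)) {
      stop("phantom geometry too large for grid: ", name)
    }
  }

  # --- labyrinth: vestibule + cochlear spiral + three canal arcs
  vest <- ellipsoid_mask(shape, sp, lab_c, g$vestibule_radii_mm)

  coch_c <- lab_c + c(0.5, 2.0, -1.0)
  tmax <- 2.25 * 2 * pi
  t <- seq(0, tmax, by = 0.03)
  rad <- g$cochlea_radius_mm * (1 - 0.65 * t / tmax)
  coch_pts <- cbind(coch_c[1] + rad * cos(t),
                    coch_c[2] + rad * sin(t),
                    coch_c[3] + 0.3 * t / (2 * pi))
  coch <- tube_mask(shape, sp, coch_pts, g$cochlea_tube_mm)

  can_c <- lab_c + c(0, -0.5, 1.0)
  R <- g$canal_ring_mm
  arc <- seq(0, 4 * pi / 3, by = 0.02)
  canal_pts <- rbind(
    cbind(can_c[1] + R * cos(arc), can_c[2] + R * sin(arc),
          rep(can_c[3], length(arc))),                       # lateral (axial plane)
    cbind(can_c[1] + R * cos(arc + pi / 3), rep(can_c[2], length(arc)),
          can_c[3] + R * sin(arc + pi / 3)),                 # superior (coronal plane)
    cbind(rep(can_c[1], length(arc)), can_c[2] + R * cos(arc + pi / 3),
          can_c[3] + R * sin(arc + pi / 3))                  # posterior (sagittal plane)
  )
  canals <- tube_mask(shape, sp, canal_pts, g$canal_radius_mm)

  # connector ducts: the canals open into the vestibule and the cochlea
  # communicates with it, keeping the labyrinth one fluid-connected body
  # under geometry jitter
  seg_pts <- function(a, b) {
    s <- seq(0, 1, by = 0.02)
    cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]),
          a[3] + s * (b[3] - a[3]))
  }
  arc_ends <- rbind(
    can_c + c(R * cos(0), R * sin(0), 0),
    can_c + c(R * cos(4 * pi / 3), R * sin(4 * pi / 3), 0),
    can_c + c(R * cos(pi / 3), 0, R * sin(pi / 3)),
    can_c + c(R * cos(4 * pi / 3 + pi / 3), 0, R * sin(4 * pi / 3 + pi / 3)),
    can_c + c(0, R * cos(pi / 3), R * sin(pi / 3)),
    can_c + c(0, R * cos(4 * pi / 3 + pi / 3), R * sin(4 * pi / 3 + pi / 3))
  )
  conn_pts <- do.call(rbind, c(
    lapply(seq_len(nrow(arc_ends)), function(i) seg_pts(lab_c, arc_ends[i, ])),
    list(seg_pts(lab_c, coch_pts[1, ]))
  ))
  connectors <- tube_mask(shape, sp, conn_pts, g$canal_radius_mm)

  inner <- vest | coch | canals | connectors

  k <- max(1L, as.integer(round(g$capsule_thickness_mm / min(sp))))
  check_fit(inner, k + 1L, "inner_ear/otic_capsule")
  dil <- array(cpp_dilate(as.integer(inner), shape, k, 6L) == 1L, shape)
  capsule <- dil & !inner

  # --- middle-ear air cavity with ossicles
  cavity <- ellipsoid_mask(shape, sp, cav_c, g$cavity_radii_mm)
  check_fit(cavity, 1L, "ossicles (air cavity)")
  oss_offsets <- list(c(-0.6, 0.3, 0.6), c(0.4, -0.3, 0), c(1.0, 0.2, -0.6))
  oss <- array(FALSE, shape)
  for (i in seq_along(g$ossicle_radii_mm)) {
    oss <- oss | ellipsoid_mask(shape, sp, cav_c + oss_offsets[[i]],
                                g$ossicle_radii_mm[[i]])
  }
  oss <- oss & cavity

  # --- facial nerve: thin soft-tissue tube curving past the labyrinth
  s <- seq(0, 1, by = 0.004)
  nerve_pts <- cbind(lab_c[1] + 1.0 + 6.5 * s,
                     lab_c[2] - 2.6 + g$nerve_amplitude_mm * sin(pi * s),
                     lab_c[3] + 2.0 - 4.5 * s)
  nerve <- tube_mask(shape, sp, nerve_pts, g$nerve_radius_mm)

  # --- sigmoid sinus: wide soft-tissue channel at the posterior face
  zpath <- seq(0.25, ext[3] - 0.25, by = 0.05)
  sinus_pts <- cbind(ctr[1] + 1.0 + 0.8 * sin(pi * zpath / ext[3]),
                     2.0 + 0.6 * cos(pi * zpath / ext[3]),
                     zpath)
  sinus <- tube_mask(shape, sp, sinus_pts, g$sinus_radius_mm)

  # --- precedence masking keeps labels pairwise disjoint
  oss <- oss & !inner & !capsule
  cavity <- cavity & !inner & !capsule & !oss
  nerve <- nerve & !inner & !capsule & !oss & !cavity
  sinus <- sinus & !inner & !capsule & !oss & !cavity & !nerve

  hu <- array(th[["trabecular"]], shape)
  hu[sinus] <- th[["soft"]]
  hu[nerve] <- th[["soft"]]
  hu[cavity] <- th[["air"]]
  hu[oss] <- th[["compact"]]
  hu[capsule] <- th[["compact"]]
  hu[inner] <- th[["fluid"]]
  if (config$noise_sd > 0) {
    hu <- hu + with_seed(derive_seed(config$seed, 1L),
                         rnorm(length(hu), 0, config$noise_sd))
  }

  vol <- oto_volume(hu, spacing = sp)
  labels <- list(
    inner_ear = oto_labelmap(inner * 1L, spacing = sp),
    otic_capsule = oto_labelmap(capsule * 1L, spacing = sp),
    ossicles = oto_labelmap(oss * 1L, spacing = sp),
    facial_nerve = oto_labelmap(nerve * 1L, spacing = sp),
    sigmoid_sinus = oto_labelmap(sinus * 1L, spacing = sp)
  )
  if (config$side == "left") {
    vol <- flip_lr(vol)
    labels <- lapply(labels, flip_lr)
  }
  list(volume = vol, labels = labels, side = config$side, config = config)
}

#' Degrade a label map into a plausible raw prediction
#'
#' Erodes the mask by `erode_voxels` (face connectivity) and then flips
#' each remaining background voxel to foreground with probability
#' `noise_flip_rate`. Used as the corrupted-input substrate for testing
#' refinement.
#'
#' @param label an [oto_labelmap()].
#' @param corruption `list(erode_voxels =, noise_flip_rate =)`.
#' @param seed integer seed for the flip noise.
#' @return The corrupted [oto_labelmap()]; empty (with a warning) if the
#'   erosion removes every voxel.
#' @export
corrupt_label <- function(label, corruption = list(erode_voxels = 1L,
                                                   noise_flip_rate = 0.005),
                          seed = 1L) {
  m <- label$mask
  d <- dim(m)
  ev <- as.integer(corruption$erode_voxels %||% 0L)
  rate <- corruption$noise_flip_rate %||% 0
  if (ev > 0L) m <- array(cpp_erode(as.integer(m), d, ev, 6L), d)
  if (sum(m) == 0L && sum(label$mask) > 0L) {
    warning("corrupt_label: erosion emptied the mask")
    return(set_grid_values(label, m))
  }
  if (rate > 0) {
    flips <- with_seed(derive_seed(seed, 2L), runif(length(m)) < rate)
    m[flips & m == 0L] <- 1L
  }
  set_grid_values(label, m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a phantom dataset with jittered geometry
#'
#' Produces `n` phantoms with per-sample seeds derived from the master
#' seed: structure radii are perturbed by +/-20% (uniform), the labyrinth
#' and cavity placements are jittered by up to 0.5 mm, and each sample is
#' randomly left- or right-sided. Two calls with the same master seed give
#' identical datasets.
#'
#' @param n number of phantoms (>= 1).
#' @param config_template a [phantom_config()] supplying grid, noise and
#'   base geometry.
#' @param seed master seed.
#' @return List of `n` results of [generate_phantom()].
#' @export
generate_dataset <- function(n, config_template = phantom_config(), seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    jit <- with_seed(si, list(
      r = runif(8, 0.8, 1.2),
      lab = runif(3, -0.5, 0.5),
      cav = runif(3, -0.5, 0.5),
      side = runif(1)
    ))
    g <- config_template$geometry
    g$vestibule_radii_mm <- g$vestibule_radii_mm * jit$r[1]
    g$cochlea_radius_mm <- g$cochlea_radius_mm * jit$r[2]
    g$canal_ring_mm <- g$canal_ring_mm * jit$r[3]
    g$canal_radius_mm <- g$canal_radius_mm * jit$r[4]
    g$nerve_radius_mm <- g$nerve_radius_mm * jit$r[5]
    g$sinus_radius_mm <- g$sinus_radius_mm * jit$r[6]
    g$nerve_amplitude_mm <- g$nerve_amplitude_mm * jit$r[7]
    g$ossicle_radii_mm <- lapply(g$ossicle_radii_mm, function(r) r * jit$r[8])
    g$labyrinth_offset_mm <- g$labyrinth_offset_mm + jit$lab
    g$cavity_offset_mm <- g$cavity_offset_mm + jit$cav
    cfg <- phantom_config(grid = config_template$grid, seed = si,
                          noise_sd = config_template$noise_sd,
                          tissue_hu = config_template$tissue_hu,
                          geometry = g,
                          side = if (jit$side < 0.5) "right" else "left",
                          corruption = config_template$corruption)
    generate_phantom(cfg)
  })
}

#' Seeded train/test split of a phantom dataset
#'
#' @param dataset list as returned by [generate_dataset()].
#' @param n_test number of held-out samples.
#' @param seed split seed.
#' @return `list(train =, test =, test_idx =)`.
#' @export
split_dataset <- function(dataset, n_test, seed = 1L) {
  n <- length(dataset)
  if (n_test >= n) stop("n_test must be smaller than the dataset")
  test_idx <- sort(with_seed(derive_seed(seed, 99L), sample.int(n, n_test)))
  list(train = dataset[setdiff(seq_len(n), test_idx)],
       test = dataset[test_idx], test_idx = test_idx)
}
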