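#' Intensity window
#'
#' The HU window used to rescale CT intensities to the unit interval before
#' training or inference. The defaults (-500 to 2000 HU) span air-adjacent
#' soft tissue up to dense compact bone, the range informative for temporal
#' bone anatomy.
#'
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return An object of class `hu_window`.
#' @export
hu_window <- function(lo = -500, hi = 2000) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("hu_window requires finite lo < hi")
  }
  structure(list(lo = lo, hi = hi), class = "hu_window")
}

#' Training-time augmentation settings
#'
#' Two augmentations are applied per epoch: a single multiplicative
#' intensity jitter drawn uniformly from `[1 - m, 1 + m]` applied to the
#' whole volume with probability `jitter_prob`, and a synchronized
#' left-right flip of volume and label with probability `flip_prob`.
#' Defaults: 10% jitter magnitude at 10% probability, 50% flip probability.
#'
#' @param jitter_prob probability of applying the intensity jitter.
#' @param jitter_magnitude jitter half-width `m` (unitless fraction).
#' @param flip_prob probability of the left-right flip.
#' @param seed integer; augmentation draws are reproducible from
#'   `(seed, epoch, sample)`.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(jitter_prob = 0.1, jitter_magnitude = 0.1,
                           flip_prob = 0.5, seed = 1L) {
  for (p in c(jitter_prob, flip_prob)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (!is.finite(jitter_magnitude) || jitter_magnitude < 0) {
    stop("jitter_magnitude must be >= 0")
  }
  structure(list(jitter_prob = jitter_prob, jitter_magnitude = jitter_magnitude,
                 flip_prob = flip_prob, seed = as.integer(seed)),
            class = "augment_config")
}

#' Rescale HU intensities to the unit interval
#'
#' Applies `clamp((v - lo) / (hi - lo), 0, 1)` per voxel; grid metadata is
#' unchanged. With the default window, -500 HU maps to 0, 2000 HU to 1 and
#' 750 HU to 0.5.
#'
#' @param volume an [oto_volume()] in raw HU.
#' @param window an [hu_window()].
#' @return An [oto_volume()] with unitless values in `[0, 1]`.
#' @export
window_rescale <- function(volume, window = hu_window()) {
  if (!inherits(window, "hu_window")) stop("window must be an hu_window")
  v <- (volume$values - window$lo) / (window$hi - window$lo)
  volume$values <- pmin(pmax(v, 0), 1)
  volume
}

#' Standardize a dataset to right-sided anatomy
#'
#' Left-sided scans are mirrored across the left-right axis so all inputs
#' present right-sided anatomy; right-sided scans pass through unchanged.
#' The volume and its label map receive identical treatment, and the output
#' is always marked right-sided, so the operation is idempotent.
#'
#' @param volume an [oto_volume()].
#' @param label an optional [oto_labelmap()] paired with `volume`, or a
#'   named list of label maps.
#' @param source_side `"left"` or `"right"`.
#' @return A list with elements `volume`, `label`, `flipped` and `side`
#'   (always `"right"`).
#' @export
standardize_side <- function(volume, label = NULL, source_side = c("right", "left")) {
  source_side <- match.arg(source_side)
  flipped <- source_side == "left"
  if (flipped) {
    volume <- flip_lr(volume)
    if (!is.null(label)) {
      label <- if (inherits(label, "oto_labelmap")) {
        flip_lr(label)
      } else {
        lapply(label, flip_lr)
      }
    }
  }
  list(volume = volume, label = label, flipped = flipped, side = "right")
}

#' Apply training-time augmentation to a (volume, label) pair
#'
#' With probability `jitter_prob` all intensities are multiplied by one
#' factor drawn uniformly from `[1 - m, 1 + m]` and re-clamped to `[0, 1]`;
#' with probability `flip_prob` the volume and label are flipped together
#' across the left-right axis. Randomness is keyed by
#' `(config$seed, epoch, sample)` so every epoch of every cross-validation
#' fold is reproducible.
#'
#' @param volume an [oto_volume()] already rescaled to `[0, 1]`.
#' @param label the paired [oto_labelmap()].
#' @param config an [augment_config()].
#' @param epoch integer epoch counter (0-based).
#' @param sample integer sample index within the epoch.
#' @return A list with `volume`, `label`, `jitter_factor` (NA when the
#'   jitter branch was not taken) and `flipped`.
#' @export
augment <- function(volume, label, config = augment_config(), epoch = 0L,
                    sample = 1L) {
  draws <- with_seed(derive_seed(config$seed, epoch, sample), runif(3))
  jitter_factor <- NA_real_
  if (draws[1] < config$jitter_prob) {
    m <- config$jitter_magnitude
    jitter_factor <- (1 - m) + draws[2] * (2 * m)
    volume$values <- pmin(pmax(volume$values * jitter_factor, 0), 1)
  }
  flipped <- draws[3] < config$flip_prob
  if (flipped) {
    volume <- flip_lr(volume)
    label <- flip_lr(label)
  }
  list(volume = volume, label = label, jitter_factor = jitter_factor,
       flipped = flipped)
}
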