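#' End-to-end pipeline configuration
#'
#' Aggregates every stage's settings: intensity window, training grid and
#' isotropic working spacing, per-structure refinement specs, network and
#' training protocol, phantom-generation settings and output paths.
#' Full-scale defaults follow the reference protocol (256 x 256 x 240
#' training grid at 1 mm, 0.25 mm working spacing, 2000 epochs); use
#' [demo_pipeline_config()] for a desk-scale run.
#'
#' @param window an [hu_window()].
#' @param training_grid a [grid_spec()] volumes are resampled to for
#'   training and prediction.
#' @param working_spacing isotropic refinement spacing in mm.
#' @param structures named list of [structure_spec()]s.
#' @param structures_to_train character; which structures get a model.
#' @param derive_capsule derive the otic capsule from the refined inner ear.
#' @param net a [net_config()].
#' @param train a [train_config()].
#' @param phantom `list(n_train =, n_test =, config = phantom_config())`.
#' @param out_dir output directory for volumes, metrics and the manifest.
#' @param seed master seed for the run.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = hu_window(),
                            training_grid = grid_spec(c(256L, 256L, 240L), c(1, 1, 1)),
                            working_spacing = 0.25,
                            structures = default_structure_specs(),
                            structures_to_train = "inner_ear",
                            derive_capsule = TRUE,
                            net = net_config(),
                            train = train_config(),
                            phantom = list(n_train = 12L, n_test = 4L,
                                           config = phantom_config()),
                            out_dir = NULL,
                            seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  nm <- vapply(structures, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("structure specs must be unique by name")
  names(structures) <- nm
  for (st in structures_to_train) {
    if (!st %in% nm) {
      stop("no structure spec (HU range) configured for '", st, "'")
    }
  }
  if (derive_capsule && !"otic_capsule" %in% nm) {
    stop("derive_capsule requires an otic_capsule structure spec")
  }
  if (!is.finite(working_spacing) || working_spacing <= 0) {
    stop("working_spacing must be positive")
  }
  structure(list(window = window, training_grid = training_grid,
                 working_spacing = working_spacing, structures = structures,
                 structures_to_train = structures_to_train,
                 derive_capsule = derive_capsule, net = net, train = train,
                 phantom = phantom, out_dir = out_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Desk-scale demonstration configuration
#'
#' 64^3 phantoms at 0.25 mm; training at 0.5 mm (32^3) mirroring the
#' coarse-train / fine-refine pattern of the full-scale protocol;
#' refinement at 0.25 mm; a depth-3 network with 4 base channels trained
#' for 30 epochs at learning rate 3e-2. Completes on one CPU core in a few
#' minutes.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_train,n_test phantom counts.
#' @param epochs training epochs (scaled down from the full protocol).
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir, seed = 1L, n_train = 12L, n_test = 4L,
                                 epochs = 30L) {
  pipeline_config(
    training_grid = grid_spec(c(32L, 32L, 32L), c(0.5, 0.5, 0.5)),
    working_spacing = 0.25,
    net = net_config(depth = 3L, base_channels = 4L,
                     patch_shape = c(32L, 32L, 32L)),
    train = train_config(epochs = epochs, initial_lr = 3e-2,
                         decay_factor = 1 / 3, decay_every = 400L,
                         batch_size = 2L, seed = seed,
                         augment = augment_config(seed = seed)),
    phantom = list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                   config = phantom_config()),
    out_dir = out_dir, seed = seed
  )
}

log_stage <- function(config, stage, msg, logfile = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  if (identical(config$log_level, "info")) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full pipeline on seeded phantoms
#'
#' Phantom generation, preprocessing (side standardization, HU windowing,
#' resampling to the training grid), per-structure training, prediction on
#' the held-out phantoms, HU-constrained refinement, otic-capsule
#' derivation and objective evaluation. Writes per-case NIfTI outputs, a
#' `metrics.csv` and a stage-status `manifest.json` to `config$out_dir`.
#' Re-running with the same configuration and seed reproduces the metrics
#' exactly (fixed thread count assumed). Ground-truth labels of the test
#' cases are consulted only in the evaluation stage.
#'
#' @param config a [pipeline_config()] with non-NULL `out_dir`.
#' @return Invisibly, a list with `metrics` (data.frame), `models`,
#'   `manifest` and `out_dir`.
#' @export
run_end_to_end <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "log.txt")
  cat("", file = logfile)

  cfg_json <- file.path(out_dir, "config.json")
  writeLines(jsonlite::serializeJSON(config), cfg_json)
  config_hash <- unname(tools::md5sum(cfg_json))

  stages <- c("phantom", "preprocess", "train", "predict", "refine", "evaluate")
  manifest <- list(package = "otoseg",
                   version = as.character(utils::packageVersion("otoseg")),
                   seed = config$seed, config_hash = config_hash,
                   stages = stats::setNames(as.list(rep("absent", length(stages))),
                                            stages))
  write_manifest(out_dir, manifest)
  fail <- function(stage, case, e) {
    manifest$stages[[stage]] <<- "FAILED"
    write_manifest(out_dir, manifest)
    stop("pipeline failed in stage '", stage, "' (case ", case, "): ",
         conditionMessage(e))
  }

  # --- phantoms
  t0 <- proc.time()[["elapsed"]]
  n_total <- config$phantom$n_train + config$phantom$n_test
  ds <- tryCatch(generate_dataset(n_total, config$phantom$config,
                                  seed = config$seed),
                 error = function(e) fail("phantom", NA, e))
  parts <- split_dataset(ds, config$phantom$n_test, seed = config$seed)
  manifest$stages$phantom <- "complete"
  write_manifest(out_dir, manifest)
  log_stage(config, "phantom",
            sprintf("%d train / %d test phantoms (%.1f s)",
                    length(parts$train), length(parts$test),
                    proc.time()[["elapsed"]] - t0), logfile)

  # --- preprocessing (standardize side, resample to training grid, window)
  t0 <- proc.time()[["elapsed"]]
  prep <- function(sample, with_labels) {
    std <- standardize_side(sample$volume,
                            if (with_labels) sample$labels else NULL,
                            source_side = sample$side)
    net_vol <- window_rescale(resample(std$volume, config$training_grid,
                                       "continuous"), config$window)
    net_labs <- if (with_labels) {
      lapply(std$label, resample, target = config$training_grid)
    } else {
      NULL
    }
    list(native_volume = std$volume, native_labels = std$label,
         net_volume = net_vol, net_labels = net_labs)
  }
  train_prep <- lapply(parts$train, prep, with_labels = TRUE)
  test_prep <- lapply(parts$test, prep, with_labels = FALSE)
  test_truth <- lapply(parts$test, function(s) {
    standardize_side(s$volume, s$labels, source_side = s$side)$label
  })
  manifest$stages$preprocess <- "complete"
  write_manifest(out_dir, manifest)
  log_stage(config, "preprocess",
            sprintf("done (%.1f s)", proc.time()[["elapsed"]] - t0), logfile)

  # --- per-structure training
  t0 <- proc.time()[["elapsed"]]
  models <- list()
  for (si in seq_along(config$structures_to_train)) {
    st <- config$structures_to_train[si]
    dset <- lapply(train_prep, function(s) {
      list(volume = s$net_volume, label = s$net_labels[[st]])
    })
    model <- build_model(config$net, seed = derive_seed(config$seed, 1000L + si),
                         structure_name = st)
    model <- tryCatch(train(model, dset, config$train),
                      error = function(e) fail("train", st, e))
    models[[st]] <- model
    save_model(model, file.path(out_dir, paste0("model_", st, ".ckpt")))
    log_stage(config, "train",
              sprintf("%s: %d epochs, final loss %.4f, train DSC %.3f", st,
                      nrow(model$training_curve),
                      utils::tail(model$training_curve$loss, 1),
                      utils::tail(model$training_curve$dsc, 1)), logfile)
  }
  manifest$stages$train <- "complete"
  write_manifest(out_dir, manifest)
  log_stage(config, "train",
            sprintf("all structures (%.1f s)", proc.time()[["elapsed"]] - t0),
            logfile)

  # --- prediction + refinement on the held-out phantoms
  preds <- list()
  for (ci in seq_along(test_prep)) {
    tc <- test_prep[[ci]]
    case_id <- sprintf("case_%03d", ci)
    write_volume(tc$native_volume,
                 file.path(out_dir, paste0(case_id, "_ct.nii.gz")))
    for (st in names(models)) {
      t1 <- proc.time()[["elapsed"]]
      prob <- tryCatch(predict(models[[st]], tc$net_volume),
                       error = function(e) fail("predict", case_id, e))
      raw_mask <- binarize(prob, 0.5)
      native_grid <- grid_spec(grid_shape(tc$native_volume),
                               tc$native_volume$spacing)
      raw_native <- resample(raw_mask, native_grid, "nearest")
      refined <- tryCatch(
        refine_pipeline(raw_native, tc$native_volume, config$structures[[st]],
                        config$working_spacing),
        error = function(e) fail("refine", case_id, e))
      secs <- proc.time()[["elapsed"]] - t1
      preds[[case_id]][[st]] <- list(raw = raw_native, refined = refined,
                                     seconds = secs)
      write_volume(refined,
                   file.path(out_dir, paste0(case_id, "_", st, "_refined.nii.gz")))
      if (config$derive_capsule && st == "inner_ear") {
        t1 <- proc.time()[["elapsed"]]
        caps_spec <- config$structures$otic_capsule
        capsule <- derive_otic_capsule(refined, tc$native_volume,
                                       range = caps_spec$refine_range,
                                       max_iterations = caps_spec$max_grow_iterations,
                                       connectivity = caps_spec$grow_connectivity)
        preds[[case_id]]$otic_capsule <- list(refined = capsule,
                                              seconds = proc.time()[["elapsed"]] - t1)
        write_volume(capsule,
                     file.path(out_dir, paste0(case_id, "_otic_capsule.nii.gz")))
      }
    }
    log_stage(config, "predict", paste0(case_id, " done"), logfile)
  }
  manifest$stages$predict <- "complete"
  manifest$stages$refine <- "complete"
  write_manifest(out_dir, manifest)

  # --- evaluation (the only stage that reads test ground truth)
  rows <- list()
  for (ci in seq_along(test_prep)) {
    case_id <- sprintf("case_%03d", ci)
    for (st in names(preds[[case_id]])) {
      pr <- preds[[case_id]][[st]]
      rep <- tryCatch(
        evaluate_pair(pr$refined, test_truth[[ci]][[st]], seconds = pr$seconds),
        error = function(e) fail("evaluate", case_id, e))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(case_id = case_id, structure = st),
              as.data.frame(rep))
    }
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  manifest$stages$evaluate <- "complete"
  write_manifest(out_dir, manifest)
  for (st in unique(metrics$structure)) {
    m <- metrics[metrics$structure == st, ]
    log_stage(config, "evaluate",
              sprintf("%s: mean DSC %.3f, mean AHD %.3f mm, volsim %.1f%%",
                      st, mean(m$dsc), mean(m$ahd_mm), mean(m$volsim_pct)),
              logfile)
  }
  invisible(list(metrics = metrics, models = models, manifest = manifest,
                 out_dir = out_dir))
}

#' Read back a run's manifest
#'
#' @param run_dir a directory previously used as `out_dir` of
#'   [run_end_to_end()].
#' @return The manifest record: package version, seed, config hash and
#'   per-stage completion status.
#' @export
version_manifest <- function(run_dir) {
  path <- file.path(run_dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest found in ", run_dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
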