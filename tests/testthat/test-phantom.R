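test_that("phantom generation is deterministic and obeys its construction", {
  cfg <- phantom_config(seed = 12, noise_sd = 0)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$labels$inner_ear$mask, b$labels$inner_ear$mask)
  # noise-free tissues carry their exact configured HU
  th <- cfg$tissue_hu
  expect_true(all(a$volume$values[a$labels$inner_ear$mask == 1L] == th[["fluid"]]))
  expect_true(all(a$volume$values[a$labels$otic_capsule$mask == 1L] == th[["compact"]]))
  expect_true(all(a$volume$values[a$labels$ossicles$mask == 1L] == th[["compact"]]))
  expect_true(all(a$volume$values[a$labels$sigmoid_sinus$mask == 1L] == th[["soft"]]))
  # labels pairwise disjoint
  overlap <- Reduce(`+`, lapply(a$labels, function(l) l$mask))
  expect_lte(max(overlap), 1)
})

test_that("each structure is non-empty and the capsule wraps the inner ear", {
  ph <- generate_phantom(phantom_config(seed = 30))
  for (nm in names(ph$labels)) expect_gt(sum(ph$labels[[nm]]$mask), 0)
  d <- dim(ph$labels$inner_ear$mask)
  boundary <- otoseg:::cpp_boundary(as.integer(ph$labels$inner_ear$mask), d)
  ring <- otoseg:::cpp_dilate(as.integer(ph$labels$otic_capsule$mask), d, 1L, 6L)
  # every inner-ear boundary voxel has a face neighbor in the capsule
  expect_true(all(ring[boundary == 1L] == 1L))
})

test_that("left phantoms are exact mirrors of right phantoms", {
  r <- generate_phantom(phantom_config(seed = 9, side = "right"))
  l <- generate_phantom(phantom_config(seed = 9, side = "left"))
  expect_identical(l$volume$values, flip_lr(r$volume)$values)
  for (nm in names(r$labels)) {
    expect_identical(l$labels[[nm]]$mask, flip_lr(r$labels[[nm]])$mask)
  }
})

test_that("config invariants reject impossible worlds", {
  expect_error(phantom_config(tissue_hu = c(air = -1000, fluid = 600,
                                            soft = 40, trabecular = 300,
                                            compact = 1500)), "ordered")
  expect_error(phantom_config(geometry = list(canal_radius_mm = 0.1)),
               "representable")
  # geometry that cannot fit the grid names the offending structure
  expect_error(generate_phantom(phantom_config(
    geometry = list(canal_ring_mm = 9))), "too large.*inner_ear")
})

test_that("refinement of the true inner-ear label is a near fixed point", {
  ph <- generate_phantom(phantom_config(seed = 16, noise_sd = 50))
  spec <- default_structure_specs()$inner_ear
  refined <- hu_constrained_refine(ph$labels$inner_ear, ph$volume, spec)
  expect_gte(dice(refined, ph$labels$inner_ear), 0.99)
})

test_that("corrupt_label degrades as configured", {
  d <- c(9, 9, 9)
  cube <- array(0L, d); cube[3:7, 3:7, 3:7] <- 1L  # 5^3 solid cube
  lm <- oto_labelmap(cube, spacing = c(0.25, 0.25, 0.25))
  identity_out <- corrupt_label(lm, list(erode_voxels = 0, noise_flip_rate = 0))
  expect_identical(identity_out$mask, cube)
  eroded <- corrupt_label(lm, list(erode_voxels = 1, noise_flip_rate = 0))
  expect_equal(sum(eroded$mask), 27)               # 3^3 remains
  expect_true(all(eroded$mask[4:6, 4:6, 4:6] == 1L))
  noisy <- corrupt_label(lm, list(erode_voxels = 1, noise_flip_rate = 0.01),
                         seed = 2)
  expect_lt(dice(noisy, lm), 1)
  # erosion that wipes out the mask warns and returns empty
  thin <- array(0L, d); thin[5, , ] <- 1L
  expect_warning(gone <- corrupt_label(oto_labelmap(thin),
                                       list(erode_voxels = 1,
                                            noise_flip_rate = 0.5)),
                 "emptied")
  expect_equal(sum(gone$mask), 0)
})

test_that("datasets are reproducible with jittered geometry and mixed sides", {
  ds1 <- generate_dataset(6, phantom_config(), seed = 77)
  ds2 <- generate_dataset(6, phantom_config(), seed = 77)
  for (i in seq_along(ds1)) {
    expect_identical(ds1[[i]]$volume$values, ds2[[i]]$volume$values)
  }
  # a dataset sample is exactly generate_phantom at its recorded config
  redo <- generate_phantom(ds1[[3]]$config)
  expect_identical(redo$volume$values, ds1[[3]]$volume$values)
  radii <- vapply(ds1, function(s) s$config$geometry$canal_radius_mm, numeric(1))
  expect_gt(length(unique(radii)), 1)  # geometry is actually jittered
  split <- split_dataset(ds1, 2, seed = 5)
  expect_length(split$train, 4)
  expect_length(split$test, 2)
  expect_identical(split_dataset(ds1, 2, seed = 5)$test_idx, split$test_idx)
})

test_that("geometry jitter spans a wide range across a larger sample", {
  ds <- generate_dataset(20, phantom_config(), seed = 123)
  radii <- vapply(ds, function(s) s$config$geometry$canal_radius_mm, numeric(1))
  expect_gte(max(radii) / min(radii), 1.3)
  rings <- vapply(ds, function(s) s$config$geometry$canal_ring_mm, numeric(1))
  expect_gte(max(rings) / min(rings), 1.3)
})
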