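tiny_net <- function(...) {
  net_config(depth = 2L, base_channels = 4L, patch_shape = c(8L, 8L, 8L), ...)
}

test_that("soft_dice_loss matches hand evaluation and pairs with dice", {
  r <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_lt(soft_dice_loss(r, r), 1e-4)                 # perfect prediction
  expect_gt(soft_dice_loss(rep(0, 8), r), 1 - 1e-4)     # empty prediction
  expect_equal(soft_dice_loss(rep(0.5, 8), r, eps = 0), 0.5)  # hand-derived
  expect_error(soft_dice_loss(rep(0.5, 4), r), "shape")
  set.seed(19)
  for (i in 1:10) {
    p <- as.numeric(runif(27) < 0.4)   # binary probabilities
    ref <- array(as.integer(runif(27) < 0.4), c(3, 3, 3))
    l <- soft_dice_loss(p, ref)
    expect_gte(l, 0); expect_lte(l, 1)
    d <- dice(oto_labelmap(array(as.integer(p), c(3, 3, 3))),
              oto_labelmap(ref))
    expect_equal(1 - l, d, tolerance = 1e-3)  # eps-order agreement
  }
})

test_that("the learning-rate schedule reproduces the step-decay protocol", {
  cfg <- train_config()  # protocol defaults: 1e-4, 1/3 every 400
  expect_identical(lr_schedule(c(0, 400, 800), cfg),
                   c(1e-4, 1e-4 / 3, 1e-4 / 9))
  expect_identical(lr_schedule(399, cfg), 1e-4)
  # piecewise constant with exactly floor(epochs / decay_every) drops
  lrs <- lr_schedule(0:1999, cfg)
  expect_equal(sum(diff(lrs) != 0), 1999 %/% 400)
})

test_that("config invariants are enforced", {
  expect_error(net_config(depth = 1), "depth")
  expect_error(net_config(base_channels = 2), "base_channels")
  expect_error(net_config(depth = 3, patch_shape = c(10, 8, 8)), "divisible")
  expect_error(train_config(decay_factor = 0), "decay_factor")
  expect_error(binarize(oto_volume(array(0.5, c(2, 2, 2))), 1.5), "threshold")
})

test_that("build_model fulfills the shape, range and reproducibility contracts", {
  nc <- net_config(depth = 3, base_channels = 4, patch_shape = c(16, 16, 16))
  m1 <- build_model(nc, seed = 42)
  m2 <- build_model(nc, seed = 42)
  x <- oto_volume(array(runif(16^3), c(16, 16, 16)))
  p1 <- predict(m1, x)
  p2 <- predict(m2, x)
  expect_identical(dim(p1$values), c(16L, 16L, 16L))
  expect_true(all(p1$values >= 0 & p1$values <= 1))
  expect_identical(p1$values, p2$values)      # same seed, same init
  expect_identical(p1$values, predict(m1, x)$values)  # determinism
  m3 <- build_model(nc, seed = 43)
  expect_false(identical(predict(m3, x)$values, p1$values))
})

test_that("parameter count matches the analytic formula and scales ~4x", {
  # depth-2 net, channels c then 2c: counted layer by layer from the
  # documented architecture (27-voxel kernels, instance-norm gain/offset)
  count_depth2 <- function(c) {
    conv3 <- function(ci, co) co * ci * 27 + co
    inorm <- function(co) 2 * co
    enc1 <- conv3(1, c) + inorm(c) + conv3(c, c) + inorm(c)
    enc2 <- conv3(c, 2 * c) + inorm(2 * c) + conv3(2 * c, 2 * c) + inorm(2 * c)
    dec1 <- conv3(2 * c, c) + inorm(c) +          # up-convolution
      conv3(2 * c, c) + inorm(c) + conv3(c, c) + inorm(c)
    out <- c + 1
    enc1 + enc2 + dec1 + out
  }
  nc4 <- net_config(depth = 2, base_channels = 4, patch_shape = c(8, 8, 8))
  nc8 <- net_config(depth = 2, base_channels = 8, patch_shape = c(8, 8, 8))
  n4 <- n_parameters(build_model(nc4))
  n8 <- n_parameters(build_model(nc8))
  expect_equal(n4, count_depth2(4))
  expect_equal(n8, count_depth2(8))
  expect_gt(n8 / n4, 3.4)
  expect_lt(n8 / n4, 4.2)
})

test_that("predict pads non-divisible grids and crops back", {
  nc <- net_config(depth = 3, base_channels = 4, patch_shape = c(16, 16, 16))
  m <- build_model(nc, seed = 1)
  odd <- oto_volume(array(runif(10 * 14 * 9), c(10, 14, 9)))
  p <- predict(m, odd)
  expect_identical(dim(p$values), c(10L, 14L, 9L))
  expect_true(all(p$values >= 0 & p$values <= 1))
})

test_that("binarize thresholds correctly and is monotone in the threshold", {
  p <- oto_volume(array(c(0.7, 0.5, 0.49, 0.2, 1, 0, 0.999, 0.3), c(2, 2, 2)))
  expect_identical(as.vector(binarize(p, 0.5)$mask),
                   c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L))
  expect_true(all(binarize(p, 0)$mask == 1L))
  set.seed(4)
  pr <- oto_volume(array(runif(5^3), c(5, 5, 5)))
  counts <- vapply(seq(0, 1, by = 0.1), function(t) sum(binarize(pr, t)$mask),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("training validates inputs and epochs = 0 is the identity", {
  nc <- tiny_net()
  m <- build_model(nc, seed = 3)
  x <- oto_volume(array(runif(8^3), c(8, 8, 8)))
  lab <- oto_labelmap(array(as.integer(runif(8^3) < 0.2), c(8, 8, 8)))
  expect_error(train(m, list(), train_config()), "non-empty")
  raw_hu <- oto_volume(array(1500, c(8, 8, 8)))
  expect_error(train(m, list(list(volume = raw_hu, label = lab)),
                     train_config(epochs = 1)), "rescaled")
  m0 <- train(m, list(list(volume = x, label = lab)), train_config(epochs = 0))
  expect_identical(predict(m0, x)$values, predict(m, x)$values)
})

test_that("a small model overfits a single phantom (smoke oracle)", {
  ph <- generate_phantom(phantom_config(seed = 4))
  tg <- grid_spec(c(32L, 32L, 32L), c(0.5, 0.5, 0.5))
  vol <- window_rescale(resample(ph$volume, tg), hu_window())
  lab <- resample(ph$labels$inner_ear, tg)
  nc <- net_config(depth = 3, base_channels = 4, patch_shape = c(32, 32, 32))
  m <- build_model(nc, seed = 2, structure_name = "inner_ear")
  tc <- train_config(epochs = 150, initial_lr = 3e-2, batch_size = 1, seed = 2,
                     augment = augment_config(jitter_prob = 0, flip_prob = 0,
                                              seed = 2))
  m <- train(m, list(list(volume = vol, label = lab)), tc)
  expect_equal(nrow(m$training_curve), 150)
  pred <- binarize(predict(m, vol))
  expect_gte(dice(pred, lab), 0.95)
  # training loss non-increasing over 50-epoch windows (local noise allowed)
  loss <- m$training_curve$loss
  for (i in seq(1, length(loss) - 50, by = 10)) {
    expect_lte(loss[i + 50], loss[i] + 0.02)
  }
})

test_that("checkpoints round-trip the model", {
  m <- build_model(tiny_net(residual_blocks = TRUE), seed = 9,
                   structure_name = "ossicles")
  path <- tempfile(fileext = ".ckpt")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$structure_name, "ossicles")
  expect_identical(m2$params, m$params)
  bad <- tempfile(fileext = ".ckpt")
  saveRDS(list(schema = "something-else"), bad)
  expect_error(load_model(bad), "schema")
  unlink(c(path, bad))
})

test_that("cross_validate partitions the data into disjoint exhaustive folds", {
  set.seed(6)
  mk <- function() {
    list(volume = oto_volume(array(runif(8^3), c(8, 8, 8))),
         label = oto_labelmap(array(as.integer(runif(8^3) < 0.3), c(8, 8, 8))))
  }
  ds <- replicate(5, mk(), simplify = FALSE)
  cfg <- train_config(epochs = 1, initial_lr = 1e-3, folds = 5, seed = 8,
                      augment = augment_config(jitter_prob = 0, flip_prob = 0))
  res <- cross_validate(ds, tiny_net(), cfg)
  cases <- sort(unlist(lapply(res$folds, function(f) f$case)))
  expect_identical(cases, 1:5)                    # leave-one-out partition
  expect_true(all(vapply(res$folds, nrow, integer(1)) == 1L))
  expect_true(all(c("dsc", "ahd_mm", "volsim_pct") %in% names(res$mean)))
  expect_error(cross_validate(ds, tiny_net(), train_config(folds = 6)),
               "exceed")
})
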