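#' Network architecture settings
#'
#' Describes the 3D encoder-decoder (U-Net style) used as the trainable
#' segmentation backend: `depth` resolution levels, channels doubling with
#' each level, symmetric decoder with skip concatenations, and a final
#' sigmoid producing one foreground probability per voxel. Setting
#' `residual_blocks = TRUE` adds identity shortcut connections around each
#' convolution block (with a 1x1x1 projection when channel counts differ),
#' representing the residual-network family of variants.
#'
#' @param depth number of resolution levels (>= 2).
#' @param base_channels feature channels at the first level (>= 4).
#' @param residual_blocks logical; add residual shortcut connections.
#' @param patch_shape integer length-3; input patch size, each component
#'   divisible by `2^(depth - 1)`.
#' @return An object of class `net_config`.
#' @export
net_config <- function(depth = 3L, base_channels = 8L, residual_blocks = FALSE,
                       patch_shape = c(64L, 64L, 64L)) {
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (length(patch_shape) == 1L) patch_shape <- rep(patch_shape, 3L)
  patch_shape <- as.integer(patch_shape)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_channels < 4L) stop("base_channels must be >= 4")
  div <- 2L^(depth - 1L)
  if (any(patch_shape %% div != 0L)) {
    stop("patch_shape must be divisible by 2^(depth-1) = ", div, " per axis")
  }
  structure(list(depth = depth, base_channels = base_channels,
                 residual_blocks = isTRUE(residual_blocks),
                 patch_shape = patch_shape),
            class = "net_config")
}

#' Training protocol settings
#'
#' Defaults follow the reference protocol for full-scale training: Adam for
#' 2000 epochs at initial learning rate 1e-4 with a step decay by a third
#' every 400 epochs, and fivefold cross-validation. Desk-scale runs
#' override `epochs`, `initial_lr` and `folds`.
#'
#' @param epochs number of passes over the training set (>= 0; 0 returns
#'   the model unchanged).
#' @param initial_lr initial Adam learning rate.
#' @param decay_factor multiplicative step-decay factor in `(0, 1]`.
#' @param decay_every epochs between decay steps.
#' @param folds cross-validation folds (>= 2 when cross-validating).
#' @param batch_size gradient-accumulation batch size.
#' @param seed integer master seed for initialization, shuffling and
#'   augmentation.
#' @param augment an [augment_config()].
#' @param window an [hu_window()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 2000L, initial_lr = 1e-4,
                         decay_factor = 1 / 3, decay_every = 400L,
                         folds = 5L, batch_size = 2L, seed = 1L,
                         augment = augment_config(seed = seed),
                         window = hu_window()) {
  if (epochs < 0) stop("epochs must be >= 0")
  if (!is.finite(decay_factor) || decay_factor <= 0 || decay_factor > 1) {
    stop("decay_factor must lie in (0, 1]")
  }
  if (decay_every < 1) stop("decay_every must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 folds = as.integer(folds), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), augment = augment, window = window),
            class = "train_config")
}

#' Step-decay learning-rate schedule
#'
#' `lr(epoch) = initial_lr * decay_factor ^ floor(epoch / decay_every)`,
#' with 0-based epochs. With the defaults this reproduces the protocol of
#' lr 1e-4 decayed by a third every 400 epochs: epoch 0 gives 1e-4, epoch
#' 400 gives 1e-4/3, epoch 800 gives 1e-4/9.
#'
#' @param epoch 0-based epoch (vectorized).
#' @param config a [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, config) {
  config$initial_lr * config$decay_factor^(epoch %/% config$decay_every)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * r) + eps) / (sum(p) + sum(r) + eps)` between a
#' probability grid and a binary reference. Zero (to eps order) when the
#' probabilities match a non-empty reference exactly; the natural training
#' companion of the Dice evaluation metric.
#'
#' @param probabilities numeric grid with values in `[0, 1]`.
#' @param reference binary grid of the same shape.
#' @param eps smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(probabilities, reference, eps = 1e-5) {
  p <- as.numeric(probabilities)
  r <- as.numeric(reference)
  if (length(p) != length(r)) stop("probabilities and reference shapes differ")
  1 - (2 * sum(p * r) + eps) / (sum(p) + sum(r) + eps)
}

soft_dice_grad <- function(p, r, eps = 1e-5) {
  I <- sum(p * r)
  S <- sum(p) + sum(r) + eps
  -(2 * r * S - (2 * I + eps)) / S^2
}

# ---- parameter construction -------------------------------------------------

conv3_init <- function(c_out, c_in, gain = 2) {
  fan_in <- c_in * 27
  list(W = matrix(rnorm(c_out * fan_in, sd = sqrt(gain / fan_in)),
                  nrow = c_out),
       b = rep(0, c_out))
}

inorm_init <- function(c_out) list(gamma = rep(1, c_out), beta = rep(0, c_out))

conv1_init <- function(c_out, c_in, gain = 2) {
  list(W = matrix(rnorm(c_out * c_in, sd = sqrt(gain / c_in)), nrow = c_out),
       b = rep(0, c_out))
}

#' Build an untrained segmentation model
#'
#' Constructs the encoder-decoder parameter set for one binary structure
#' model. The encoder halves resolution and doubles channels per level; the
#' decoder mirrors it with nearest-neighbor upsampling, an up-convolution
#' and skip concatenation; a 1x1x1 convolution plus sigmoid produces the
#' foreground probability. Initialization is reproducible from `seed`.
#'
#' @param config a [net_config()].
#' @param seed integer initialization seed.
#' @param structure_name token naming the target structure.
#' @return An object of class `oto_segmodel`.
#' @export
build_model <- function(config, seed = 1L, structure_name = "structure") {
  if (!inherits(config, "net_config")) stop("config must be a net_config")
  depth <- config$depth
  base <- config$base_channels
  ch <- base * 2L^(seq_len(depth) - 1L)
  res <- config$residual_blocks
  params <- with_seed(as.integer(seed), {
    p <- list(enc = vector("list", depth), dec = vector("list", depth - 1L))
    for (l in seq_len(depth)) {
      c_in <- if (l == 1L) 1L else ch[l - 1L]
      blk <- list(a = conv3_init(ch[l], c_in), an = inorm_init(ch[l]),
                  b = conv3_init(ch[l], ch[l]), bn = inorm_init(ch[l]))
      if (res) blk$proj <- conv1_init(ch[l], c_in)
      p$enc[[l]] <- blk
    }
    for (l in seq_len(depth - 1L)) {
      blk <- list(up = conv3_init(ch[l], ch[l + 1L]), un = inorm_init(ch[l]),
                  a = conv3_init(ch[l], 2L * ch[l]), an = inorm_init(ch[l]),
                  b = conv3_init(ch[l], ch[l]), bn = inorm_init(ch[l]))
      if (res) blk$proj <- conv1_init(ch[l], 2L * ch[l])
      p$dec[[l]] <- blk
    }
    p$out <- conv1_init(1L, ch[1L], gain = 1)
    p
  })
  structure(list(net_config = config, params = params,
                 structure_name = structure_name,
                 training_curve = data.frame(epoch = integer(), loss = numeric(),
                                             dsc = numeric(), lr = numeric()),
                 seed = as.integer(seed)),
            class = "oto_segmodel")
}

#' @export
print.oto_segmodel <- function(x, ...) {
  np <- n_parameters(x)
  cat(sprintf("<oto_segmodel> '%s': depth %d, base %d channels%s, %d parameters, %d epoch(s) trained\n",
              x$structure_name, x$net_config$depth, x$net_config$base_channels,
              if (x$net_config$residual_blocks) " (residual)" else "",
              as.integer(np), nrow(x$training_curve)))
  invisible(x)
}

#' Total number of learnable parameters of a model
#' @param model an `oto_segmodel`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

# ---- forward / backward -----------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Instance normalization: per-channel standardization over all voxels of
# the instance, with learnable gain/offset. The stabilizer that makes small
# 3D segmentation nets trainable at usable learning rates with batch ~1.
inorm_fwd <- function(x, prm, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = xhat * prm$gamma + prm$beta,
       cache = list(xhat = xhat, inv = inv, gamma = prm$gamma))
}

inorm_bwd <- function(g, cache) {
  ggamma <- rowSums(g * cache$xhat)
  gbeta <- rowSums(g)
  n <- ncol(g)
  gx <- (cache$gamma * cache$inv) *
    (g - gbeta / n - cache$xhat * (ggamma / n))
  list(gx = gx, g = list(gamma = ggamma, beta = gbeta))
}

block_fwd <- function(x, dim, pb, residual) {
  a_pre <- cpp_conv3_fwd(x, pb$a$W, pb$a$b, dim)
  an <- inorm_fwd(a_pre, pb$an)
  a_act <- relu(an$y)
  b_pre <- cpp_conv3_fwd(a_act, pb$b$W, pb$b$b, dim)
  bn <- inorm_fwd(b_pre, pb$bn)
  z <- bn$y
  if (residual) z <- z + (pb$proj$W %*% x + pb$proj$b)
  y <- relu(z)
  list(y = y, cache = list(x = x, an = an, a_act = a_act, bn = bn, z = z,
                           dim = dim))
}

block_bwd <- function(gy, cache, pb, residual) {
  gz <- gy * (cache$z > 0)
  bn_b <- inorm_bwd(gz, cache$bn$cache)
  r_b <- cpp_conv3_bwd(cache$a_act, pb$b$W, bn_b$gx, cache$dim)
  ga_act <- r_b$gx * (cache$an$y > 0)
  an_b <- inorm_bwd(ga_act, cache$an$cache)
  r_a <- cpp_conv3_bwd(cache$x, pb$a$W, an_b$gx, cache$dim)
  gx <- r_a$gx
  g <- list(a = list(W = r_a$gW, b = as.numeric(r_a$gb)), an = an_b$g,
            b = list(W = r_b$gW, b = as.numeric(r_b$gb)), bn = bn_b$g)
  if (residual) {
    g$proj <- list(W = gz %*% t(cache$x), b = rowSums(gz))
    gx <- gx + t(pb$proj$W) %*% gz
  }
  list(g = g, gx = gx)
}

net_fwd <- function(model, x, dim) {
  p <- model$params
  depth <- model$net_config$depth
  res <- model$net_config$residual_blocks
  caches <- list()
  skips <- vector("list", depth - 1L)
  cur <- x
  curdim <- dim
  for (l in seq_len(depth - 1L)) {
    bf <- block_fwd(cur, curdim, p$enc[[l]], res)
    skips[[l]] <- bf$y
    caches[[paste0("enc", l)]] <- bf$cache
    mp <- cpp_maxpool2(bf$y, curdim)
    caches[[paste0("pool", l)]] <- list(idx = mp$idx, n_in = prod(curdim))
    cur <- mp$out
    curdim <- curdim %/% 2L
  }
  bf <- block_fwd(cur, curdim, p$enc[[depth]], res)
  caches$bott <- bf$cache
  cur <- bf$y
  for (l in rev(seq_len(depth - 1L))) {
    small_dim <- curdim
    up_in <- cpp_upsample2(cur, curdim)
    curdim <- curdim * 2L
    up_pre <- cpp_conv3_fwd(up_in, p$dec[[l]]$up$W, p$dec[[l]]$up$b, curdim)
    un <- inorm_fwd(up_pre, p$dec[[l]]$un)
    up_act <- relu(un$y)
    caches[[paste0("up", l)]] <- list(up_in = up_in, un = un,
                                      small_dim = small_dim, dim = curdim)
    bf <- block_fwd(rbind(skips[[l]], up_act), curdim, p$dec[[l]], res)
    caches[[paste0("dec", l)]] <- bf$cache
    cur <- bf$y
  }
  logits <- p$out$W %*% cur + p$out$b
  prob <- 1 / (1 + exp(-logits))
  caches$final_in <- cur
  list(p = prob, caches = caches)
}

net_bwd <- function(model, fw, gp) {
  p <- model$params
  depth <- model$net_config$depth
  res <- model$net_config$residual_blocks
  grads <- list(enc = vector("list", depth), dec = vector("list", depth - 1L))
  glogit <- gp * fw$p * (1 - fw$p)
  grads$out <- list(W = glogit %*% t(fw$caches$final_in),
                    b = sum(glogit))
  gcur <- t(p$out$W) %*% glogit
  gskips <- vector("list", depth - 1L)
  for (l in seq_len(depth - 1L)) {
    bb <- block_bwd(gcur, fw$caches[[paste0("dec", l)]], p$dec[[l]], res)
    grads$dec[[l]] <- bb$g
    c_l <- nrow(fw$caches[[paste0("enc", l)]]$z)
    gskips[[l]] <- bb$gx[seq_len(c_l), , drop = FALSE]
    gup_act <- bb$gx[c_l + seq_len(c_l), , drop = FALSE]
    upc <- fw$caches[[paste0("up", l)]]
    gun <- gup_act * (upc$un$y > 0)
    un_b <- inorm_bwd(gun, upc$un$cache)
    r_up <- cpp_conv3_bwd(upc$up_in, p$dec[[l]]$up$W, un_b$gx, upc$dim)
    grads$dec[[l]]$up <- list(W = r_up$gW, b = as.numeric(r_up$gb))
    grads$dec[[l]]$un <- un_b$g
    gcur <- cpp_upsample2_bwd(r_up$gx, upc$small_dim)
  }
  bb <- block_bwd(gcur, fw$caches$bott, p$enc[[depth]], res)
  grads$enc[[depth]] <- bb$g
  gcur <- bb$gx
  for (l in rev(seq_len(depth - 1L))) {
    pl <- fw$caches[[paste0("pool", l)]]
    gy <- cpp_maxpool2_bwd(pl$idx, gcur, pl$n_in) + gskips[[l]]
    bb <- block_bwd(gy, fw$caches[[paste0("enc", l)]], p$enc[[l]], res)
    grads$enc[[l]] <- bb$g
    gcur <- bb$gx
  }
  grads
}

# ---- parameter-tree arithmetic (for Adam) -----------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, function(t) tree_map(f, t)))
  f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a))) b <- b[names(a)]   # match subtrees by name
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# ---- training / inference ---------------------------------------------------

# Pad spatial dims of a values array up to multiples of `div` with `fill`,
# returning the padded array and the original dims.
pad_to_multiple <- function(vals, div, fill = 0) {
  d <- dim(vals)
  target <- as.integer(ceiling(d / div) * div)
  if (all(target == d)) return(list(values = vals, dim = d, padded = FALSE))
  out <- array(fill, target)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vals
  list(values = out, dim = d, padded = TRUE)
}

#' Train a segmentation model
#'
#' Runs Adam on the soft Dice loss with the step-decay schedule of
#' [lr_schedule()]. Augmentation (intensity jitter, synchronized flips) is
#' re-drawn every epoch per sample from `(seed, epoch, sample)`. The
#' per-epoch mean loss and binarized training Dice are appended to the
#' model's `training_curve`. Deterministic given the seed and a fixed
#' thread count.
#'
#' @param model an untrained or partially trained `oto_segmodel`.
#' @param dataset non-empty list of `list(volume =, label =)` pairs; volumes
#'   must already be preprocessed to `[0, 1]` and share the grid shape.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress every `verbose` epochs (0 = quiet).
#' @return The trained `oto_segmodel`.
#' @export
train <- function(model, dataset, config = train_config(), verbose = 0L) {
  if (!inherits(model, "oto_segmodel")) stop("model must be an oto_segmodel")
  if (length(dataset) == 0L) stop("dataset must be non-empty")
  div <- 2L^(model$net_config$depth - 1L)
  for (s in dataset) {
    rng <- range(s$volume$values)
    if (rng[1] < 0 || rng[2] > 1 + 1e-9) {
      stop("training volumes must be window-rescaled to [0, 1]")
    }
    stop_unless_same_grid(s$volume, s$label, "each volume and its label")
  }
  if (config$epochs == 0L) return(model)

  params <- model$params
  state <- list(t = 0L,
                m = tree_map(function(x) x * 0, params),
                v = tree_map(function(x) x * 0, params))
  n <- length(dataset)
  curve <- model$training_curve
  start_epoch <- nrow(curve)

  for (e in seq_len(config$epochs) - 1L) {
    epoch <- start_epoch + e
    lr <- lr_schedule(epoch, config)
    order <- with_seed(derive_seed(config$seed, epoch, 777L), sample.int(n))
    losses <- numeric(n)
    dscs <- numeric(n)
    acc <- NULL
    acc_n <- 0L
    model$params <- params
    for (pos in seq_len(n)) {
      i <- order[pos]
      aug <- augment(dataset[[i]]$volume, dataset[[i]]$label, config$augment,
                     epoch = epoch, sample = i)
      pv <- pad_to_multiple(aug$volume$values, div, fill = 0)
      pl <- pad_to_multiple(aug$label$mask, div, fill = 0L)
      x <- matrix(as.numeric(pv$values), nrow = 1L)
      r <- as.numeric(pl$values)
      fw <- net_fwd(model, x, dim(pv$values))
      loss <- soft_dice_loss(fw$p, r)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      losses[pos] <- loss
      pb <- as.numeric(fw$p) >= 0.5
      dscs[pos] <- dice_counts(sum(pb & r == 1), sum(pb), sum(r == 1))
      gp <- matrix(soft_dice_grad(as.numeric(fw$p), r), nrow = 1L)
      g <- net_bwd(model, fw, gp)
      acc <- if (is.null(acc)) g else tree_map2(`+`, acc, g)
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size || pos == n) {
        g_mean <- tree_map(function(x) x / acc_n, acc)
        st <- adam_step(params, g_mean, state, lr)
        params <- st$params
        state <- st$state
        model$params <- params
        acc <- NULL
        acc_n <- 0L
      }
    }
    curve <- rbind(curve, data.frame(epoch = epoch, loss = mean(losses),
                                     dsc = mean(dscs), lr = lr))
    if (verbose > 0L && (epoch %% verbose == 0L)) {
      message(sprintf("epoch %4d  lr %.2e  loss %.4f  dsc %.4f",
                      epoch, lr, mean(losses), mean(dscs)))
    }
  }
  model$params <- params
  model$training_curve <- curve
  model
}

#' Predict per-voxel foreground probability
#'
#' Runs the model on a preprocessed (windowed, side-standardized, resampled)
#' volume. Grids not divisible by the network's pooling factor are
#' zero-padded and cropped back. Deterministic.
#'
#' @param object an `oto_segmodel`.
#' @param volume an [oto_volume()] with values in `[0, 1]`.
#' @param ... unused.
#' @return An [oto_volume()] of probabilities on the input grid.
#' @export
predict.oto_segmodel <- function(object, volume, ...) {
  div <- 2L^(object$net_config$depth - 1L)
  pv <- pad_to_multiple(volume$values, div, fill = 0)
  x <- matrix(as.numeric(pv$values), nrow = 1L)
  fw <- net_fwd(object, x, dim(pv$values))
  prob <- array(as.numeric(fw$p), dim(pv$values))
  d <- pv$dim
  prob <- prob[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  oto_volume(prob, spacing = volume$spacing, origin = volume$origin,
             orientation = volume$orientation)
}

#' Threshold a probability volume into a label map
#'
#' @param probabilities an [oto_volume()] with values in `[0, 1]`.
#' @param threshold scalar in `[0, 1]`; voxels with `p >= threshold` become
#'   foreground.
#' @return An [oto_labelmap()].
#' @export
binarize <- function(probabilities, threshold = 0.5) {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  oto_labelmap((probabilities$values >= threshold) * 1L,
               spacing = probabilities$spacing, origin = probabilities$origin,
               orientation = probabilities$orientation)
}

#' k-fold cross-validation of the segmentation backend
#'
#' Partitions the dataset into `config$folds` disjoint, seed-reproducible
#' parts; trains on the complement of each part and evaluates predictions
#' on the held-out part with [evaluate_pair()].
#'
#' @param dataset list of `list(volume =, label =)` pairs (preprocessed).
#' @param net a [net_config()].
#' @param config a [train_config()].
#' @param threshold binarization threshold for evaluation.
#' @return A list with `folds` (per-fold data.frame of case metrics),
#'   `fold_means`, and `mean` (grand mean across folds).
#' @export
cross_validate <- function(dataset, net, config, threshold = 0.5) {
  n <- length(dataset)
  k <- config$folds
  if (k > n) stop("folds (", k, ") exceed dataset size (", n, ")")
  if (k < 2L) stop("cross-validation needs folds >= 2")
  assign_fold <- with_seed(derive_seed(config$seed, 424242L),
                           sample(rep(seq_len(k), length.out = n)))
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(assign_fold == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    model <- build_model(net, seed = derive_seed(config$seed, f),
                         structure_name = "cv")
    model <- train(model, dataset[train_idx], config)
    rows <- lapply(test_idx, function(i) {
      t0 <- proc.time()[["elapsed"]]
      pred <- binarize(predict(model, dataset[[i]]$volume), threshold)
      secs <- proc.time()[["elapsed"]] - t0
      rep <- evaluate_pair(pred, dataset[[i]]$label, seconds = secs)
      cbind(data.frame(fold = f, case = i), as.data.frame(rep))
    })
    fold_reports[[f]] <- do.call(rbind, rows)
  }
  all_rows <- do.call(rbind, fold_reports)
  fold_means <- stats::aggregate(cbind(dsc, ahd_mm, volsim_pct) ~ fold,
                                 data = all_rows, FUN = mean, na.action = NULL,
                                 na.rm = TRUE)
  list(folds = fold_reports, fold_means = fold_means,
       mean = colMeans(all_rows[, c("dsc", "ahd_mm", "volsim_pct")],
                       na.rm = TRUE))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint containing a schema tag, the architecture config,
#' structure name, weights and training curve.
#'
#' @param model an `oto_segmodel`.
#' @param path checkpoint path (conventionally `.ckpt`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `oto_segmodel`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(schema = "otoseg-checkpoint-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "otoseg-checkpoint-1")) {
    stop("not an otoseg checkpoint (schema mismatch): ", path)
  }
  obj$model
}
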