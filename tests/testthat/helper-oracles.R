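# Independent pure-R brute-force oracles used to validate the production
# (Rcpp) implementations. Deliberately naive: enumeration and double loops.

neighbor_offsets_r <- function(connectivity) {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
  if (connectivity == 6) o <- o[abs(o$dx) + abs(o$dy) + abs(o$dz) == 1, ]
  as.matrix(o)
}

# Level-by-level flood fill of `eligible` from `seed` (seed returned as-is),
# at most max_iter rounds of one connectivity shell each.
oracle_flood <- function(seed, eligible, connectivity = 6, max_iter = Inf) {
  d <- dim(seed)
  offs <- neighbor_offsets_r(connectivity)
  out <- seed == 1
  frontier <- which(out)
  it <- 0
  while (length(frontier) > 0 && it < max_iter) {
    it <- it + 1
    nxt <- integer(0)
    for (lin in frontier) {
      idx <- arrayInd(lin, d)
      for (r in seq_len(nrow(offs))) {
        ni <- idx[1] + offs[r, 1]; nj <- idx[2] + offs[r, 2]; nk <- idx[3] + offs[r, 3]
        if (ni < 1 || nj < 1 || nk < 1 || ni > d[1] || nj > d[2] || nk > d[3]) next
        if (!out[ni, nj, nk] && eligible[ni, nj, nk] == 1) {
          out[ni, nj, nk] <- TRUE
          nxt <- c(nxt, lin3_r(ni, nj, nk, d))
        }
      }
    }
    frontier <- nxt
  }
  out * 1L
}

lin3_r <- function(i, j, k, d) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)

# Boundary voxels: mask voxels with a face neighbor outside the mask
# (outside the grid counts as outside the mask).
oracle_boundary <- function(mask) {
  d <- dim(mask)
  offs <- neighbor_offsets_r(6)
  out <- array(FALSE, d)
  for (lin in which(mask == 1)) {
    idx <- arrayInd(lin, d)
    for (r in seq_len(nrow(offs))) {
      ni <- idx[1] + offs[r, 1]; nj <- idx[2] + offs[r, 2]; nk <- idx[3] + offs[r, 3]
      outside <- ni < 1 || nj < 1 || nk < 1 || ni > d[1] || nj > d[2] || nk > d[3]
      if (outside || mask[ni, nj, nk] == 0) {
        out[lin] <- TRUE
        break
      }
    }
  }
  out
}

oracle_boundary_coords <- function(label) {
  b <- oracle_boundary(label$mask)
  idx <- which(b, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, label$spacing, `*`), 2, label$origin, `+`)
}

# O(|A| * |B|) double-loop average Hausdorff distance over boundary voxels.
oracle_ahd <- function(a, b) {
  A <- oracle_boundary_coords(a)
  B <- oracle_boundary_coords(b)
  dmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2 +
                 (Q[, 3] - P[i, 3])^2))
    }, numeric(1))
  }
  (mean(dmin(A, B)) + mean(dmin(B, A))) / 2
}

oracle_dice <- function(a, b) {
  na <- sum(a$mask == 1); nb <- sum(b$mask == 1)
  if (na + nb == 0) return(1)
  2 * sum(a$mask == 1 & b$mask == 1) / (na + nb)
}

# Random blobby mask on a small grid: union of 1-3 random ellipsoids.
random_mask <- function(d = c(10, 10, 10), spacing = c(1, 1, 1), n_blobs = NULL) {
  m <- array(FALSE, d)
  n_blobs <- if (is.null(n_blobs)) sample(1:3, 1) else n_blobs
  coords <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  for (b in seq_len(n_blobs)) {
    c0 <- runif(3, 2, d - 1)
    r0 <- runif(3, 1, d / 3)
    inside <- ((coords$i - c0[1]) / r0[1])^2 + ((coords$j - c0[2]) / r0[2])^2 +
      ((coords$k - c0[3]) / r0[3])^2 <= 1
    m[as.matrix(coords[inside, ])] <- TRUE
  }
  if (!any(m)) m[sample(length(m), 2)] <- TRUE
  oto_labelmap(m * 1L, spacing = spacing)
}

# Minimal independent NIfTI-1 writer with an arbitrary affine (float32
# data), used to test reading + canonical reorientation against files the
# package writer cannot produce.
write_nifti_with_affine <- function(path, arr, affine) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(arr)
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(348L, 4); writeBin(raw(36), con)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)
  wf(c(0, 0, 0)); wi(c(0L, 16L, 32L, 0L), 2)
  wf(c(1, sp, 1, 1, 1, 1)); wf(352); wf(c(1, 0))
  wi(0L, 2); wi(c(0L, 2L), 1); wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)
  writeBin(raw(104), con)
  wi(c(0L, 1L), 2); wf(rep(0, 6))
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  writeBin(raw(16), con)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}
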