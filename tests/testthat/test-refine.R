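vol_from <- function(arr, spacing = c(1, 1, 1)) {
  oto_volume(arr, spacing = spacing)
}
lab_from <- function(arr, spacing = c(1, 1, 1)) {
  oto_labelmap(arr * 1L, spacing = spacing)
}
soft_spec <- function(...) {
  structure_spec("inner_ear", hu_range(-400, 550), ...)
}

test_that("hu_constrained_refine shrinks, grows and is a fixed point when converged", {
  # 5x5x5: a 3-voxel in-range line with only its middle voxel labeled
  hu <- array(1000, c(5, 5, 5))
  hu[2:4, 3, 3] <- 100
  lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
  out <- hu_constrained_refine(lab_from(lab), vol_from(hu), soft_spec())
  expect_identical(which(out$mask == 1L), which(hu == 100))
  # fixed point: refining the refined label changes nothing
  out2 <- hu_constrained_refine(out, vol_from(hu), soft_spec())
  expect_identical(out2$mask, out$mask)
  # pure shrink: labeled voxel out of range with no in-range neighbors
  lab2 <- array(0L, c(5, 5, 5)); lab2[1, 1, 1] <- 1L
  out3 <- hu_constrained_refine(lab_from(lab2), vol_from(hu), soft_spec())
  expect_equal(sum(out3$mask), 0)
  # growth cap: max_grow_iterations = 0 is shrink-only
  out4 <- hu_constrained_refine(lab_from(lab), vol_from(hu),
                                soft_spec(max_grow_iterations = 0L))
  expect_identical(out4$mask, lab)
})

test_that("hu_constrained_refine equals the seeded flood-fill oracle", {
  set.seed(101)
  for (i in 1:10) {
    d <- c(8, 8, 8)
    hu <- array(sample(c(100, 1000), prod(d), replace = TRUE, prob = c(0.4, 0.6)), d)
    lab <- array(as.integer(runif(prod(d)) < 0.1), d)
    for (conn in c("faces", "all_neighbors")) {
      spec <- soft_spec(grow_connectivity = conn)
      got <- hu_constrained_refine(lab_from(lab), vol_from(hu), spec)
      inr <- (hu >= -400 & hu <= 550) * 1L
      want <- oracle_flood(lab * inr, inr,
                           connectivity = if (conn == "faces") 6 else 26)
      expect_identical(got$mask, array(as.integer(want), d))
      # idempotence
      again <- hu_constrained_refine(got, vol_from(hu), spec)
      expect_identical(again$mask, got$mask)
    }
  }
})

test_that("enlarging the HU range never shrinks the refined set", {
  set.seed(55)
  for (i in 1:8) {
    d <- c(8, 8, 8)
    hu <- array(runif(prod(d), -800, 2000), d)
    lab <- array(as.integer(runif(prod(d)) < 0.15), d)
    narrow <- hu_constrained_refine(lab_from(lab), vol_from(hu),
                                    structure_spec("inner_ear", hu_range(0, 400)))
    wide <- hu_constrained_refine(lab_from(lab), vol_from(hu),
                                  structure_spec("inner_ear", hu_range(-200, 800)))
    expect_true(all(wide$mask[narrow$mask == 1L] == 1L))
  }
})

test_that("remove_islands keeps the right components", {
  d <- c(10, 10, 10)
  m <- array(0L, d)
  m[2:6, 2:5, 2:6] <- 1L                 # 100 voxels
  m[9, 9, c(2, 4)] <- 1L                 # two isolated voxels
  big_only <- remove_islands(lab_from(m), list(type = "min_size", min_size = 5))
  expect_equal(sum(big_only$mask), 100)
  kl <- remove_islands(lab_from(m), list(type = "keep_largest"))
  expect_equal(sum(kl$mask), 100)
  # keep_largest output is a single connected component
  cc <- otoseg:::cpp_cc_label(as.integer(kl$mask), d, 26L)
  expect_equal(max(cc), 1)
  # diagonal contact makes ONE component under 26-connectivity
  m2 <- array(0L, d); m2[2, 2, 2] <- 1L; m2[3, 3, 3] <- 1L
  out2 <- remove_islands(lab_from(m2), list(type = "min_size", min_size = 2))
  expect_equal(sum(out2$mask), 2)
  # single component passes through keep_largest unchanged; empty stays empty
  single <- array(0L, d); single[4:6, 4:6, 4:6] <- 1L
  expect_identical(remove_islands(lab_from(single))$mask, single)
  empty <- lab_from(array(0L, d))
  expect_equal(sum(remove_islands(empty)$mask), 0)
})

test_that("remove_islands never adds voxels and breaks ties deterministically", {
  set.seed(77)
  for (i in 1:6) {
    m <- random_mask(c(9, 9, 9))
    out <- remove_islands(m)
    expect_lte(sum(out$mask), sum(m$mask))
    expect_true(all(m$mask[out$mask == 1L] == 1L))
  }
  # two equal-size components: the one containing the smallest linear index wins
  m <- array(0L, c(10, 4, 4))
  m[1:2, 1, 1] <- 1L
  m[9:10, 4, 4] <- 1L
  out <- remove_islands(lab_from(m), list(type = "keep_largest"))
  expect_identical(which(out$mask == 1L), which(m == 1L)[1:2])
})

test_that("refine_pipeline is a no-op under an unbounded spec on an isotropic grid", {
  set.seed(91)
  m <- random_mask(c(8, 8, 8), spacing = c(0.25, 0.25, 0.25))
  hu <- array(runif(8^3, -500, 2000), c(8, 8, 8))
  v <- vol_from(hu, spacing = c(0.25, 0.25, 0.25))
  spec <- structure_spec("inner_ear", hu_range(-1024, 3071),
                         island_policy = list(type = "min_size", min_size = 1),
                         max_grow_iterations = 0L)
  out <- refine_pipeline(m, v, spec, working_spacing = 0.25,
                         pre_island_min_size = 1L)
  expect_identical(out$mask, m$mask)
  # empty input stays empty
  empty <- oto_labelmap(array(0L, c(8, 8, 8)), spacing = c(0.25, 0.25, 0.25))
  expect_equal(sum(refine_pipeline(empty, v, spec, 0.25)$mask), 0)
})

test_that("refine_pipeline improves a corrupted phantom label", {
  ph <- generate_phantom(phantom_config(seed = 14))
  truth <- ph$labels$inner_ear
  corrupted <- corrupt_label(truth, list(erode_voxels = 1, noise_flip_rate = 0.005),
                             seed = 3)
  before <- dice(corrupted, truth)
  refined <- refine_pipeline(corrupted, ph$volume, soft_spec(), 0.25)
  after <- dice(refined, truth)
  expect_lt(before, 1)
  expect_gt(after, before)
})

test_that("derive_otic_capsule recovers the constructed shell exactly", {
  ph <- generate_phantom(phantom_config(seed = 6, noise_sd = 0))
  caps <- derive_otic_capsule(ph$labels$inner_ear, ph$volume)
  expect_identical(caps$mask, ph$labels$otic_capsule$mask)
  expect_equal(sum(caps$mask * ph$labels$inner_ear$mask), 0)  # disjoint
})

test_that("derive_otic_capsule degenerate cases and the first-shell contract", {
  # 5^3 crafted grid: center fluid voxel, compact at exactly two face
  # neighbors, trabecular elsewhere
  hu <- array(300, c(5, 5, 5))
  hu[3, 3, 3] <- 20
  hu[2, 3, 3] <- 1500
  hu[3, 4, 3] <- 1500
  hu[1, 3, 3] <- 1500  # compact, face-connected to [2,3,3] but not to inner ear
  inner <- array(0L, c(5, 5, 5)); inner[3, 3, 3] <- 1L
  shell0 <- derive_otic_capsule(lab_from(inner), vol_from(hu), max_iterations = 0L)
  expect_identical(which(shell0$mask == 1L),
                   sort(as.integer(c(lin3_r(2, 3, 3, c(5, 5, 5)),
                                     lin3_r(3, 4, 3, c(5, 5, 5))))))
  shell1 <- derive_otic_capsule(lab_from(inner), vol_from(hu), max_iterations = 1L)
  expect_equal(sum(shell1$mask), 3)  # growth reaches [1,3,3]
  # inner ear bordered everywhere by trabecular bone: no capsule
  hu2 <- array(300, c(5, 5, 5)); hu2[3, 3, 3] <- 20
  none <- derive_otic_capsule(lab_from(inner), vol_from(hu2))
  expect_equal(sum(none$mask), 0)
  empty <- lab_from(array(0L, c(5, 5, 5)))
  expect_warning(res <- derive_otic_capsule(empty, vol_from(hu)), "empty")
  expect_equal(sum(res$mask), 0)
})
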