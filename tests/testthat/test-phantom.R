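test_that("generation is deterministic in (spec, group, seed)", {
  spec <- tiny_spec()
  g1 <- generate_sample(spec, "control", 99)
  g2 <- generate_sample(spec, "control", 99)
  expect_identical(unclass(g1$sample$channels$edu),
                   unclass(g2$sample$channels$edu))
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_sample(spec, "control", 100)
  expect_false(identical(unclass(g1$sample$channels$edu),
                         unclass(g3$sample$channels$edu)))
})

test_that("with no foci and no diffuse signal the EdU channel is pure noise", {
  spec <- tiny_spec(lambda = 0, noise_sd = 500)
  g <- generate_sample(spec, "control", 7)
  edu <- as.numeric(g$sample$channels$edu)
  # half-normal after clipping at 0: mean = sd * sqrt(2/pi) on ~half the
  # voxels; just require the mean to sit within 3 sd of the noise scale
  expect_lt(mean(edu), 500 * 3)
  expect_equal(g$truth$niches$focus_count, 0L)
  expect_equal(g$truth$niches$focus_voxels, 0L)
})

test_that("focus counts recover the Poisson rate over repeated seeds", {
  spec <- tiny_spec(lambda = 1e-4, blur_um = 0, noise_sd = 0)
  region_vox <- sum(phantom_niche_region(spec, "anterior"))
  lamV <- 1e-4 * region_vox * voxel_volume(voxel_geometry(spec$pixel_size_um))
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(s)
    generate_sample(spec, "control", 5000 + s)$truth$niches$focus_count,
    numeric(1))
  expect_lt(abs(mean(counts) - lamV), 3 * sqrt(lamV) / sqrt(n_rep))
})

test_that("ground truth is internally consistent", {
  spec <- tiny_spec(lambda = 3e-4)
  g <- generate_sample(spec, "control", 55)
  tr <- g$truth
  expect_gte(tr$niches$focus_voxels, 0L)
  expect_lte(tr$niches$focus_voxels,
             tr$niches$focus_count * length(optquant:::sphere_offsets(7.5, 5)))
  expect_equal(tr$brain_voxels, sum(phantom_brain_mask(spec)))
  expect_equal(unname(tr$parenchyma_voxels), c(0L, 0L))  # control: no diffuse
})

test_that("an empty niche region is rejected by name", {
  flat <- c(control = 1, "1dpl" = 1, "3dpl" = 1, "7dpl" = 1)
  spec <- tiny_spec()
  spec$niches[[1]]$dv_range_um <- c(1000, 1001)  # outside the brain
  expect_error(generate_sample(spec, "control", 1), "anterior")
})

test_that("structure analysis recovers ground-truth niche volume under benign settings", {
  # bright foci, no blur, no noise: every focus voxel lands in a non-black
  # bin and nothing else does, so recovery is exact
  spec <- tiny_spec(lambda = 2e-4, peak = 40000, blur_um = 0, noise_sd = 0)
  g <- generate_sample(spec, "control", 77)
  reg <- phantom_niche_region(spec, "anterior")
  ap_idx <- range(which(apply(reg, 1, any)))
  roi <- box_roi(c(0, dim(reg)[1]), c(0, dim(reg)[2]), c(0, dim(reg)[3]))
  res <- structure_volume(g$sample, roi = roi)
  expect_equal(res$pixel_count, g$truth$niches$focus_voxels)

  # with mild blur and noise the recovery degrades gracefully (within 30%)
  spec2 <- tiny_spec(lambda = 2e-4, peak = 40000, blur_um = 2, noise_sd = 300)
  g2 <- generate_sample(spec2, "control", 77)
  res2 <- structure_volume(g2$sample, roi = roi)
  expect_lt(abs(res2$pixel_count - g2$truth$niches$focus_voxels),
            0.3 * g2$truth$niches$focus_voxels + 30)
})

test_that("cohorts are reproducible with the requested group sizes", {
  spec <- tiny_spec()
  npg <- c(control = 2L, "1dpl" = 2L, "3dpl" = 2L, "7dpl" = 2L)
  c1 <- generate_cohort(spec, npg, seed = 3)
  c2 <- generate_cohort(spec, npg, seed = 3)
  expect_equal(length(c1$samples), 8L)
  expect_equal(table(c1$manifest$group)[names(npg)],
               table(rep(names(npg), npg))[names(npg)])
  expect_identical(unclass(c1$samples[[3]]$channels$edu),
                   unclass(c2$samples[[3]]$channels$edu))
  expect_false(anyDuplicated(c1$manifest$sample_id) > 0)

  # default cohort mirrors the injury time-course group sizes (5, 4, 4, 5)
  expect_equal(sum(eval(formals(generate_cohort)$n_per_group)), 18L)
})

test_that("cohort files on disk round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec()
  coh <- generate_cohort(spec, c(control = 2L, "1dpl" = 2L), seed = 9,
                         dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  man <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4L)
  samples <- load_cohort(man)
  expect_identical(unclass(samples[["control_01"]]$channels$edu),
                   unclass(coh$samples[["control_01"]]$channels$edu))
})

test_that("brain segmentation of the autofluorescence channel finds the ellipsoid", {
  spec <- tiny_spec(noise_sd = 400)
  g <- generate_sample(spec, "control", 123)
  m <- segment_brain(g$sample$channels$autofluorescence, threshold = "otsu",
                     largest_component = TRUE)
  truth <- g$truth$brain_voxels
  expect_lt(abs(sum(m) - truth) / truth, 0.10)
})
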