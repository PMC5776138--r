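test_that("structure volume counts the box's voxels in the chosen bins", {
  arr <- array(0L, c(10, 8, 8))
  smp <- make_sample(arr)
  roi <- box_roi(c(0, 10), c(0, 8), c(0, 8))
  expect_equal(structure_volume(smp, roi = roi)$volume_um3, 0)

  arr[1, 1, 1:10 %% 8 + 1] <- 5000L  # fills some voxels
  arr <- array(0L, c(10, 8, 8)); arr[1:10] <- 0L
  arr[2, 3, 1:5] <- 5000L; arr[4, 5, 1:5] <- 5000L  # 10 voxels in bin 1
  res <- structure_volume(make_sample(arr), roi = roi)
  expect_equal(res$pixel_count, 10L)
  expect_equal(res$volume_um3, 1250)

  expect_error(structure_volume(smp, roi = box_roi(c(0, 11), c(0, 8), c(0, 8))),
               "exceeds")
  expect_error(structure_volume(smp, roi = roi, bins_used = integer(0)),
               "non-empty")
  expect_error(structure_volume(smp, roi = roi, bins_used = 0), "non-empty")
})

test_that("all-15-bin structure volume equals brute-force thresholding at 4096", {
  set.seed(12)
  for (r in 1:8) {
    arr <- array(sample(0:65535, 16^3, TRUE), c(16, 16, 16))
    smp <- make_sample(arr, pixel_size_um = 4.5)
    roi <- box_roi(c(2, 13), c(0, 16), c(5, 16))
    res <- structure_volume(smp, roi = roi)
    sub <- arr[3:13, 1:16, 6:16]
    expect_equal(res$pixel_count, sum(sub >= 4096))
    expect_equal(res$volume_um3, sum(sub >= 4096) * 4.5^3)
    # restricted bin subset equals counting within the subset's edges
    res3 <- structure_volume(smp, roi = roi, bins_used = 1:3)
    expect_equal(res3$pixel_count, sum(sub >= 4096 & sub < 16384))
  }
})

test_that("slice sampling takes ceil(depth/stride) sections from the interval start", {
  d <- c(100L, 6L, 6L)
  arr <- array(5000L, d)
  smp <- make_sample(arr)
  full <- matrix(TRUE, 6, 6)
  idx <- seq.int(0L, 99L, by = 5L)
  masks <- stats::setNames(rep(list(full), length(idx)), as.character(idx))
  n <- niche_roi(c(0, 100), masks, stride = 5)
  res <- slice_volume(smp, niche = n, bins_used = 1:15)
  expect_equal(res$pixel_count, 20L * 36L)  # exactly 20 sampled sections

  # empty masks give zero
  n0 <- niche_roi(c(0, 100), stats::setNames(rep(list(!full), length(idx)),
                                             as.character(idx)), 5)
  expect_equal(slice_volume(smp, niche = n0)$volume_um3, 0)

  # a sampled slice without a mask is an error
  n_missing <- niche_roi(c(0, 100), masks[-2], stride = 5)
  expect_error(slice_volume(smp, niche = n_missing), "slice 5 has no mask")

  # extrapolation multiplies by the stride
  rex <- slice_volume(smp, niche = n, bins_used = 1:15, extrapolate = TRUE)
  expect_equal(rex$pixel_count, res$pixel_count * 5L)
})

test_that("stride-1 full-mask slice analysis equals structure analysis", {
  set.seed(13)
  arr <- array(sample(0:65535, 12 * 7 * 9, TRUE), c(12, 7, 9))
  smp <- make_sample(arr)
  roi <- box_roi(c(2, 10), c(0, 7), c(0, 9))
  idx <- 2:9
  masks <- stats::setNames(rep(list(matrix(TRUE, 7, 9)), 8), as.character(idx))
  n <- niche_roi(c(2, 10), masks, stride = 1)
  sv <- structure_volume(smp, roi = roi)
  sl <- slice_volume(smp, niche = n, bins_used = 1:15)
  expect_equal(sl$pixel_count, sv$pixel_count)
  expect_equal(sl$volume_um3, sv$volume_um3)
})

test_that("volume is monotone in bins_used, ROI size and mask size", {
  set.seed(14)
  arr <- array(sample(0:65535, 10 * 8 * 8, TRUE), c(10, 8, 8))
  smp <- make_sample(arr)
  small <- box_roi(c(2, 6), c(2, 6), c(2, 6))
  big <- box_roi(c(0, 10), c(0, 8), c(0, 8))
  expect_lte(structure_volume(smp, roi = small)$volume_um3,
             structure_volume(smp, roi = big)$volume_um3)
  expect_lte(structure_volume(smp, roi = big, bins_used = 1:3)$volume_um3,
             structure_volume(smp, roi = big, bins_used = 1:15)$volume_um3)

  idx <- c(0L, 5L)
  m_small <- matrix(FALSE, 8, 8); m_small[3:5, 3:5] <- TRUE
  m_big <- matrix(TRUE, 8, 8)
  n_small <- niche_roi(c(0, 10), stats::setNames(list(m_small, m_small),
                                                 c("0", "5")), 5)
  n_big <- niche_roi(c(0, 10), stats::setNames(list(m_big, m_big),
                                               c("0", "5")), 5)
  expect_lte(slice_volume(smp, niche = n_small)$volume_um3,
             slice_volume(smp, niche = n_big)$volume_um3)
})

test_that("diffuse parenchymal signal moves structure volume but spares the niche", {
  # two phantoms differing only in the diffuse component: niche-restricted
  # slice volume barely moves while whole-hemisphere structure volume jumps
  flat <- c(control = 1, "1dpl" = 1, "3dpl" = 1, "7dpl" = 1)
  base <- tiny_spec(lambda = 2e-4, peak = 12000, blur_um = 3, noise_sd = 600)
  lesioned <- base
  lesioned$parenchyma_amplitude <- c(control = 0, "1dpl" = 9000,
                                     "3dpl" = 0, "7dpl" = 0)
  lesioned$parenchyma_ap_span_um <- c(0, 200)

  niche <- phantom_niche_roi(base, "anterior", "lesioned", stride = 5)
  hemi <- phantom_box_roi(base, "lesioned_hemisphere")

  g_ctrl <- generate_sample(base, "control", 31)
  g_les <- generate_sample(lesioned, "1dpl", 31)
  sv_ctrl <- structure_volume(g_ctrl$sample, roi = hemi)$pixel_count
  sv_les <- structure_volume(g_les$sample, roi = hemi)$pixel_count
  sl_ctrl <- slice_volume(g_ctrl$sample, niche = niche)$pixel_count
  sl_les <- slice_volume(g_les$sample, niche = niche)$pixel_count

  expect_gt(sv_les, sv_ctrl * 3)             # hemisphere measure explodes
  added <- sv_les - sv_ctrl
  expect_lt(abs(sl_les - sl_ctrl), added * 0.05)  # niche measure barely moves
})
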