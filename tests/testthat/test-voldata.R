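test_that("TIFF round trip is bit-exact and preserves extents", {
  set.seed(11)
  v <- rand_volume(c(10, 64, 64))
  expect_identical(dim(v), c(10L, 64L, 64L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_channel(v, path)
  back <- read_channel(path, voxel_geometry(5))
  expect_identical(unclass(back), unclass(v))

  z <- channel_volume(array(0L, c(3, 4, 5)))
  pz <- withr::local_tempfile(fileext = ".tif")
  write_channel(z, pz)
  expect_true(all(read_channel(pz, voxel_geometry(5)) == 0L))
})

test_that("8-bit stacks are upscaled by 257 so 255 maps to 65535", {
  path <- withr::local_tempfile(fileext = ".tif")
  page <- matrix(c(0L, 255L, 128L, 7L), 2, 2)
  tiff::writeTIFF(page / 255, path, bits.per.sample = 8L)
  v <- read_channel(path, voxel_geometry(5))
  expect_identical(as.integer(v[1, , ]), c(0L, 255L, 128L, 7L) * 257L)
  expect_equal(max(v), 65535L)
})

test_that("non-grayscale pages are rejected with the page named", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), path)
  expect_error(read_channel(path, voxel_geometry(5)), "page 1")
})

test_that("channel_volume validates domain and shape", {
  expect_error(channel_volume(array(-1L, c(2, 2, 2))), "outside")
  expect_error(channel_volume(array(70000L, c(2, 2, 2))), "outside")
  expect_error(channel_volume(matrix(0L, 2, 2)), "3-D")
  expect_s3_class(channel_volume(array(65535L, c(1, 1, 1))), "channel_volume")
})

test_that("manifest loading validates ids, groups and columns", {
  dir <- withr::local_tempdir()
  # touch the channel files so path validation passes
  mk <- function(n) {
    f <- file.path(dir, n)
    write_channel(channel_volume(array(0L, c(2, 2, 2))), f)
    n
  }
  rows <- data.frame(
    sample_id = c("a", "b"), group = c("control", "1dpl"),
    pixel_size_um = 5,
    edu_path = c(mk("a_e.tif"), mk("b_e.tif")),
    autofluorescence_path = c(mk("a_a.tif"), mk("b_a.tif")))
  man_path <- file.path(dir, "manifest.csv")
  write.csv(rows, man_path, row.names = FALSE)
  man <- load_manifest(man_path)
  expect_equal(nrow(man), 2L)

  rows2 <- rows; rows2$sample_id <- c("a", "a")
  write.csv(rows2, man_path, row.names = FALSE)
  expect_error(load_manifest(man_path), "duplicate sample_id.*a")

  write.csv(rows, man_path, row.names = FALSE)
  expect_error(load_manifest(man_path, groups = c("control", "7dpl")),
               "unknown group")
  write.csv(rows[, -2], man_path, row.names = FALSE)
  expect_error(load_manifest(man_path), "missing columns.*group")

  # 4 groups x 5 samples -> 20 records in 4 labels
  big <- do.call(rbind, lapply(c("control", "1dpl", "3dpl", "7dpl"), function(g)
    data.frame(sample_id = paste0(g, 1:5), group = g, pixel_size_um = 4.5,
               edu_path = "a_e.tif", autofluorescence_path = "a_a.tif")))
  write.csv(big, man_path, row.names = FALSE)
  man <- load_manifest(man_path)
  expect_equal(nrow(man), 20L)
  expect_equal(length(unique(man$group)), 4L)
})

test_that("horizontal maximum projection matches a brute-force oracle", {
  arr <- array(0L, c(6, 8, 7))
  arr[4, 8, 6] <- 900L
  p <- max_project_horizontal(channel_volume(arr))
  expect_equal(p[4, 6], 900L)
  expect_equal(sum(p), 900L)

  cst <- channel_volume(array(123L, c(3, 4, 5)))
  expect_true(all(max_project_horizontal(cst) == 123L))

  set.seed(7)
  v <- rand_volume(c(5, 6, 7))
  p <- max_project_horizontal(v)
  for (i in 1:5) for (k in 1:7) {
    expect_equal(p[i, k], max(v[i, , k]))
  }
})

test_that("projection is idempotent under D-V duplication and commutes with monotone maps", {
  set.seed(8)
  v <- rand_volume(c(4, 3, 5))
  # duplicate along D-V explicitly
  arr <- array(0L, c(4, 6, 5))
  arr[, 1:3, ] <- unclass(v); arr[, 4:6, ] <- unclass(v)
  expect_identical(max_project_horizontal(channel_volume(arr)),
                   max_project_horizontal(v))
  # strictly increasing remap on [0, 65535] (shape-preserving)
  f <- function(x) {
    y <- x %/% 2L + 10L
    y[y > 65535L] <- 65535L
    y
  }
  lhs <- max_project_horizontal(channel_volume(f(unclass(v))))
  rhs <- f(max_project_horizontal(v))
  expect_identical(lhs, rhs)
})

test_that("box and niche ROIs enforce their invariants", {
  expect_error(box_roi(c(2, 2), c(0, 1), c(0, 1)), "start < stop")
  expect_error(box_roi(c(-1, 2), c(0, 1), c(0, 1)), "start < stop")
  r <- box_roi(c(0, 10), c(2, 5), c(1, 3))
  expect_s3_class(r, "box_roi")

  m <- matrix(TRUE, 4, 4)
  expect_error(niche_roi(c(0, 10), list("12" = m)), "inside the ap interval")
  expect_error(niche_roi(c(0, 10), list("2" = m), stride = 0), "positive integer")
  expect_error(niche_roi(c(0, 10), list("2" = m, "4" = matrix(TRUE, 3, 3))),
               "shape differs")
  expect_s3_class(niche_roi(c(0, 10), list("0" = m, "5" = m), 5), "niche_roi")
})

test_that("ROI JSON round trip works for box and niche ROIs", {
  dir <- withr::local_tempdir()
  bp <- file.path(dir, "box.json")
  jsonlite::write_json(list(ap = c(0, 5), dv = c(1, 4), lr = c(2, 6)), bp,
                       auto_unbox = FALSE)
  b <- read_box_roi(bp)
  expect_equal(b$ap, c(0L, 5L))
  expect_equal(b$lr, c(2L, 6L))

  mask <- matrix(c(rep(1, 6), rep(0, 10)), 4, 4)
  tiff::writeTIFF(mask, file.path(dir, "m0.tif"), bits.per.sample = 8L)
  jsonlite::write_json(list(ap = c(0, 5), stride = 5,
                            masks = list("0" = "m0.tif")),
                       file.path(dir, "niche.json"), auto_unbox = TRUE)
  n <- read_niche_roi(file.path(dir, "niche.json"))
  expect_equal(n$stride, 5L)
  expect_equal(sum(n$masks[["0"]]), 6)
})
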