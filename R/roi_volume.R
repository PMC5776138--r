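#' Structure analysis: EdU volume in a full-depth box ROI
#'
#' Every voxel of the box, across its full A-P depth, is assigned to one of
#' the 16 intensity bins; the pixel count over `bins_used` is summed and
#' converted to physical volume. The default uses all 15 non-black bins,
#' which makes the measure equal to "voxels with intensity >= 4096" times
#' the voxel volume.
#'
#' @param sample A [brain_sample()].
#' @param channel Channel name (default `"edu"`).
#' @param roi A [box_roi()] inside the volume extents.
#' @param bins_used Non-empty subset of the non-black bins `1:15`.
#' @param roi_name Label recorded in the result (default `"roi"`).
#' @return An object of class `volume_result`.
#' @export
structure_volume <- function(sample, channel = "edu", roi,
                             bins_used = nonblack_bins(), roi_name = "roi") {
  stopifnot(inherits(sample, "brain_sample"), inherits(roi, "box_roi"))
  check_bins_used(bins_used)
  vol <- get_channel(sample, channel)
  check_roi_bounds(roi, dim(vol))
  region <- vol[roi_seq(roi$ap), roi_seq(roi$dv), roi_seq(roi$lr)]
  bc <- count_bins(region)
  make_volume_result(sample, roi_name, "structure", bins_used, bc)
}

#' Slice analysis: EdU volume from every-Nth-slice niche masks
#'
#' A-P sections are sampled at `ap_start, ap_start + stride, ...` within
#' the niche's A-P interval; on each sampled section only pixels inside
#' that section's demarcation mask are binned. Pixel counts are summed over
#' sampled sections and `bins_used`. The default bin subset is the first
#' three non-black bins (lower edges 4096, 8192, 12288), targeting the
#' dimmer stem-cell labelling while excluding bright immune-cell signal.
#'
#' The reported volume is that of the *sampled* voxels only (a 1-in-stride
#' sample); within-method comparisons are unaffected by the constant
#' factor. Set `extrapolate = TRUE` to multiply by the stride for a
#' whole-niche estimate.
#'
#' @param sample A [brain_sample()].
#' @param channel Channel name (default `"edu"`).
#' @param niche A [niche_roi()]; every sampled section must carry a mask.
#' @param bins_used Non-empty subset of `1:15` (default `1:3`).
#' @param roi_name Label recorded in the result.
#' @param extrapolate Multiply counts by the stride (default `FALSE`).
#' @return An object of class `volume_result`.
#' @export
slice_volume <- function(sample, channel = "edu", niche,
                         bins_used = 1:3, roi_name = "niche",
                         extrapolate = FALSE) {
  stopifnot(inherits(sample, "brain_sample"), inherits(niche, "niche_roi"))
  check_bins_used(bins_used)
  vol <- get_channel(sample, channel)
  d <- dim(vol)
  if (niche$ap[2] > d[1]) {
    stop(sprintf("niche ap interval [%d,%d) exceeds A-P extent %d",
                 niche$ap[1], niche$ap[2], d[1]))
  }
  shp <- dim(niche$masks[[1L]])
  if (!is.null(shp) && !identical(shp, d[2:3])) {
    stop(sprintf("mask extents %dx%d differ from volume (D-V, L-R) extents %dx%d",
                 shp[1], shp[2], d[2], d[3]))
  }
  sampled <- seq.int(niche$ap[1], niche$ap[2] - 1L, by = niche$stride)
  vals <- integer(0)
  for (s in sampled) {
    key <- as.character(s)
    m <- niche$masks[[key]]
    if (is.null(m)) stop(sprintf("sampled slice %d has no mask", s))
    page <- vol[s + 1L, , , drop = TRUE]
    if (!is.matrix(page)) page <- matrix(page, d[2], d[3])
    vals <- c(vals, page[m])
  }
  bc <- count_bins(vals)
  res <- make_volume_result(sample, roi_name, "slice", bins_used, bc)
  if (extrapolate) {
    res$pixel_count <- res$pixel_count * niche$stride
    res$volume_um3 <- res$volume_um3 * niche$stride
    res$extrapolated <- TRUE
  }
  res
}

check_bins_used <- function(bins_used) {
  if (!length(bins_used) || !all(bins_used %in% 1:15)) {
    stop("'bins_used' must be a non-empty subset of the non-black bins 1:15")
  }
  invisible(TRUE)
}

make_volume_result <- function(sample, roi_name, analysis, bins_used, bc) {
  px <- sum(bc$counts[as.integer(bins_used) + 1L])
  structure(list(sample_id = sample$sample_id,
                 group = sample$group,
                 roi = roi_name,
                 analysis = analysis,
                 bins_used = sort(as.integer(bins_used)),
                 bin_counts = bc,
                 pixel_count = px,
                 volume_um3 = pixels_to_volume(px, sample$geometry),
                 extrapolated = FALSE),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("%s analysis '%s' | sample %s (%s): %d pixels in bins {%s} -> %.6g um^3%s\n",
              x$analysis, x$roi, x$sample_id, x$group, x$pixel_count,
              paste(x$bins_used, collapse = ","), x$volume_um3,
              if (x$extrapolated) " (stride-extrapolated)" else ""))
  invisible(x)
}

#' @export
as.data.frame.volume_result <- function(x, ...) {
  data.frame(sample_id = x$sample_id, group = x$group, roi = x$roi,
             analysis = x$analysis,
             bins_used = paste(x$bins_used, collapse = ";"),
             pixel_count = x$pixel_count, volume_um3 = x$volume_um3)
}

#' Bind a list of volume results into one table
#'
#' @param results List of `volume_result` objects.
#' @param per_bin Append the 16 per-bin counts as extra columns.
#' @return Data frame with one row per result, in the order given.
#' @export
volume_table <- function(results, per_bin = FALSE) {
  rows <- lapply(results, function(r) {
    df <- as.data.frame(r)
    if (per_bin) {
      bins <- as.data.frame(as.list(stats::setNames(
        r$bin_counts$counts, paste0("bin", 0:15))))
      df <- cbind(df, bins)
    }
    df
  })
  do.call(rbind, rows)
}
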