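#' Non-black pixel mask
#'
#' The histogram analysis thresholds the horizontal maximum projection at
#' strictly positive intensity: every non-black pixel (intensity > 0)
#' enters the per-segment mean. Note this is a different predicate from the
#' quantizer's non-black *bins* (intensity >= 4096), which apply to the
#' structure and slice analyses.
#'
#' @param image 2-D integer intensity matrix in `[0, 65535]`.
#' @return Logical matrix, `TRUE` where intensity > 0.
#' @export
nonblack_mask <- function(image) {
  stopifnot(is.matrix(image))
  check_intensity_domain(image)
  image > 0
}

#' Anterior-posterior segment boundaries
#'
#' Partitions the A-P pixel axis into physical segments of width
#' `segment_um`: the pixel whose anterior edge sits at `i * pixel_size_um`
#' belongs to segment `floor(i * pixel_size_um / segment_um)`. The trailing
#' segment is retained even if it covers less than a full `segment_um` and
#' is flagged `partial`.
#'
#' @param n_ap_pixels Number of A-P pixels (virtual sections).
#' @param geometry A [voxel_geometry()].
#' @param segment_um Segment width in micrometres (default 20).
#' @return Data frame with columns `segment_index`, `start`, `stop`
#'   (0-based half-open pixel intervals), `ap_start_um`, `ap_stop_um`
#'   (physical span) and `partial`.
#' @export
segment_boundaries <- function(n_ap_pixels, geometry, segment_um = 20) {
  stopifnot(inherits(geometry, "voxel_geometry"),
            n_ap_pixels >= 1, segment_um > 0)
  ps <- geometry$pixel_size_um
  i <- seq_len(n_ap_pixels) - 1L
  seg <- floor(i * ps / segment_um)
  idx <- sort(unique(seg))
  start <- vapply(idx, function(s) min(i[seg == s]), numeric(1))
  stop_ <- vapply(idx, function(s) max(i[seg == s]) + 1, numeric(1))
  out <- data.frame(segment_index = as.integer(idx),
                    start = as.integer(start), stop = as.integer(stop_),
                    ap_start_um = idx * segment_um,
                    ap_stop_um = (idx + 1) * segment_um,
                    partial = FALSE)
  # last segment is partial if the tissue ends before its nominal far edge
  out$partial[nrow(out)] <- (n_ap_pixels * ps) < out$ap_stop_um[nrow(out)]
  out
}

#' Anterior-posterior EdU intensity profile of one sample
#'
#' The histogram analysis: the channel is collapsed by a horizontal
#' maximum projection, a non-black mask (> 0) is applied, the A-P axis is
#' divided into `segment_um`-wide segments, and each segment's mean
#' intensity over masked pixels is reported. Segments containing no
#' non-black pixel report mean 0 so that profiles stay plottable.
#'
#' @param sample A [brain_sample()].
#' @param channel Channel name (default `"edu"`).
#' @param segment_um Segment width in micrometres (default 20).
#' @param nonblack_only If `TRUE` (default), the mean is taken over
#'   non-black pixels only; `FALSE` averages over all pixels of the
#'   segment's projection columns.
#' @return An object of class `ap_profile`: data frame with columns
#'   `segment_index`, `ap_start_um`, `ap_stop_um`, `mean_intensity`,
#'   `n_nonblack`, `partial`; attributes `sample_id`, `group`,
#'   `segment_um`.
#' @export
sample_profile <- function(sample, channel = "edu", segment_um = 20,
                           nonblack_only = TRUE) {
  stopifnot(inherits(sample, "brain_sample"))
  vol <- get_channel(sample, channel)
  proj <- max_project_horizontal(vol)
  segs <- segment_boundaries(nrow(proj), sample$geometry, segment_um)
  mask <- nonblack_mask(proj)
  mean_int <- numeric(nrow(segs))
  n_nb <- integer(nrow(segs))
  for (k in seq_len(nrow(segs))) {
    rows <- seq.int(segs$start[k] + 1L, segs$stop[k])
    sub <- proj[rows, , drop = FALSE]
    msk <- mask[rows, , drop = FALSE]
    n_nb[k] <- sum(msk)
    vals <- if (nonblack_only) sub[msk] else as.vector(sub)
    mean_int[k] <- if (length(vals)) mean(vals) else 0
    if (nonblack_only && n_nb[k] == 0L) mean_int[k] <- 0
  }
  out <- data.frame(segment_index = segs$segment_index,
                    ap_start_um = segs$ap_start_um,
                    ap_stop_um = segs$ap_stop_um,
                    mean_intensity = mean_int,
                    n_nonblack = n_nb,
                    partial = segs$partial)
  structure(out, class = c("ap_profile", "data.frame"),
            sample_id = sample$sample_id, group = sample$group,
            segment_um = segment_um)
}

#' Aggregate per-sample profiles into a group profile
#'
#' Profiles are aligned at the anterior end and truncated to the shortest
#' profile (age-matched animals yield near-equal segment counts; no
#' registration or warping is attempted). Per segment, the mean of the
#' per-sample means and its SEM are reported.
#'
#' @param profiles List of [sample_profile()] results with one common
#'   `segment_um`.
#' @param group Group label; defaults to the first profile's group.
#' @return An object of class `group_profile`: data frame with
#'   `segment_index`, `ap_start_um`, `ap_stop_um`, `mean`, `sem`, `n`.
#' @export
group_profile <- function(profiles, group = NULL) {
  if (!length(profiles)) stop("need at least one profile")
  if (!all(vapply(profiles, inherits, logical(1), "ap_profile"))) {
    stop("all elements must be ap_profile objects")
  }
  widths <- vapply(profiles, attr, numeric(1), "segment_um")
  if (length(unique(widths)) != 1L) stop("profiles differ in segment_um")
  if (is.null(group)) group <- attr(profiles[[1L]], "group")
  len <- min(vapply(profiles, nrow, integer(1)))
  m <- vapply(profiles, function(p) p$mean_intensity[seq_len(len)],
              numeric(len))
  m <- matrix(m, nrow = len)
  mu <- rowMeans(m)
  n <- length(profiles)
  sem <- if (n > 1L) apply(m, 1L, stats::sd) / sqrt(n) else rep(0, len)
  out <- data.frame(segment_index = profiles[[1L]]$segment_index[seq_len(len)],
                    ap_start_um = profiles[[1L]]$ap_start_um[seq_len(len)],
                    ap_stop_um = profiles[[1L]]$ap_stop_um[seq_len(len)],
                    mean = mu, sem = sem, n = n)
  structure(out, class = c("group_profile", "data.frame"),
            group = group, segment_um = widths[1L])
}

#' Per-segment percent change of a treatment profile from control
#'
#' @param treatment,control [group_profile()] objects with equal
#'   `segment_um`; lengths are reconciled by anterior-end truncation.
#' @return Data frame with `segment_index`, `ap_start_um`,
#'   `percent_change` and `undefined`; segments whose control mean is 0
#'   carry `NA` percent change and `undefined = TRUE`, never a number.
#' @export
percent_change <- function(treatment, control) {
  stopifnot(inherits(treatment, "group_profile"),
            inherits(control, "group_profile"))
  if (attr(treatment, "segment_um") != attr(control, "segment_um")) {
    stop("profiles differ in segment_um")
  }
  len <- min(nrow(treatment), nrow(control))
  tr <- treatment$mean[seq_len(len)]
  ct <- control$mean[seq_len(len)]
  undef <- ct == 0
  pc <- rep(NA_real_, len)
  pc[!undef] <- 100 * (tr[!undef] - ct[!undef]) / ct[!undef]
  data.frame(segment_index = treatment$segment_index[seq_len(len)],
             ap_start_um = treatment$ap_start_um[seq_len(len)],
             percent_change = pc, undefined = undef)
}

#' @export
plot.ap_profile <- function(x, ...) {
  mid <- (x$ap_start_um + x$ap_stop_um) / 2
  graphics::plot(mid, x$mean_intensity, type = "h",
                 xlab = "A-P position (um)", ylab = "mean EdU intensity",
                 main = sprintf("A-P profile: %s (%s)",
                                attr(x, "sample_id"), attr(x, "group")), ...)
  invisible(x)
}

#' @export
plot.group_profile <- function(x, ...) {
  mid <- (x$ap_start_um + x$ap_stop_um) / 2
  graphics::plot(mid, x$mean, type = "l",
                 ylim = range(0, x$mean + x$sem),
                 xlab = "A-P position (um)", ylab = "mean EdU intensity",
                 main = sprintf("Group profile: %s (n = %d)",
                                attr(x, "group"), x$n[1L]), ...)
  graphics::arrows(mid, x$mean - x$sem, mid, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  invisible(x)
}
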