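#' The 16-bin intensity quantizer
#'
#' The 16-bit intensity domain `[0, 65535]` is divided into 16 equal bins of
#' width 4096 (the "16 colors" look-up-table convention of the original
#' FIJI workflow). Bin 0 -- intensities below 4096 -- is the *black bin* and
#' is excluded from volume quantification; the remaining 15 *non-black*
#' bins, labelled by their lower edges (4096, 8192, ...), carry the signal.
#' The top bin additionally absorbs 65535, since 16 x 4096 exceeds the
#' representable maximum by one.
#'
#' @param intensity Integer vector of intensities in `[0, 65535]`.
#' @return `bin_of`: integer bin indices in `0..15`.
#' @name quantizer
NULL

BIN_WIDTH <- 4096L
N_BINS <- 16L

#' @rdname quantizer
#' @export
bin_of <- function(intensity) {
  check_intensity_domain(intensity)
  pmin.int(as.integer(intensity) %/% BIN_WIDTH, N_BINS - 1L)
}

check_intensity_domain <- function(x) {
  if (anyNA(x)) stop("intensity contains NA")
  bad <- which(x < 0 | x > INTENSITY_MAX)
  if (length(bad)) {
    stop(sprintf("intensity out of [0, %d]: value %s at position %d",
                 INTENSITY_MAX, format(x[bad[1]]), bad[1]))
  }
  invisible(TRUE)
}

#' Non-black bin indices
#'
#' @return The 15 bin indices `1:15` used for volume quantification (bin 0,
#'   the black bin, is excluded).
#' @export
nonblack_bins <- function() 1:15

#' Lower intensity edge of each bin
#'
#' @param bins Integer bin indices in `0..15`.
#' @return Lower edges (`bins * 4096`); the first three non-black bins have
#'   edges 4096, 8192 and 12288.
#' @export
bin_lower_edge <- function(bins) {
  stopifnot(all(bins %in% 0:15))
  as.integer(bins) * BIN_WIDTH
}

#' Count pixels per intensity bin
#'
#' @param region Integer vector (or array) of intensities in `[0, 65535]`.
#' @return An object of class `bin_counts`: list with `counts` (16
#'   non-negative integers, bins 0..15) and `n_pixels`; `sum(counts) ==
#'   n_pixels` always holds.
#' @export
count_bins <- function(region) {
  region <- as.integer(region)
  b <- bin_of(region)
  counts <- tabulate(b + 1L, nbins = N_BINS)
  structure(list(counts = counts, n_pixels = length(region)),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts over %d pixels (black bin: %d; non-black: %d)\n",
              x$n_pixels, x$counts[1], x$n_pixels - x$counts[1]))
  tab <- data.frame(bin = 0:15, lower_edge = bin_lower_edge(0:15),
                    count = x$counts)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Voxel volume from geometry
#'
#' @param geometry A [voxel_geometry()].
#' @return Voxel volume in cubic micrometres (`pixel_size_um^3`); 125 for
#'   5 um pixels, 91.125 for 4.5 um.
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$pixel_size_um^3
}

#' Convert a pixel count to physical volume
#'
#' @param count Non-negative pixel (voxel) count.
#' @param geometry A [voxel_geometry()].
#' @return Volume in cubic micrometres: `count * voxel_volume(geometry)`.
#' @export
pixels_to_volume <- function(count, geometry) {
  if (any(count < 0)) stop("'count' must be non-negative")
  count * voxel_volume(geometry)
}
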