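#' Isotropic voxel geometry
#'
#' OPT reconstructions of cleared brains are isotropic: one scalar edge
#' length fully determines the voxel. Reported pixel sizes for adult
#' zebrafish whole-brain scans fall around 4.5--5 micrometres, giving voxel
#' volumes of roughly 91--125 cubic micrometres.
#'
#' @param pixel_size_um Edge length of one voxel in micrometres. Must be a
#'   single positive number.
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry(5)
#' voxel_volume(g)  # 125
#' @export
voxel_geometry <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("'pixel_size_um' must be a single positive finite number")
  }
  structure(list(pixel_size_um = as.numeric(pixel_size_um)),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("Isotropic voxel geometry: %.4g um pixel, %.6g um^3 voxel\n",
              x$pixel_size_um, x$pixel_size_um^3))
  invisible(x)
}

# Full 16-bit intensity domain. The upper end of a 16-bit image is 65535
# ("white"); the quantizer's 16 x 4096 bins cover exactly this domain.
INTENSITY_MAX <- 65535L

#' Single-channel 3-D fluorescence volume
#'
#' Wraps a 3-D integer array of 16-bit intensities with the package's fixed
#' anatomical axis convention: axis 1 runs anterior to posterior (stack
#' pages, i.e. 1-pixel virtual cross-sections), axis 2 dorsal to ventral
#' (page rows), axis 3 left to right (page columns).
#'
#' @param intensities 3-D numeric array with all values in `[0, 65535]`.
#' @return The array, coerced to integer storage, with class
#'   `channel_volume`.
#' @export
channel_volume <- function(intensities) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("'intensities' must be a 3-D array")
  }
  if (any(dim(intensities) < 1L)) stop("all three extents must be >= 1")
  v <- intensities
  if (anyNA(v)) stop("intensities contain NA")
  rng <- range(v)
  if (rng[1] < 0 || rng[2] > INTENSITY_MAX) {
    stop(sprintf("intensities outside [0, %d]: range %s..%s",
                 INTENSITY_MAX, format(rng[1]), format(rng[2])))
  }
  storage.mode(v) <- "integer"
  class(v) <- c("channel_volume", class(v))
  v
}

#' @export
print.channel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("channel_volume: %d (A-P) x %d (D-V) x %d (L-R), range %d..%d\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

is_channel_volume <- function(x) inherits(x, "channel_volume")

#' A specimen: named channels plus geometry and group label
#'
#' @param sample_id Character scalar identifying the specimen.
#' @param group Treatment group label (e.g. `"control"`, `"1dpl"`).
#' @param channels Named list of [channel_volume()] objects sharing one
#'   grid; typical names are `"edu"` and `"autofluorescence"`.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `brain_sample`.
#' @export
brain_sample <- function(sample_id, group, channels, geometry) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(group), length(group) == 1L,
            inherits(geometry, "voxel_geometry"))
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("'channels' must be a non-empty named list")
  }
  dims <- lapply(channels, dim)
  for (nm in names(channels)) {
    if (!is_channel_volume(channels[[nm]])) {
      stop(sprintf("channel '%s' is not a channel_volume", nm))
    }
    if (!identical(dims[[nm]], dims[[1L]])) {
      stop(sprintf("channel '%s' extents differ from channel '%s'",
                   nm, names(channels)[1L]))
    }
  }
  structure(list(sample_id = sample_id, group = group,
                 channels = channels, geometry = geometry),
            class = "brain_sample")
}

#' @export
print.brain_sample <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("brain_sample '%s' (group %s): %s; channels: %s; %g um pixels\n",
              x$sample_id, x$group, paste(d, collapse = " x "),
              paste(names(x$channels), collapse = ", "),
              x$geometry$pixel_size_um))
  invisible(x)
}

get_channel <- function(sample, channel) {
  if (!channel %in% names(sample$channels)) {
    stop(sprintf("sample '%s' has no channel '%s' (available: %s)",
                 sample$sample_id, channel,
                 paste(names(sample$channels), collapse = ", ")))
  }
  sample$channels[[channel]]
}

#' Axis-aligned box region of interest
#'
#' Index intervals are 0-based and half-open (`[start, stop)`), matching the
#' package-wide slicing convention. The A-P interval length is the ROI's
#' "z-depth" in virtual sections.
#'
#' @param ap,dv,lr Length-2 integer vectors `c(start, stop)` on the
#'   anterior-posterior, dorsal-ventral and left-right axes.
#' @return An object of class `box_roi`.
#' @export
box_roi <- function(ap, dv, lr) {
  chk <- function(iv, nm) {
    if (!is.numeric(iv) || length(iv) != 2L || anyNA(iv) ||
        iv[1] < 0 || iv[1] >= iv[2] || any(iv != trunc(iv))) {
      stop(sprintf("'%s' must be an integer interval [start, stop) with 0 <= start < stop", nm))
    }
    as.integer(iv)
  }
  structure(list(ap = chk(ap, "ap"), dv = chk(dv, "dv"), lr = chk(lr, "lr")),
            class = "box_roi")
}

# 1-based R index sequence for one 0-based half-open interval
roi_seq <- function(iv) seq.int(iv[1] + 1L, iv[2])

check_roi_bounds <- function(roi, dims) {
  nm <- c("ap", "dv", "lr")
  for (k in 1:3) {
    if (roi[[nm[k]]][2] > dims[k]) {
      stop(sprintf("ROI %s interval [%d,%d) exceeds axis extent %d",
                   nm[k], roi[[nm[k]]][1], roi[[nm[k]]][2], dims[k]))
    }
  }
  invisible(TRUE)
}

#' Per-slice niche region of interest
#'
#' Slice analysis samples a neurogenic compartment every `stride`-th virtual
#' section; each sampled section carries its own 2-D demarcation mask over
#' the (D-V, L-R) plane (the "hashed lines" a human analyst would draw).
#'
#' @param ap Length-2 0-based half-open A-P interval.
#' @param masks Named list of logical matrices; names are 0-based A-P slice
#'   indices (as characters) inside `ap`. All masks must share one shape.
#' @param stride Positive integer sampling interval (default 5, i.e. every
#'   5th section).
#' @return An object of class `niche_roi`.
#' @export
niche_roi <- function(ap, masks, stride = 5L) {
  if (!is.numeric(ap) || length(ap) != 2L || ap[1] < 0 || ap[1] >= ap[2] ||
      any(ap != trunc(ap))) {
    stop("'ap' must be an integer interval [start, stop) with 0 <= start < stop")
  }
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1 ||
      stride != trunc(stride)) {
    stop("'stride' must be a positive integer")
  }
  if (!is.list(masks) || is.null(names(masks))) {
    stop("'masks' must be a named list of logical matrices keyed by A-P index")
  }
  keys <- suppressWarnings(as.integer(names(masks)))
  if (anyNA(keys)) stop("mask names must be integer A-P slice indices")
  if (any(keys < ap[1] | keys >= ap[2])) {
    stop("every mask key must lie inside the ap interval")
  }
  shp <- NULL
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!is.matrix(m) || !is.logical(m)) {
      stop(sprintf("mask '%s' must be a logical matrix", names(masks)[i]))
    }
    if (is.null(shp)) shp <- dim(m)
    if (!identical(dim(m), shp)) {
      stop(sprintf("mask '%s' shape differs from the first mask", names(masks)[i]))
    }
  }
  structure(list(ap = as.integer(ap), masks = masks, stride = as.integer(stride)),
            class = "niche_roi")
}

#' Read one fluorescence channel from a multi-page TIFF stack
#'
#' One file holds one channel of one specimen; page order is anterior to
#' posterior. 8-bit stacks are upscaled to the 16-bit domain by multiplying
#' by 257, so that 255 maps exactly to 65535.
#'
#' @param path Path to a multi-page grayscale TIFF (8- or 16-bit).
#' @param geometry A [voxel_geometry()] (recorded by the caller; the TIFF
#'   itself carries no trusted physical calibration).
#' @return A [channel_volume()] with axis 1 = page index (A-P).
#' @export
read_channel <- function(path, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop(sprintf("cannot read TIFF '%s': %s",
                                                     path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  shp <- NULL
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (!is.matrix(p)) {
      stop(sprintf("page %d of '%s' is not single-sample grayscale", i, path))
    }
    if (is.null(shp)) shp <- dim(p)
    if (!identical(dim(p), shp)) {
      stop(sprintf("page %d of '%s' has shape %dx%d, expected %dx%d",
                   i, path, nrow(p), ncol(p), shp[1], shp[2]))
    }
    bits <- attr(p, "bits.per.sample")
    if (!is.null(bits) && bits == 8L) pages[[i]] <- p * 257L
    else if (!is.null(bits) && !bits %in% c(8L, 16L)) {
      stop(sprintf("page %d of '%s': unsupported bit depth %d", i, path, bits))
    }
  }
  v <- array(0L, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) v[i, , ] <- pages[[i]]
  channel_volume(v)
}

#' Write a channel volume as a multi-page 16-bit grayscale TIFF
#'
#' Inverse of [read_channel()]: the round trip is bit-exact.
#'
#' @param volume A [channel_volume()].
#' @param path Output path; the parent directory must exist.
#' @param compression `"none"` (default) or `"deflate"`.
#' @return `path`, invisibly.
#' @export
write_channel <- function(volume, path, compression = c("none", "deflate")) {
  stopifnot(is_channel_volume(volume))
  compression <- match.arg(compression)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory '%s' does not exist", dirname(path)))
  }
  pages <- lapply(seq_len(dim(volume)[1]), function(i) {
    m <- volume[i, , , drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, dim(volume)[2], dim(volume)[3])
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = compression)
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' The manifest is a CSV with header
#' `sample_id,group,pixel_size_um,edu_path,autofluorescence_path` and an
#' optional `marker_path` column. Channel paths are resolved relative to the
#' manifest's directory unless absolute.
#'
#' @param path Manifest CSV path.
#' @param groups Optional character vector of allowed group labels; when
#'   given, any other label is rejected.
#' @param check_paths Verify that every referenced channel file exists
#'   (default `TRUE`).
#' @return A data frame of class `cohort_manifest` with resolved paths.
#' @export
load_manifest <- function(path, groups = NULL, check_paths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "pixel_size_um", "edu_path",
                "autofluorescence_path")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop(sprintf("manifest '%s' is missing columns: %s",
                 path, paste(missing, collapse = ", ")))
  }
  dup <- m$sample_id[duplicated(m$sample_id)]
  if (length(dup)) {
    stop(sprintf("duplicate sample_id in manifest: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(groups)) {
    bad <- setdiff(unique(m$group), groups)
    if (length(bad)) {
      stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
    }
  }
  if (any(!is.finite(m$pixel_size_um) | m$pixel_size_um <= 0)) {
    stop("pixel_size_um must be positive for every sample")
  }
  base <- dirname(normalizePath(path))
  pathcols <- intersect(c("edu_path", "autofluorescence_path", "marker_path"),
                        names(m))
  for (col in pathcols) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]]) & nzchar(m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
    if (check_paths) {
      gone <- m[[col]] != "" & !file.exists(m[[col]])
      if (any(gone)) {
        stop(sprintf("manifest column %s: missing file(s): %s",
                     col, paste(m[[col]][gone], collapse = ", ")))
      }
    }
  }
  class(m) <- c("cohort_manifest", class(m))
  m
}

#' Load every sample referenced by a manifest
#'
#' @param manifest A `cohort_manifest` from [load_manifest()].
#' @return A list of [brain_sample()] objects, named by sample id.
#' @export
load_cohort <- function(manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    g <- voxel_geometry(manifest$pixel_size_um[i])
    ch <- list(edu = read_channel(manifest$edu_path[i], g),
               autofluorescence = read_channel(manifest$autofluorescence_path[i], g))
    if ("marker_path" %in% names(manifest) &&
        nzchar(manifest$marker_path[i])) {
      ch$marker <- read_channel(manifest$marker_path[i], g)
    }
    brain_sample(manifest$sample_id[i], manifest$group[i], ch, g)
  })
  names(out) <- manifest$sample_id
  out
}

#' Read a box ROI from JSON
#'
#' Format: `{"ap":[a,b],"dv":[c,d],"lr":[e,f]}` with 0-based half-open
#' intervals.
#' @param path JSON file path.
#' @return A [box_roi()].
#' @export
read_box_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("ap", "dv", "lr")) {
    if (is.null(j[[nm]])) stop(sprintf("ROI JSON '%s' lacks field '%s'", path, nm))
  }
  box_roi(j$ap, j$dv, j$lr)
}

#' Read a niche ROI from JSON
#'
#' Format: `{"ap":[a,b],"stride":5,"masks":{"<ap_index>":"<mask tiff>"}}`.
#' Mask TIFFs are single-page; any non-zero pixel is inside the niche.
#' Relative mask paths resolve against the JSON file's directory.
#'
#' @param path JSON file path.
#' @return A [niche_roi()].
#' @export
read_niche_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$ap) || is.null(j$masks)) {
    stop(sprintf("niche ROI JSON '%s' needs fields 'ap' and 'masks'", path))
  }
  stride <- if (is.null(j$stride)) 5L else j$stride
  base <- dirname(normalizePath(path))
  masks <- lapply(j$masks, function(p) {
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    m <- tiff::readTIFF(p, as.is = TRUE)
    if (!is.matrix(m)) stop(sprintf("mask '%s' is not single-channel", p))
    m > 0
  })
  names(masks) <- names(j$masks)
  niche_roi(j$ap, masks, stride)
}

#' Maximum intensity projection through the horizontal plane
#'
#' Collapses the dorsal-ventral axis, yielding a 2-D image over
#' (A-P, L-R): per position, the maximum intensity across all D-V levels.
#' This is the projection underlying the anterior-posterior histogram
#' analysis.
#'
#' @param volume A [channel_volume()].
#' @return An integer matrix with rows = A-P positions, columns = L-R.
#' @export
max_project_horizontal <- function(volume) {
  stopifnot(is_channel_volume(volume))
  d <- dim(volume)
  # collapse axis 2: pmax over D-V levels, vectorized over (A-P, L-R)
  out <- matrix(-1L, d[1], d[3])
  for (j in seq_len(d[2])) out <- pmax(out, volume[, j, , drop = TRUE])
  if (!is.matrix(out)) out <- matrix(out, d[1], d[3])
  storage.mode(out) <- "integer"
  out
}
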