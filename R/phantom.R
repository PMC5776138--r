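#' Specification of a synthetic OPT brain phantom
#'
#' Describes a desk-scale caricature of a reconstructed adult zebrafish
#' brain: an autofluorescent ellipsoidal brain shell; midline ventricular,
#' tectal and cerebellar proliferation niches along the A-P axis seeded
#' with punctate EdU foci (Poisson counts, hard-edged spheres); and a
#' lesion-condition-dependent diffuse parenchymal component over the time
#' course control / 1 / 3 / 7 days post lesion (dpl). Signal is smoothed by
#' a Gaussian blur standing in for the OPT point-spread and reconstruction
#' smoothing, then additive Gaussian noise is applied and the result is
#' clipped and quantized to the 16-bit domain.
#'
#' The default injury schedule realizes the qualitative post-lesion
#' pattern the analyses are designed to resolve: a strong diffuse immune
#' burst at 1 dpl (focal in the lesioned telencephalic hemisphere, milder
#' brain-wide), decaying by 3 and 7 dpl, while ventricular-niche focus
#' rates peak at 3 dpl ipsilaterally (1 dpl contralaterally) and tectal /
#' cerebellar niches stay at their constitutive rates throughout.
#'
#' @param extents Grid extents in pixels, `c(A-P, D-V, L-R)`.
#' @param pixel_size_um Isotropic pixel size in micrometres.
#' @param brain_semiaxes_um Ellipsoid semi-axes (A-P, D-V, L-R) in um.
#' @param brain_center_um Ellipsoid centre in um; default grid centre.
#' @param niches List of niche definitions; see Details in the source.
#'   Each is a list with `name`, `type` (`"midline_band"`,
#'   `"dorsal_shell"` or `"dorsal_band"`), `ap_span_um`, `lambda_per_um3`
#'   (focus rate), `focus_radius_um`, `peak_intensity`, geometric
#'   parameters for the type, and per-group focus-rate multipliers
#'   `ipsi_boost` / `contra_boost` over the groups.
#' @param groups Treatment group labels, anterior of all schedules.
#' @param parenchyma_amplitude Per-group intensity of the focal diffuse
#'   component confined to the lesioned telencephalic hemisphere.
#' @param parenchyma_ap_span_um A-P span of the focal component
#'   (the telencephalon).
#' @param systemic_amplitude Per-group intensity of the brain-wide diffuse
#'   component (immune infiltration distal to the lesion), applied outside
#'   all niche regions.
#' @param autofluorescence_base Mean autofluorescence intensity inside the
#'   brain.
#' @param blur_sigma_um Gaussian blur standard deviation in um.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(extents = c(80L, 48L, 48L),
                         pixel_size_um = 5,
                         brain_semiaxes_um = c(185, 100, 100),
                         brain_center_um = NULL,
                         niches = default_niches(),
                         groups = c("control", "1dpl", "3dpl", "7dpl"),
                         parenchyma_amplitude = c(control = 0, "1dpl" = 9000,
                                                  "3dpl" = 4500, "7dpl" = 500),
                         parenchyma_ap_span_um = c(25, 225),
                         systemic_amplitude = c(control = 0, "1dpl" = 5000,
                                                "3dpl" = 1200, "7dpl" = 0),
                         autofluorescence_base = 25000,
                         blur_sigma_um = 3,
                         noise_sd = 600) {
  stopifnot(length(extents) == 3L, all(extents >= 8L),
            pixel_size_um > 0, length(brain_semiaxes_um) == 3L,
            all(brain_semiaxes_um > 0), blur_sigma_um >= 0, noise_sd >= 0,
            autofluorescence_base >= 0)
  if (is.null(brain_center_um)) {
    brain_center_um <- extents * pixel_size_um / 2
  }
  for (sched in list(parenchyma_amplitude, systemic_amplitude)) {
    if (!all(groups %in% names(sched))) {
      stop("amplitude schedules must name every group")
    }
    if (any(sched < 0)) stop("amplitudes must be >= 0")
  }
  for (nd in niches) {
    stopifnot(nd$lambda_per_um3 >= 0, nd$focus_radius_um >= 0,
              nd$peak_intensity >= 0, nd$peak_intensity <= INTENSITY_MAX)
    for (b in list(nd$ipsi_boost, nd$contra_boost)) {
      if (!all(groups %in% names(b))) {
        stop(sprintf("niche '%s': boost schedules must name every group", nd$name))
      }
    }
  }
  structure(list(extents = as.integer(extents),
                 pixel_size_um = pixel_size_um,
                 brain_semiaxes_um = brain_semiaxes_um,
                 brain_center_um = brain_center_um,
                 niches = niches, groups = groups,
                 parenchyma_amplitude = parenchyma_amplitude,
                 parenchyma_ap_span_um = parenchyma_ap_span_um,
                 systemic_amplitude = systemic_amplitude,
                 autofluorescence_base = autofluorescence_base,
                 blur_sigma_um = blur_sigma_um,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Default niche definitions of the phantom
#'
#' Three caricature niches: a midline ventricular band in the
#' telencephalon (the pallial stem-cell niche, the only one whose focus
#' rate responds to the lesion), a dorsal tectal shell, and a dorsal
#' cerebellar band. Spans and rates are chosen so each niche hosts on the
#' order of 50--90 constitutive EdU foci at the default grid.
#'
#' @return List of niche definition lists.
#' @export
default_niches <- function() {
  flat <- c(control = 1, "1dpl" = 1, "3dpl" = 1, "7dpl" = 1)
  list(
    list(name = "ventricular", type = "midline_band",
         ap_span_um = c(50, 250), lambda_per_um3 = 5e-5,
         focus_radius_um = 7.5, peak_intensity = 12000,
         lr_halfwidth_um = 30, dv_range_um = c(60, 180),
         ipsi_boost = c(control = 1, "1dpl" = 1.3, "3dpl" = 2.5, "7dpl" = 1.3),
         contra_boost = c(control = 1, "1dpl" = 2.2, "3dpl" = 1.2, "7dpl" = 1)),
    list(name = "tectal", type = "dorsal_shell",
         ap_span_um = c(240, 310), lambda_per_um3 = 1.0e-4,
         focus_radius_um = 7.5, peak_intensity = 12000,
         radial_range = c(0.75, 1),
         ipsi_boost = flat, contra_boost = flat),
    list(name = "cerebellar", type = "dorsal_band",
         ap_span_um = c(320, 370), lambda_per_um3 = 1.5e-4,
         focus_radius_um = 7.5, peak_intensity = 12000,
         lr_halfwidth_um = 50, dv_range_um = c(40, 100),
         ipsi_boost = flat, contra_boost = flat)
  )
}

# voxel-centre coordinates (um) along each axis
phantom_coords <- function(spec) {
  lapply(1:3, function(k) {
    (seq_len(spec$extents[k]) - 0.5) * spec$pixel_size_um
  })
}

# per-axis normalized squared ellipsoid terms
phantom_ellipse_terms <- function(spec) {
  co <- phantom_coords(spec)
  lapply(1:3, function(k) {
    ((co[[k]] - spec$brain_center_um[k]) / spec$brain_semiaxes_um[k])^2
  })
}

#' Brain (ellipsoid) mask of a phantom
#'
#' @param spec A [phantom_spec()].
#' @return Logical 3-D array, `TRUE` inside the brain ellipsoid.
#' @export
phantom_brain_mask <- function(spec) {
  tt <- phantom_ellipse_terms(spec)
  outer(outer(tt[[1]], tt[[2]], "+"), tt[[3]], "+") <= 1
}

#' Niche region mask of a phantom
#'
#' @param spec A [phantom_spec()].
#' @param niche_name Name of one niche in `spec$niches`.
#' @return Logical 3-D array of the niche's voxel region (before focus
#'   placement).
#' @export
phantom_niche_region <- function(spec, niche_name) {
  nd <- find_niche(spec, niche_name)
  brain <- phantom_brain_mask(spec)
  co <- phantom_coords(spec)
  d <- spec$extents
  in_ap <- co[[1]] >= nd$ap_span_um[1] & co[[1]] < nd$ap_span_um[2]
  reg <- brain & array(rep(in_ap, times = d[2] * d[3]), dim = d)
  if (nd$type == "midline_band") {
    in_dv <- co[[2]] >= nd$dv_range_um[1] & co[[2]] < nd$dv_range_um[2]
    in_lr <- abs(co[[3]] - spec$brain_center_um[3]) <= nd$lr_halfwidth_um
    reg <- reg &
      aperm(array(rep(in_dv, times = d[1] * d[3]), dim = c(d[2], d[1], d[3])),
            c(2, 1, 3)) &
      aperm(array(rep(in_lr, times = d[1] * d[2]), dim = c(d[3], d[1], d[2])),
            c(2, 3, 1))
  } else if (nd$type == "dorsal_shell") {
    tt <- phantom_ellipse_terms(spec)
    rho <- sqrt(outer(outer(tt[[1]], tt[[2]], "+"), tt[[3]], "+"))
    dorsal <- co[[2]] < spec$brain_center_um[2]
    reg <- reg & rho >= nd$radial_range[1] & rho <= nd$radial_range[2] &
      aperm(array(rep(dorsal, times = d[1] * d[3]), dim = c(d[2], d[1], d[3])),
            c(2, 1, 3))
  } else if (nd$type == "dorsal_band") {
    in_dv <- co[[2]] >= nd$dv_range_um[1] & co[[2]] < nd$dv_range_um[2]
    in_lr <- abs(co[[3]] - spec$brain_center_um[3]) <= nd$lr_halfwidth_um
    reg <- reg &
      aperm(array(rep(in_dv, times = d[1] * d[3]), dim = c(d[2], d[1], d[3])),
            c(2, 1, 3)) &
      aperm(array(rep(in_lr, times = d[1] * d[2]), dim = c(d[3], d[1], d[2])),
            c(2, 3, 1))
  } else {
    stop(sprintf("unknown niche type '%s'", nd$type))
  }
  reg
}

find_niche <- function(spec, niche_name) {
  for (nd in spec$niches) if (nd$name == niche_name) return(nd)
  stop(sprintf("phantom has no niche named '%s'", niche_name))
}

#' Box ROI for a named phantom structure
#'
#' Convenience boxes matching the analyses run on real scans: the lesioned
#' (left) and unlesioned (right) telencephalic hemispheres over the
#' telencephalic A-P span, the tectum and cerebellum over their niches'
#' A-P spans, or the whole grid.
#'
#' @param spec A [phantom_spec()].
#' @param region One of `"lesioned_hemisphere"`, `"unlesioned_hemisphere"`,
#'   `"tectum"`, `"cerebellum"`, `"whole"`.
#' @return A [box_roi()].
#' @export
phantom_box_roi <- function(spec, region = c("lesioned_hemisphere",
                                             "unlesioned_hemisphere",
                                             "tectum", "cerebellum", "whole")) {
  region <- match.arg(region)
  d <- spec$extents
  ps <- spec$pixel_size_um
  mid_lr <- as.integer(floor(d[3] / 2))
  ap_px <- function(span_um) {
    c(max(0L, as.integer(floor(span_um[1] / ps))),
      min(d[1], as.integer(ceiling(span_um[2] / ps))))
  }
  switch(region,
    whole = box_roi(c(0, d[1]), c(0, d[2]), c(0, d[3])),
    lesioned_hemisphere = box_roi(ap_px(spec$parenchyma_ap_span_um),
                                  c(0, d[2]), c(0, mid_lr)),
    unlesioned_hemisphere = box_roi(ap_px(spec$parenchyma_ap_span_um),
                                    c(0, d[2]), c(mid_lr, d[3])),
    tectum = box_roi(ap_px(find_niche(spec, "tectal")$ap_span_um),
                     c(0, d[2]), c(0, d[3])),
    cerebellum = box_roi(ap_px(find_niche(spec, "cerebellar")$ap_span_um),
                         c(0, d[2]), c(0, d[3])))
}

#' Niche ROI (per-slice masks) for slice analysis on a phantom
#'
#' Builds the demarcation masks a human analyst would draw around a
#' phantom niche: the niche region restricted to one hemisphere, sampled
#' every `stride`-th section, with an optional in-plane erosion that keeps
#' the demarcation conservatively inside the niche (as manual demarcation
#' does), avoiding boundary voxels contaminated by blurred parenchymal
#' signal.
#'
#' @param spec A [phantom_spec()].
#' @param niche_name Niche to demarcate.
#' @param hemisphere `"both"`, `"lesioned"` (left) or `"unlesioned"`.
#' @param stride Sampling interval in sections (default 5).
#' @param erode In-plane 4-neighbour erosion iterations (default 1).
#' @return A [niche_roi()].
#' @export
phantom_niche_roi <- function(spec, niche_name,
                              hemisphere = c("both", "lesioned", "unlesioned"),
                              stride = 5L, erode = 1L) {
  hemisphere <- match.arg(hemisphere)
  reg <- phantom_niche_region(spec, niche_name)
  d <- spec$extents
  mid_lr <- as.integer(floor(d[3] / 2))
  if (hemisphere == "lesioned") reg[, , (mid_lr + 1L):d[3]] <- FALSE
  if (hemisphere == "unlesioned" && mid_lr >= 1L) reg[, , 1:mid_lr] <- FALSE
  ap_idx <- which(apply(reg, 1L, any))
  if (!length(ap_idx)) {
    stop(sprintf("niche '%s' region is empty in hemisphere '%s'",
                 niche_name, hemisphere))
  }
  ap <- c(min(ap_idx) - 1L, max(ap_idx))  # 0-based half-open
  sampled <- seq.int(ap[1], ap[2] - 1L, by = stride)
  masks <- lapply(sampled, function(s) {
    m <- reg[s + 1L, , , drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, d[2], d[3])
    for (k in seq_len(erode)) m <- erode4(m)
    m
  })
  names(masks) <- as.character(sampled)
  niche_roi(ap, masks, stride)
}

# one iteration of 4-neighbour binary erosion on a logical matrix
erode4 <- function(m) {
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
  m & up & dn & lf & rt
}

# separable 3-D Gaussian blur (truncated at 3 sigma, edge-renormalized)
gaussian_blur3d <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  d <- dim(x)
  R <- max(1L, ceiling(3 * sigma_px))
  w <- exp(-(0:R)^2 / (2 * sigma_px^2))
  kmat <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - R):min(n, i + R)
      K[i, j] <- w[abs(j - i) + 1L]
      K[i, ] <- K[i, ] / sum(K[i, ])
    }
    K
  }
  # axis 1
  x <- array(kmat(d[1]) %*% matrix(x, d[1]), dim = d)
  # axis 2
  x <- aperm(x, c(2, 1, 3))
  x <- array(kmat(d[2]) %*% matrix(x, d[2]), dim = d[c(2, 1, 3)])
  x <- aperm(x, c(2, 1, 3))
  # axis 3
  x <- aperm(x, c(3, 1, 2))
  x <- array(kmat(d[3]) %*% matrix(x, d[3]), dim = d[c(3, 1, 2)])
  aperm(x, c(2, 3, 1))
}

# sphere of voxel-offset triples within radius_um of a voxel centre
sphere_offsets <- function(radius_um, pixel_size_um) {
  r_px <- radius_um / pixel_size_um
  R <- floor(r_px)
  g <- expand.grid(da = -R:R, db = -R:R, dc = -R:R)
  keep <- sqrt(g$da^2 + g$db^2 + g$dc^2) <= r_px
  as.matrix(g[keep, , drop = FALSE])
}

#' Generate one synthetic brain sample with ground truth
#'
#' Draws Poisson focus counts per niche (hemisphere-resolved, with the
#' group's boost multipliers), paints hard-edged spheres of the niche's
#' peak intensity at uniform positions in the niche region, adds the
#' group's diffuse parenchymal components, blurs, adds Gaussian noise and
#' quantizes to 16 bits. Ground truth is recorded before blur and noise.
#' Identical `(spec, group, seed)` give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param group One of `spec$groups`.
#' @param seed Integer random seed.
#' @param sample_id Sample identifier (default derived from group/seed).
#' @return List with `sample` (a [brain_sample()]) and `truth`: per-niche
#'   focus counts and focus-voxel counts, per-hemisphere parenchymal
#'   voxel counts, and the brain-mask voxel count.
#' @export
generate_sample <- function(spec, group, seed,
                            sample_id = sprintf("%s_s%d", group, seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!group %in% spec$groups) {
    stop(sprintf("unknown group '%s' (expected one of %s)", group,
                 paste(spec$groups, collapse = ", ")))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  d <- spec$extents
  ps <- spec$pixel_size_um
  vv <- ps^3
  brain <- phantom_brain_mask(spec)
  mid_lr <- as.integer(floor(d[3] / 2))
  lr_index <- function(idx) ((idx - 1L) %/% (d[1] * d[2])) + 1L  # linear->LR

  edu <- array(0, dim = d)
  any_niche <- array(FALSE, dim = d)
  truth_niche <- data.frame(name = character(0), focus_count = integer(0),
                            focus_voxels = integer(0))
  for (nd in spec$niches) {
    reg <- phantom_niche_region(spec, nd$name)
    idx <- which(reg)
    if (!length(idx)) stop(sprintf("niche '%s' is empty after discretization",
                                   nd$name))
    any_niche <- any_niche | reg
    ipsi <- idx[lr_index(idx) <= mid_lr]
    contra <- idx[lr_index(idx) > mid_lr]
    off <- sphere_offsets(nd$focus_radius_um, ps)
    total_foci <- 0L
    painted <- integer(0)
    for (side in c("ipsi", "contra")) {
      part <- if (side == "ipsi") ipsi else contra
      if (!length(part)) next
      mult <- if (side == "ipsi") nd$ipsi_boost[[group]] else nd$contra_boost[[group]]
      n_foci <- stats::rpois(1L, nd$lambda_per_um3 * mult * length(part) * vv)
      total_foci <- total_foci + n_foci
      if (n_foci == 0L) next
      centers <- part[sample.int(length(part), n_foci, replace = TRUE)]
      ca <- ((centers - 1L) %% d[1]) + 1L
      rest <- (centers - 1L) %/% d[1]
      cb <- (rest %% d[2]) + 1L
      cc <- (rest %/% d[2]) + 1L
      for (f in seq_len(n_foci)) {
        a <- ca[f] + off[, 1L]; b <- cb[f] + off[, 2L]; c3 <- cc[f] + off[, 3L]
        ok <- a >= 1L & a <= d[1] & b >= 1L & b <= d[2] & c3 >= 1L & c3 <= d[3]
        lin <- a[ok] + (b[ok] - 1L) * d[1] + (c3[ok] - 1L) * d[1] * d[2]
        painted <- c(painted, lin)
        edu[lin] <- pmax(edu[lin], nd$peak_intensity)
      }
    }
    truth_niche <- rbind(truth_niche, data.frame(
      name = nd$name, focus_count = total_foci,
      focus_voxels = length(unique(painted))))
  }

  # diffuse parenchymal components (outside every niche region)
  co_ap <- phantom_coords(spec)[[1]]
  in_tel <- co_ap >= spec$parenchyma_ap_span_um[1] &
            co_ap < spec$parenchyma_ap_span_um[2]
  tel <- array(rep(in_tel, times = d[2] * d[3]), dim = d)
  left <- array(FALSE, dim = d)
  if (mid_lr >= 1L) left[, , 1:mid_lr] <- TRUE
  parenchyma <- brain & !any_niche
  focal <- parenchyma & tel & left
  amp_focal <- spec$parenchyma_amplitude[[group]]
  amp_sys <- spec$systemic_amplitude[[group]]
  diffuse <- array(0, dim = d)
  if (amp_sys > 0) diffuse[parenchyma] <- amp_sys
  if (amp_focal > 0) diffuse[focal] <- diffuse[focal] + amp_focal
  signal_vox <- diffuse > 0
  truth_parenchyma <- c(left = sum(signal_vox & left),
                        right = sum(signal_vox & !left))

  sigma_px <- spec$blur_sigma_um / ps
  edu <- gaussian_blur3d(edu + diffuse, sigma_px)
  if (spec$noise_sd > 0) {
    edu <- edu + stats::rnorm(length(edu), 0, spec$noise_sd)
  }
  edu <- round(pmin(pmax(edu, 0), INTENSITY_MAX))

  auto <- array(0, dim = d)
  auto[brain] <- spec$autofluorescence_base
  auto <- gaussian_blur3d(auto, sigma_px)
  if (spec$noise_sd > 0) {
    auto <- auto + stats::rnorm(length(auto), 0, spec$noise_sd)
  }
  auto <- round(pmin(pmax(auto, 0), INTENSITY_MAX))

  smp <- brain_sample(sample_id, group,
                      list(edu = channel_volume(array(as.integer(edu), d)),
                           autofluorescence = channel_volume(array(as.integer(auto), d))),
                      voxel_geometry(ps))
  list(sample = smp,
       truth = list(niches = truth_niche,
                    parenchyma_voxels = truth_parenchyma,
                    brain_voxels = sum(brain)))
}

#' Generate a phantom cohort
#'
#' Per-sample seeds are derived deterministically from the cohort seed and
#' the sample index, so the whole cohort is reproducible from
#' `(spec, n_per_group, seed)`. When `dir` is given, channel TIFFs, a
#' manifest CSV and a ground-truth CSV are written there in the formats the
#' reader side of the package consumes.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_group Named integer vector: group label -> sample count;
#'   default mirrors the cohort sizes of the injury time-course study
#'   (control 5, 1 dpl 4, 3 dpl 4, 7 dpl 5).
#' @param seed Integer cohort seed.
#' @param dir Optional output directory (created if needed).
#' @return List with `samples` (list of [brain_sample()]), `truths`
#'   (per-sample ground truth), `manifest` (data frame), and
#'   `ground_truth` (flat data frame of niche truths).
#' @export
generate_cohort <- function(spec,
                            n_per_group = c(control = 5L, "1dpl" = 4L,
                                            "3dpl" = 4L, "7dpl" = 5L),
                            seed = 1L, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), all(n_per_group >= 1L))
  if (!all(names(n_per_group) %in% spec$groups)) {
    stop("n_per_group names must be spec groups")
  }
  plan <- data.frame(group = rep(names(n_per_group), n_per_group),
                     stringsAsFactors = FALSE)
  plan$replicate <- unlist(lapply(n_per_group, seq_len), use.names = FALSE)
  plan$sample_id <- sprintf("%s_%02d", plan$group, plan$replicate)
  if (anyDuplicated(plan$sample_id)) stop("duplicate sample ids")
  plan$seed <- (as.numeric(seed) * 1009 + seq_len(nrow(plan)) * 9973) %%
    .Machine$integer.max

  samples <- vector("list", nrow(plan))
  truths <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    g <- generate_sample(spec, plan$group[i], plan$seed[i],
                         sample_id = plan$sample_id[i])
    samples[[i]] <- g$sample
    truths[[i]] <- g$truth
  }
  names(samples) <- names(truths) <- plan$sample_id

  manifest <- data.frame(sample_id = plan$sample_id, group = plan$group,
                         pixel_size_um = spec$pixel_size_um,
                         edu_path = paste0(plan$sample_id, "_edu.tif"),
                         autofluorescence_path = paste0(plan$sample_id, "_auto.tif"),
                         seed = plan$seed)
  gt <- do.call(rbind, lapply(plan$sample_id, function(sid) {
    tr <- truths[[sid]]
    cbind(data.frame(sample_id = sid), tr$niches,
          data.frame(parenchyma_left = tr$parenchyma_voxels[["left"]],
                     parenchyma_right = tr$parenchyma_voxels[["right"]],
                     brain_voxels = tr$brain_voxels))
  }))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(plan))) {
      write_channel(samples[[i]]$channels$edu,
                    file.path(dir, manifest$edu_path[i]))
      write_channel(samples[[i]]$channels$autofluorescence,
                    file.path(dir, manifest$autofluorescence_path[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, truths = truths, manifest = manifest,
       ground_truth = gt)
}
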