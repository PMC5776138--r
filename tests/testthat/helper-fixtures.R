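# Fixtures built in code: tiny volumes, samples and phantom specs.

rand_volume <- function(d = c(6, 5, 4), max_int = 65535L) {
  channel_volume(array(sample.int(max_int + 1L, prod(d), replace = TRUE) - 1L,
                       dim = d))
}

make_sample <- function(arr, pixel_size_um = 5, group = "control",
                        sample_id = "s1", channel = "edu") {
  ch <- stats::setNames(list(channel_volume(arr)), channel)
  brain_sample(sample_id, group, ch, voxel_geometry(pixel_size_um))
}

# minimal one-niche phantom: a single anterior midline band, no diffuse
# components; parameters tuned for speed, not realism
tiny_spec <- function(lambda = 2e-4, peak = 30000, blur_um = 2,
                      noise_sd = 200, extents = c(40L, 24L, 24L),
                      focus_radius_um = 7.5) {
  flat <- c(control = 1, "1dpl" = 1, "3dpl" = 1, "7dpl" = 1)
  phantom_spec(
    extents = extents, pixel_size_um = 5,
    brain_semiaxes_um = c(95, 55, 55),
    niches = list(list(
      name = "anterior", type = "midline_band",
      ap_span_um = c(25, 75), lambda_per_um3 = lambda,
      focus_radius_um = focus_radius_um, peak_intensity = peak,
      lr_halfwidth_um = 20, dv_range_um = c(25, 95),
      ipsi_boost = flat, contra_boost = flat)),
    parenchyma_amplitude = c(control = 0, "1dpl" = 0, "3dpl" = 0, "7dpl" = 0),
    systemic_amplitude = c(control = 0, "1dpl" = 0, "3dpl" = 0, "7dpl" = 0),
    blur_sigma_um = blur_um, noise_sd = noise_sd)
}

# brute-force histogram of the 16 intensity bins (independent oracle)
oracle_bin_counts <- function(values) {
  counts <- integer(16)
  for (v in as.integer(values)) {
    b <- min(v %/% 4096L, 15L)
    counts[b + 1L] <- counts[b + 1L] + 1L
  }
  counts
}

# independent Tukey-Kramer computation from first principles:
# studentized range statistic against stats::ptukey
oracle_tukey <- function(data) {
  k <- length(data)
  ns <- lengths(data)
  means <- vapply(data, mean, numeric(1))
  df <- sum(ns) - k
  mse <- sum(vapply(data, function(v) sum((v - mean(v))^2), numeric(1))) / df
  labs <- names(data)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[j] - means[i]) / se
    out[[length(out) + 1L]] <- data.frame(
      group_a = labs[i], group_b = labs[j],
      p_adj = stats::ptukey(q, k, df, lower.tail = FALSE))
  }
  do.call(rbind, out)
}
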