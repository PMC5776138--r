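#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML file. Common fields: `out_dir`, `seed`,
#' `manifest` (for analysis commands), plus one section per command
#' (`generate`, `profile`, `structure`, `slice`, `morphometry`,
#' `compare`) holding its parameters. Paths are resolved relative to the
#' configuration file's directory.
#'
#' @param path YAML configuration path.
#' @return A named list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop(sprintf("config '%s' is not a YAML mapping", path))
  cfg$.base <- dirname(normalizePath(path))
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || cfg$seed != trunc(cfg$seed)) {
      stop("'seed' must be an integer")
    }
  }
  for (p in c("segment_um", "stride")) {
    v <- cfg[[p]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      stop(sprintf("'%s' must be positive", p))
    }
  }
  if (!is.null(cfg$alpha) && !(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("'alpha' must lie in (0, 1)")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

resolve_path <- function(p, base) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

#' Run one pipeline command
#'
#' The command-line entry point (`inst/cli/optquant`) is a thin wrapper
#' over this function. Every command writes CSV artifacts into `out_dir`
#' plus a `run_log.txt` recording the resolved parameters and package
#' version; outputs are deterministic given the configuration and seed.
#' On failure, files created by the failed run are removed.
#'
#' @param command One of `"generate"`, `"profile"`, `"structure"`,
#'   `"slice"`, `"morphometry"`, `"compare"`.
#' @param config A `run_config` from [load_run_config()], or a path to a
#'   YAML file.
#' @param out_dir Output directory override.
#' @param seed Seed override (required by `generate`).
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_pipeline <- function(command = c("generate", "profile", "structure",
                                     "slice", "morphometry", "compare"),
                         config, out_dir = NULL, seed = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  base <- config$.base %||% "."
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  out_dir <- resolve_path(out_dir, base)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- seed %||% config$seed
  written <- character(0)
  on_fail_cleanup <- function() for (f in written) if (file.exists(f)) unlink(f)

  result <- tryCatch({
    art <- switch(command,
      generate = cmd_generate(config, out_dir, seed),
      profile = cmd_profile(config, out_dir, base),
      structure = cmd_structure(config, out_dir, base),
      slice = cmd_slice(config, out_dir, base),
      morphometry = cmd_morphometry(config, out_dir, base),
      compare = cmd_compare(config, out_dir, base))
    written <<- art
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      sprintf("optquant %s", as.character(utils::packageVersion("optquant"))),
      sprintf("command: %s", command),
      sprintf("seed: %s", if (is.null(seed)) "none" else seed),
      "resolved config:",
      utils::capture.output(utils::str(
        config[setdiff(names(config), ".base")]))), log_path)
    c(art, log_path)
  }, error = function(e) {
    on_fail_cleanup()
    stop(sprintf("command '%s' failed: %s", command, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cmd_generate <- function(config, out_dir, seed) {
  if (is.null(seed)) stop("'generate' requires a seed")
  gc_ <- config$generate %||% list()
  npg <- gc_$n_per_group %||% list(control = 5L, "1dpl" = 4L,
                                   "3dpl" = 4L, "7dpl" = 5L)
  npg <- stats::setNames(as.integer(unlist(npg)), names(npg))
  spec <- phantom_spec()
  coh <- generate_cohort(spec, npg, seed = as.integer(seed), dir = out_dir)
  c(file.path(out_dir, coh$manifest$edu_path),
    file.path(out_dir, coh$manifest$autofluorescence_path),
    file.path(out_dir, "manifest.csv"),
    file.path(out_dir, "ground_truth.csv"))
}

pipeline_cohort <- function(config, base) {
  if (is.null(config$manifest)) stop("config lacks a 'manifest' path")
  man <- load_manifest(resolve_path(config$manifest, base))
  load_cohort(man)
}

cmd_profile <- function(config, out_dir, base) {
  samples <- pipeline_cohort(config, base)
  pc <- config$profile %||% list()
  seg_um <- pc$segment_um %||% 20
  channel <- pc$channel %||% "edu"
  profiles <- lapply(samples, sample_profile, channel = channel,
                     segment_um = seg_um)
  long <- do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(sample_id = attr(p, "sample_id"),
                     group = attr(p, "group")),
          p[c("segment_index", "ap_start_um", "ap_stop_um",
              "mean_intensity", "n_nonblack")])
  }))
  f1 <- file.path(out_dir, "profiles.csv")
  utils::write.csv(long, f1, row.names = FALSE)
  groups <- split(profiles, vapply(profiles, attr, character(1), "group"))
  gp <- do.call(rbind, lapply(names(groups), function(g) {
    q <- group_profile(groups[[g]], group = g)
    cbind(data.frame(group = g),
          q[c("segment_index", "mean", "sem", "n")])
  }))
  f2 <- file.path(out_dir, "group_profiles.csv")
  utils::write.csv(gp, f2, row.names = FALSE)
  c(f1, f2)
}

load_config_box_rois <- function(config, section, base) {
  rois <- config[[section]]$rois
  if (is.null(rois)) stop(sprintf("config section '%s' lacks 'rois'", section))
  out <- lapply(rois, function(r) {
    if (!is.null(r$path)) read_box_roi(resolve_path(r$path, base))
    else box_roi(unlist(r$ap), unlist(r$dv), unlist(r$lr))
  })
  names(out) <- vapply(rois, function(r) r$name %||% "roi", character(1))
  out
}

cmd_structure <- function(config, out_dir, base) {
  samples <- pipeline_cohort(config, base)
  sc <- config$structure %||% list()
  bins <- as.integer(unlist(sc$bins_used %||% nonblack_bins()))
  rois <- load_config_box_rois(config, "structure", base)
  res <- list()
  for (nm in names(rois)) {
    for (s in samples) {
      res[[length(res) + 1L]] <- structure_volume(
        s, channel = sc$channel %||% "edu", roi = rois[[nm]],
        bins_used = bins, roi_name = nm)
    }
  }
  f <- file.path(out_dir, "structure_volumes.csv")
  utils::write.csv(volume_table(res), f, row.names = FALSE)
  f
}

cmd_slice <- function(config, out_dir, base) {
  samples <- pipeline_cohort(config, base)
  sc <- config$slice %||% list()
  bins <- as.integer(unlist(sc$bins_used %||% 1:3))
  niches <- sc$niches
  if (is.null(niches)) stop("config section 'slice' lacks 'niches'")
  res <- list()
  for (n in niches) {
    roi <- read_niche_roi(resolve_path(n$path, base))
    for (s in samples) {
      res[[length(res) + 1L]] <- slice_volume(
        s, channel = sc$channel %||% "edu", niche = roi,
        bins_used = bins, roi_name = n$name %||% "niche")
    }
  }
  f <- file.path(out_dir, "slice_volumes.csv")
  utils::write.csv(volume_table(res), f, row.names = FALSE)
  f
}

cmd_morphometry <- function(config, out_dir, base) {
  samples <- pipeline_cohort(config, base)
  mc <- config$morphometry %||% list()
  thr <- mc$threshold %||% "otsu"
  lc <- isTRUE(mc$largest_component)
  rows <- lapply(samples, function(s) {
    mask <- segment_brain(s$channels$autofluorescence, threshold = thr,
                          largest_component = lc)
    data.frame(sample_id = s$sample_id, structure = "whole_brain",
               threshold = attr(mask, "threshold"), voxels = sum(mask),
               volume_um3 = mask_volume(mask, s$geometry))
  })
  f <- file.path(out_dir, "morphometry.csv")
  utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
  f
}

cmd_compare <- function(config, out_dir, base) {
  cc <- config$compare %||% list()
  if (is.null(cc$input)) stop("config section 'compare' lacks 'input'")
  tab <- utils::read.csv(resolve_path(cc$input, base))
  need <- c("sample_id", "group", "roi", "analysis", "volume_um3")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop(sprintf("compare input lacks columns: %s",
                 paste(missing, collapse = ", ")))
  }
  alpha <- cc$alpha %||% 0.05
  out <- list()
  for (key in unique(paste(tab$roi, tab$analysis, sep = "|"))) {
    sub <- tab[paste(tab$roi, tab$analysis, sep = "|") == key, ]
    data <- split(sub$volume_um3, sub$group)
    cmp <- compare_groups(data, alpha = alpha)
    out[[length(out) + 1L]] <- comparison_table(
      cmp, roi = sub$roi[1L], analysis = sub$analysis[1L])
  }
  f <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(do.call(rbind, out), f, row.names = FALSE)
  f
}
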