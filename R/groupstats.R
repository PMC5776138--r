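#' Mean and standard error of the mean
#'
#' @param values Numeric vector, `n >= 1`.
#' @return Named numeric vector `c(mean, sem)`; SEM uses the sample
#'   standard deviation (n - 1 denominator) over `sqrt(n)` and is 0 for a
#'   single observation.
#' @export
mean_sem <- function(values) {
  if (!length(values)) stop("need at least one value")
  n <- length(values)
  sem <- if (n > 1L) stats::sd(values) / sqrt(n) else 0
  c(mean = mean(values), sem = sem)
}

#' One-way ANOVA with Tukey post-hoc across treatment groups
#'
#' The statistical layer used for all volume and intensity comparisons:
#' one-way ANOVA across groups followed by Tukey's HSD pairwise
#' comparisons (Tukey-Kramer for unequal group sizes), significance at
#' `alpha`. Pairwise records are emitted even when the omnibus test is
#' non-significant, flagged with the omnibus outcome, so consumers can
#' filter rather than receive silently empty output. Data with zero
#' variance everywhere yield a defined "no test" outcome (`NA` statistics,
#' nothing significant) rather than an error.
#'
#' @param data Named list: group label -> numeric vector of measurements
#'   (at least 2 groups, each with n >= 2).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An object of class `group_comparison`: list with `groups`
#'   (per-group n/mean/sem), `anova_F`, `anova_p`, `omnibus_significant`,
#'   `pairs` (data frame: `group_a`, `group_b`, `mean_diff`, `p_adj`,
#'   `significant`), and `alpha`.
#' @export
compare_groups <- function(data, alpha = 0.05) {
  if (!is.list(data) || length(data) < 2L || is.null(names(data))) {
    stop("'data' must be a named list with at least two groups")
  }
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
  ns <- lengths(data)
  if (any(ns < 2L)) {
    stop(sprintf("every group needs n >= 2 (offending: %s)",
                 paste(names(data)[ns < 2L], collapse = ", ")))
  }
  groups <- data.frame(
    group = names(data), n = as.integer(ns),
    mean = vapply(data, mean, numeric(1)),
    sem = vapply(data, function(v) mean_sem(v)[["sem"]], numeric(1)),
    row.names = NULL)

  labs <- names(data)
  pair_idx <- utils::combn(length(labs), 2L)
  df <- data.frame(value = unlist(data, use.names = FALSE),
                   group = factor(rep(labs, ns), levels = labs))

  if (stats::var(df$value) == 0) {
    # all observations identical: F is 0/0, report "no test"
    pairs <- data.frame(group_a = labs[pair_idx[1L, ]],
                        group_b = labs[pair_idx[2L, ]],
                        mean_diff = 0, p_adj = NA_real_,
                        significant = FALSE)
    return(structure(list(groups = groups, anova_F = NA_real_,
                          anova_p = NA_real_, omnibus_significant = FALSE,
                          pairs = pairs, alpha = alpha),
                     class = "group_comparison"))
  }

  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  Fv <- an[["F value"]][1L]
  pv <- an[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group

  # recover pair labels in a fixed group_a (earlier) / group_b (later) order
  split_lab <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(
    group_a = vapply(split_lab, function(x) paste(rev(x)[-1], collapse = "-"),
                     character(1)),
    group_b = NA_character_, mean_diff = NA_real_, p_adj = NA_real_)
  # TukeyHSD rows are "later-earlier"; map robustly via the known labels
  pairs <- do.call(rbind, lapply(seq_len(nrow(tk)), function(i) {
    rn <- rownames(tk)[i]
    hit <- NULL
    for (k in seq_len(ncol(pair_idx))) {
      a <- labs[pair_idx[1L, k]]; b <- labs[pair_idx[2L, k]]
      if (rn == paste0(b, "-", a)) { hit <- c(a, b); break }
      if (rn == paste0(a, "-", b)) { hit <- c(b, a); break }
    }
    if (is.null(hit)) stop(sprintf("cannot parse Tukey pair label '%s'", rn))
    data.frame(group_a = hit[1L], group_b = hit[2L],
               mean_diff = mean(data[[hit[2L]]]) - mean(data[[hit[1L]]]),
               p_adj = tk[i, "p adj"])
  }))
  pairs$significant <- !is.na(pairs$p_adj) & pairs$p_adj < alpha
  structure(list(groups = groups, anova_F = Fv, anova_p = pv,
                 omnibus_significant = is.finite(pv) && pv < alpha,
                 pairs = pairs, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA with Tukey post-hoc\n")
  print(x$groups, row.names = FALSE)
  if (is.na(x$anova_F)) {
    cat("ANOVA: undefined (zero variance) -> no significance reported\n")
  } else {
    cat(sprintf("ANOVA: F = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
                x$anova_F, x$anova_p,
                if (x$omnibus_significant) "" else "not ", x$alpha))
  }
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Tabulate a group comparison for CSV export
#'
#' @param comparison A `group_comparison`.
#' @param roi,analysis Labels prepended to every pairwise row.
#' @return Data frame with columns `roi`, `analysis`, `group_a`,
#'   `group_b`, `mean_diff`, `p_adj`, `significant`, `anova_F`, `anova_p`.
#' @export
comparison_table <- function(comparison, roi = "", analysis = "") {
  stopifnot(inherits(comparison, "group_comparison"))
  cbind(data.frame(roi = roi, analysis = analysis),
        comparison$pairs,
        data.frame(anova_F = comparison$anova_F,
                   anova_p = comparison$anova_p))
}
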