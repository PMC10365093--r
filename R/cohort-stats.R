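#' Two-sample Mann-Whitney U comparison
#'
#' Rank-based two-sided test for a location difference between two
#' patient groups.  The exact permutation null is used when
#' \code{n_x * n_y <= 400} and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction.  The U
#' statistic is reported for the first sample.
#'
#' @param x,y numeric samples (e.g. a per-patient metric in each group).
#' @param name label for the comparison.
#' @param exact_max largest \code{n_x * n_y} for which the exact null is
#'   enumerated.
#' @return An object of class \code{"group_comparison"}: a one-row data
#'   frame with \code{name}, \code{u_stat}, \code{p_value}, \code{n_x},
#'   \code{n_y}, \code{method} and \code{degenerate} (TRUE when all
#'   values across both groups are identical, in which case p = 1).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, name = "comparison", exact_max = 400) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be nonempty")
  if (!all(is.finite(c(x, y)))) stop("non-finite values in samples")
  nx <- length(x); ny <- length(y)
  degenerate <- length(unique(c(x, y))) == 1L
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (nx * ny <= exact_max) && !ties
  if (degenerate) {
    u <- nx * ny / 2
    p <- 1
    method <- "degenerate"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    u <- unname(wt$statistic)
    p <- wt$p.value
    if (is.na(p)) p <- 1     # zero-variance rank configuration
    method <- if (exact) "exact" else "normal-approx"
  }
  structure(data.frame(name = name, u_stat = u, p_value = p,
                       n_x = nx, n_y = ny, method = method,
                       degenerate = degenerate),
            class = c("group_comparison", "data.frame"))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure at level \code{alpha}: with ordered p-values
#' \code{p_(1) <= ... <= p_(m)}, all tests up to the largest k with
#' \code{p_(k) <= k alpha / m} are rejected.  Adjusted values are the
#' standard monotone BH q-values; a test is rejected iff its q-value is
#' at most \code{alpha}.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha target false-discovery rate (default 0.05).
#' @return A list with \code{reject} (logical) and \code{adjusted}
#'   (q-values), in the input order; empty input gives empty output.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L)
    return(list(reject = logical(0), adjusted = numeric(0)))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(reject = adjusted <= alpha, adjusted = adjusted)
}

#' Kolmogorov-Smirnov check of normality
#'
#' One-sample KS test of a sample against a normal distribution with the
#' sample's own mean and standard deviation.  Because the reference
#' parameters are estimated from the same data, the p-value is
#' conservative relative to the Lilliefors-corrected variant; it is used
#' here only to justify reporting medians alongside means.
#'
#' @param x numeric sample, n >= 3.
#' @return The KS p-value, with attribute \code{degenerate = TRUE} (and
#'   p = 0) when the sample has zero variance.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("normality check needs at least 3 observations")
  if (stats::sd(x) == 0)
    return(structure(0, degenerate = TRUE))
  p <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  structure(p, degenerate = FALSE)
}

#' Cohort summary in median +/- SD form
#'
#' Summarizes a per-patient statistic across a cohort as its median and
#' the (n-1 denominator) standard deviation -- the reporting style used
#' for skewed motion metrics, where the median locates the typical
#' patient and the SD conveys spread.
#'
#' @param values per-patient values.
#' @return An object of class \code{"cohort_summary"}: a one-row data
#'   frame with \code{median}, \code{sd} and \code{n}.  For n = 1 the SD
#'   is undefined and reported as 0 with attribute \code{sd_defined =
#'   FALSE}.
#' @export
cohort_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty cohort")
  s <- if (length(values) > 1L) stats::sd(values) else 0
  structure(data.frame(median = stats::median(values), sd = s,
                       n = length(values)),
            class = c("cohort_summary", "data.frame"),
            sd_defined = length(values) > 1L)
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s ± %s (median ± SD), n = %d\n",
              format(x$median, digits = digits),
              format(x$sd, digits = digits), x$n))
  invisible(x)
}

#' Run the cohort comparison families
#'
#' Builds the three families of Mann-Whitney comparisons for a two-group
#' cohort and corrects each family for multiple testing independently:
#' \describe{
#'   \item{metrics}{each of the four displacement metrics, group 1 vs
#'     group 2;}
#'   \item{axes (per group)}{within each group, the per-patient mean
#'     absolute translation components compared between axes (z vs x,
#'     z vs y, x vs y) and likewise the rotation components (x vs y,
#'     x vs z, y vs z);}
#'   \item{regions (per group)}{within each group and region, the
#'     per-patient median absolute displacement compared between axes.}
#' }
#'
#' @param metrics data frame of per-patient metrics with columns
#'   \code{patient_id}, \code{group}, \code{mean_disp_mm},
#'   \code{median_disp_mm}, \code{max_disp_mm}, \code{motion_free_frac}.
#' @param axes optional data frame of per-patient axis summaries with
#'   columns \code{patient_id}, \code{group}, \code{channel}, \code{axis},
#'   \code{mean_abs} (long form, as emitted by \code{\link{axis_summaries}}
#'   plus identifiers).
#' @param regions optional data frame of per-patient region-axis
#'   summaries with columns \code{patient_id}, \code{group}, \code{label},
#'   \code{axis}, \code{median_abs_disp_mm}.
#' @param alpha per-family false-discovery rate (default 0.05).
#' @return A data frame of class \code{"motion_comparisons"}: one row per
#'   test with \code{family}, \code{comparison}, \code{n_x}, \code{n_y},
#'   \code{u_stat}, \code{p_value}, \code{p_adjusted},
#'   \code{passed_fdr} and \code{alpha}.
#' @export
cohort_comparisons <- function(metrics, axes = NULL, regions = NULL,
                               alpha = 0.05) {
  # radix sort: locale-independent group ordering
  groups <- sort(unique(as.character(metrics$group)), method = "radix")
  if (length(groups) != 2L)
    stop("metrics must contain exactly two groups")
  g1 <- metrics[metrics$group == groups[1], ]
  g2 <- metrics[metrics$group == groups[2], ]
  if (nrow(g1) == 0L || nrow(g2) == 0L) stop("a group has no patients")

  rows <- list()
  add <- function(family, cmp) {
    cmp$family <- family
    rows[[length(rows) + 1L]] <<- cmp
  }

  for (m in c("mean_disp_mm", "median_disp_mm", "max_disp_mm",
              "motion_free_frac")) {
    add("metrics", mann_whitney_u(
      g1[[m]], g2[[m]],
      name = sprintf("%s: %s vs %s", m, groups[1], groups[2])))
  }

  axis_pairs <- list(translation = list(c("z", "x"), c("z", "y"), c("x", "y")),
                     rotation    = list(c("x", "y"), c("x", "z"), c("y", "z")))
  if (!is.null(axes)) {
    for (g in groups) {
      for (ch in names(axis_pairs)) {
        sub <- axes[axes$group == g & axes$channel == ch, ]
        for (pr in axis_pairs[[ch]]) {
          add(paste0("axes_", g), mann_whitney_u(
            sub$mean_abs[sub$axis == pr[1]],
            sub$mean_abs[sub$axis == pr[2]],
            name = sprintf("%s |%s| vs |%s| (%s)", ch, pr[1], pr[2], g)))
        }
      }
    }
  }

  if (!is.null(regions)) {
    pairs <- list(c("x", "y"), c("x", "z"), c("y", "z"))
    for (g in groups) {
      sub_g <- regions[regions$group == g, ]
      for (lab in unique(sub_g$label)) {
        sub <- sub_g[sub_g$label == lab, ]
        for (pr in pairs) {
          add(paste0("regions_", g), mann_whitney_u(
            sub$median_abs_disp_mm[sub$axis == pr[1]],
            sub$median_abs_disp_mm[sub$axis == pr[2]],
            name = sprintf("%s |%s| vs |%s| (%s)", lab, pr[1], pr[2], g)))
        }
      }
    }
  }

  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(family = r$family, comparison = r$name, n_x = r$n_x,
               n_y = r$n_y, u_stat = r$u_stat, p_value = r$p_value,
               method = r$method)
  }))
  tab$p_adjusted <- NA_real_
  tab$passed_fdr <- NA
  for (fam in unique(tab$family)) {
    idx <- tab$family == fam
    fc <- fdr_correct(tab$p_value[idx], alpha)
    tab$p_adjusted[idx] <- fc$adjusted
    tab$passed_fdr[idx] <- fc$reject
  }
  tab$alpha <- alpha
  rownames(tab) <- NULL
  structure(tab, class = c("motion_comparisons", "data.frame"),
            groups = groups)
}

#' @export
print.motion_comparisons <- function(x, digits = 4, ...) {
  cat("Cohort comparisons (Mann-Whitney U, BH-FDR per family)\n")
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, digits)
  df$p_adjusted <- signif(df$p_adjusted, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
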