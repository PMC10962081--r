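# Mean-shift clustering of single-mark localisations and FWHM cluster-width
# quantification.

#' Mean-shift clustering parameters
#'
#' @param bandwidth_sigma Gaussian kernel bandwidth in nm. The default,
#'   50 nm, matches the typical nucleosome-cluster scale.
#' @param min_points Minimum localisations for a mode to be kept as a
#'   cluster (default 15).
#' @param merge_radius Modes closer than this are merged into one cluster
#'   (default `bandwidth_sigma / 2`).
#' @param convergence_tol Mean-shift stopping tolerance in nm.
#' @param max_iter Iteration cap per point.
#' @param kernel `"gaussian"` (default) or `"flat"` (uniform weights within
#'   one bandwidth), the latter for sensitivity checks.
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(bandwidth_sigma = 50, min_points = 15,
                              merge_radius = bandwidth_sigma / 2,
                              convergence_tol = 0.1, max_iter = 500,
                              kernel = c("gaussian", "flat")) {
  kernel <- match.arg(kernel)
  stopifnot(bandwidth_sigma > 0, min_points >= 1, merge_radius >= 0,
            convergence_tol > 0, max_iter >= 1)
  structure(list(bandwidth_sigma = bandwidth_sigma,
                 min_points = as.integer(min_points),
                 merge_radius = merge_radius,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter), kernel = kernel),
            class = "clustering_params")
}

#' Cluster one mark's localisations by mean shift
#'
#' Runs kernel mean shift on the localisations carrying `mark` (per ROI if
#' ROI labels are present), merges converged modes within
#' `params$merge_radius`, and retains modes with at least
#' `params$min_points` members. Points whose trajectory converges to a
#' discarded mode stay unassigned. Cluster centres are member means and
#' each cluster's FWHM is estimated with [estimate_fwhm()].
#'
#' @param table A [localisation_table()].
#' @param mark Mark label to cluster.
#' @param params A [clustering_params()].
#' @return Object of class `cluster_set`: list with `mark`, `params`,
#'   `clusters` (data frame: `cluster_id`, `roi`, `x`, `y`, `n`,
#'   `fwhm`), `members` (list of row indices into `table` per cluster) and
#'   `assignment` (per-row cluster id or `NA`).
#' @export
mean_shift_cluster <- function(table, mark, params = clustering_params()) {
  stopifnot(inherits(table, "localisation_table"),
            inherits(params, "clustering_params"))
  sel <- which(table$mark == mark)
  clusters <- list()
  members <- list()
  assignment <- rep(NA_integer_, nrow(table))
  next_id <- 1L
  groups <- roi_groups(table)
  for (gname in names(groups)) {
    rows <- intersect(groups[[gname]], sel)
    if (length(rows) == 0L) next
    xs <- table$x[rows]
    ys <- table$y[rows]
    modes <- .ms_modes(xs, ys, params$bandwidth_sigma, params$kernel,
                       params$convergence_tol, params$max_iter, 3.7)
    lab <- merge_modes(modes, params$merge_radius)
    for (m in sort(unique(lab))) {
      in_m <- rows[lab == m]
      if (length(in_m) < params$min_points) next
      fw <- tryCatch(estimate_fwhm(list(member_rows = in_m), table),
                     error = function(e) NA_real_)
      clusters[[length(clusters) + 1L]] <- data.frame(
        cluster_id = next_id,
        roi = if (gname == "<all>") NA_character_ else gname,
        x = mean(table$x[in_m]), y = mean(table$y[in_m]),
        n = length(in_m), fwhm = fw, stringsAsFactors = FALSE)
      members[[next_id]] <- in_m
      assignment[in_m] <- next_id
      next_id <- next_id + 1L
    }
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = integer(), roi = character(), x = numeric(),
               y = numeric(), n = integer(), fwhm = numeric(),
               stringsAsFactors = FALSE)
  structure(list(mark = mark, params = params, clusters = cl,
                 members = members, assignment = assignment),
            class = "cluster_set")
}

# Group converged mode positions: modes within merge_radius of an existing
# group representative join it. Mode scatter after convergence is far below
# merge_radius, so the grouping does not depend on input order in practice.
merge_modes <- function(modes, merge_radius) {
  n <- nrow(modes)
  lab <- integer(n)
  reps <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    if (nrow(reps) > 0) {
      d2 <- (reps[, 1] - modes[i, 1])^2 + (reps[, 2] - modes[i, 2])^2
      j <- which(d2 <= merge_radius^2)
      if (length(j)) {
        lab[i] <- j[which.min(d2[j])]
        next
      }
    }
    reps <- rbind(reps, modes[i, , drop = FALSE])
    lab[i] <- nrow(reps)
  }
  lab
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set for '%s': %d cluster(s) (sigma = %g nm, min %d pts)\n",
              x$mark, nrow(x$clusters), x$params$bandwidth_sigma,
              x$params$min_points))
  if (nrow(x$clusters) > 0)
    cat(sprintf("  median FWHM %.1f nm, median size %d localisations\n",
                stats::median(x$clusters$fwhm, na.rm = TRUE),
                as.integer(stats::median(x$clusters$n))))
  invisible(x)
}

#' @export
write_results.cluster_set <- function(result, path) {
  meta <- list(mark = result$mark,
               bandwidth_sigma = result$params$bandwidth_sigma,
               min_points = result$params$min_points,
               n_clusters = nrow(result$clusters))
  write_sections(meta, result$clusters, "cluster_set", path)
}

#' Estimate a cluster's FWHM width
#'
#' Fits an isotropic 2-D Gaussian to member displacements from the member
#' mean: `sigma^2` is the bias-corrected maximum-likelihood estimate
#' `sum(|r_i - rbar|^2) / (2 (n - 1))`, de-biased on the sigma scale with
#' the chi-distribution correction factor for `2(n - 1)` degrees of
#' freedom, and FWHM = `2 sqrt(2 ln 2) sigma`.
#'
#' @param cluster Either a list with element `member_rows` (row indices
#'   into `table`), or a two-column coordinate matrix (then `table` is
#'   ignored).
#' @param table The [localisation_table()] the indices refer to.
#' @return FWHM in nm.
#' @export
estimate_fwhm <- function(cluster, table = NULL) {
  if (is.matrix(cluster)) {
    xy <- cluster
  } else {
    stopifnot(!is.null(table))
    xy <- cbind(table$x[cluster$member_rows], table$y[cluster$member_rows])
  }
  n <- nrow(xy)
  if (n < 2L) stop("FWHM estimation needs at least 2 members")
  d2 <- (xy[, 1] - mean(xy[, 1]))^2 + (xy[, 2] - mean(xy[, 2]))^2
  ss <- sum(d2)
  if (ss == 0) stop("degenerate cluster: all members coincident")
  k <- 2 * (n - 1)  # chi-square dof of the summed squared deviations
  c4 <- sqrt(2 / k) * exp(lgamma((k + 1) / 2) - lgamma(k / 2))
  sigma <- sqrt(ss / k) / c4
  2 * sqrt(2 * log(2)) * sigma
}

#' Summarise a cluster set's width distribution
#'
#' @param clusterset A [mean_shift_cluster()] result with >= 1 cluster.
#' @param bins Histogram bin edges in nm covering all widths (default
#'   10-nm bins spanning the data).
#' @return Object of class `width_distribution`: widths, median, IQR
#'   (linear-interpolation quantiles), and a probability-normalised
#'   histogram.
#' @export
width_distribution <- function(clusterset, bins = NULL) {
  stopifnot(inherits(clusterset, "cluster_set"))
  widths <- clusterset$clusters$fwhm
  widths <- widths[is.finite(widths)]
  if (length(widths) == 0L) stop("empty cluster set: no widths to summarise")
  if (is.null(bins))
    bins <- seq(10 * floor(min(widths) / 10), 10 * ceiling(max(widths) / 10),
                by = 10)
  if (min(widths) < bins[1] || max(widths) > bins[length(bins)])
    stop(sprintf("widths [%.1f, %.1f] nm fall outside bin range [%g, %g]",
                 min(widths), max(widths), bins[1], bins[length(bins)]))
  h <- graphics::hist(widths, breaks = bins, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(mark = clusterset$mark, widths = widths,
                 median = stats::median(widths),
                 iqr = stats::quantile(widths, c(0.25, 0.75), names = FALSE),
                 bin_edges = bins, probability = h$counts / length(widths)),
            class = "width_distribution")
}

#' @export
write_results.width_distribution <- function(result, path) {
  meta <- list(mark = result$mark, n = length(result$widths),
               median = result$median, iqr_low = result$iqr[1],
               iqr_high = result$iqr[2])
  tab <- data.frame(bin_low = result$bin_edges[-length(result$bin_edges)],
                    bin_high = result$bin_edges[-1],
                    probability = result$probability)
  write_sections(meta, tab, "width_distribution", path)
}

#' Compare two width distributions
#'
#' Reports the percent difference of medians,
#' `100 * (median_b - median_a) / median_a`, and a two-sided
#' Mann-Whitney/Wilcoxon rank-sum p-value.
#'
#' @param a,b [width_distribution()] objects (reference first).
#' @return List with `percent_median_difference`, `p_value`, `median_a`,
#'   `median_b`, `n_a`, `n_b`.
#' @export
compare_widths <- function(a, b) {
  stopifnot(inherits(a, "width_distribution"),
            inherits(b, "width_distribution"))
  if (length(a$widths) < 2L || length(b$widths) < 2L)
    stop("width comparison needs at least 2 clusters per group")
  wt <- suppressWarnings(stats::wilcox.test(a$widths, b$widths,
                                            alternative = "two.sided"))
  list(mark_a = a$mark, mark_b = b$mark,
       median_a = a$median, median_b = b$median,
       percent_median_difference = 100 * (b$median - a$median) / a$median,
       p_value = wt$p.value, n_a = length(a$widths), n_b = length(b$widths))
}

#' Pairwise width comparisons with Holm adjustment
#'
#' Runs [compare_widths()] of one reference distribution against several
#' others and Holm-adjusts the p-values when more than two comparisons are
#' requested.
#'
#' @param reference A [width_distribution()] (e.g. total-histone widths).
#' @param others Named list of [width_distribution()] objects.
#' @return Data frame of comparisons with `p_adjusted`.
#' @export
compare_widths_multi <- function(reference, others) {
  res <- lapply(others, function(o) compare_widths(reference, o))
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(mark = r$mark_b, median_reference = r$median_a,
               median = r$median_b,
               percent_median_difference = r$percent_median_difference,
               p_value = r$p_value, stringsAsFactors = FALSE)))
  df$p_adjusted <- if (nrow(df) > 2L) stats::p.adjust(df$p_value, "holm")
  else df$p_value
  rownames(df) <- NULL
  df
}
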