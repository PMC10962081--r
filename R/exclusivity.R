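# Mutual-exclusivity statistics for two-colour localisation data: overlap
# fractions relative to cluster centres, and the cross-class mark
# connection function with a random-labelling Monte-Carlo envelope.

#' Fraction of one mark's localisations overlapping the other's clusters
#'
#' For each ROI, computes the fraction of `other_mark` localisations whose
#' nearest `clusters` centre lies within `radius` (default 50 nm, the
#' nominal cluster half-width), and the median fraction across ROIs. The
#' complementary analysis — clustering the other mark instead — is obtained
#' by swapping roles, as both directions should be examined to avoid bias
#' from unequal localisation abundance.
#'
#' @param clusters A [mean_shift_cluster()] result (non-empty).
#' @param other A [localisation_table()] containing the other mark.
#' @param other_mark Mark label whose localisations are tested; defaults
#'   to the single mark in `other` different from `clusters$mark`.
#' @param radius Overlap radius in nm.
#' @param pooled If `TRUE`, also compute the fraction pooled over all ROIs.
#' @return Object of class `overlap_result` with `per_roi` (data frame:
#'   `roi`, `n_other`, `n_within`, `fraction`), `median_fraction` and,
#'   if requested, `pooled_fraction`.
#' @export
overlap_fraction <- function(clusters, other, other_mark = NULL,
                             radius = 50, pooled = FALSE) {
  stopifnot(inherits(clusters, "cluster_set"),
            inherits(other, "localisation_table"), radius > 0)
  if (nrow(clusters$clusters) == 0L)
    stop("overlap undefined: cluster set is empty")
  if (is.null(other_mark)) {
    cand <- setdiff(unique(other$mark), clusters$mark)
    if (length(cand) != 1L)
      stop("other_mark is ambiguous; pass it explicitly")
    other_mark <- cand
  }
  pts <- other[other$mark == other_mark, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("no localisations of mark '", other_mark, "' in the table")
  ctr <- clusters$clusters
  per_roi <- list()
  groups <- if (all(is.na(pts$roi))) list("<all>" = seq_len(nrow(pts)))
            else split(seq_len(nrow(pts)), pts$roi)
  for (g in names(groups)) {
    rows <- groups[[g]]
    cc <- if (g == "<all>") ctr else ctr[!is.na(ctr$roi) & ctr$roi == g, ,
                                         drop = FALSE]
    if (nrow(cc) == 0L) {
      warning("ROI '", g, "' has no clusters; skipped from overlap analysis")
      next
    }
    # nearest-centre distance per other-mark localisation
    d2min <- rep(Inf, length(rows))
    for (j in seq_len(nrow(cc))) {
      d2 <- (pts$x[rows] - cc$x[j])^2 + (pts$y[rows] - cc$y[j])^2
      d2min <- pmin(d2min, d2)
    }
    n_within <- sum(d2min <= radius^2)
    per_roi[[length(per_roi) + 1L]] <- data.frame(
      roi = if (g == "<all>") NA_character_ else g,
      n_other = length(rows), n_within = n_within,
      fraction = n_within / length(rows), stringsAsFactors = FALSE)
  }
  if (length(per_roi) == 0L)
    stop("no ROI had both clusters and '", other_mark, "' localisations")
  per_roi <- do.call(rbind, per_roi)
  out <- structure(list(clustered_mark = clusters$mark,
                        other_mark = other_mark, radius = radius,
                        per_roi = per_roi,
                        median_fraction = stats::median(per_roi$fraction)),
                   class = "overlap_result")
  if (pooled)
    out$pooled_fraction <- sum(per_roi$n_within) / sum(per_roi$n_other)
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap: %s localisations within %g nm of %s cluster centres\n",
    x$other_mark, x$radius, x$clustered_mark))
  cat(sprintf("  median fraction %.3f (%.1f%%) over %d ROI(s)\n",
              x$median_fraction, 100 * x$median_fraction, nrow(x$per_roi)))
  invisible(x)
}

#' @export
write_results.overlap_result <- function(result, path) {
  meta <- list(clustered_mark = result$clustered_mark,
               other_mark = result$other_mark, radius = result$radius,
               median_fraction = result$median_fraction)
  write_sections(meta, result$per_roi, "overlap_result", path)
}

#' Cross-class mark connection function with random-labelling envelope
#'
#' For each distance bin, `p_cross` is the proportion of unordered
#' within-ROI point pairs at that separation whose members carry different
#' marks. Dividing by `2 p_A p_B` (with `p_A`, `p_B` the observed class
#' proportions) normalises the random-labelling expectation to 1;
#' `centred` is `normalised - 1`, so values near 0 indicate random
#' mixing, below 0 repulsion (exclusivity) and above 0 attraction. The
#' null envelope holds positions fixed and randomly reallocates labels
#' (within ROI) `n_permutations` times, reporting pointwise 2.5% / 97.5%
#' quantiles of the centred statistic.
#'
#' @param table A [localisation_table()] containing both marks (other
#'   marks are ignored).
#' @param mark_a,mark_b The two mark labels.
#' @param bin_edges Strictly increasing distance bin edges in nm; the
#'   default 20-nm bins from 0 to 500 nm match the STED pixel pitch.
#' @param n_permutations Random-labelling replicates (default 199).
#' @param seed Optional integer seed for the permutations.
#' @param window Optional `c(width, height)` in nm: computes toroidal
#'   (periodic) pair distances for rectangular simulation windows. The
#'   default applies no edge correction.
#' @return Object of class `mcf_result`.
#' @export
mark_connection <- function(table, mark_a, mark_b,
                            bin_edges = seq(0, 500, by = 20),
                            n_permutations = 199, seed = NULL,
                            window = NULL) {
  stopifnot(inherits(table, "localisation_table"),
            length(bin_edges) >= 2, all(diff(bin_edges) > 0),
            n_permutations >= 0)
  pts <- table[table$mark %in% c(mark_a, mark_b), , drop = FALSE]
  if (nrow(pts) < 2L) stop("need at least 2 localisations of the two marks")
  if (!any(pts$mark == mark_a) || !any(pts$mark == mark_b))
    stop("table must contain both marks")
  if (!is.null(seed)) set.seed(seed)
  nb <- length(bin_edges) - 1L

  # Enumerate within-ROI pairs once: bin index and endpoint rows.
  groups <- if (all(is.na(pts$roi))) list(seq_len(nrow(pts)))
            else split(seq_len(nrow(pts)), pts$roi)
  pair_bin <- integer(0)
  pair_i <- integer(0)
  pair_j <- integer(0)
  for (rows in groups) {
    m <- length(rows)
    if (m < 2L) next
    dx <- abs(outer(pts$x[rows], pts$x[rows], "-"))
    dy <- abs(outer(pts$y[rows], pts$y[rows], "-"))
    if (!is.null(window)) {
      dx <- pmin(dx, window[1] - dx)
      dy <- pmin(dy, window[2] - dy)
    }
    dmat <- sqrt(dx^2 + dy^2)
    up <- which(upper.tri(dmat), arr.ind = TRUE)
    d <- dmat[up]
    b <- findInterval(d, bin_edges, rightmost.closed = TRUE)
    keep <- b >= 1L & b <= nb
    pair_bin <- c(pair_bin, b[keep])
    pair_i <- c(pair_i, rows[up[keep, 1]])
    pair_j <- c(pair_j, rows[up[keep, 2]])
  }
  total <- tabulate(pair_bin, nbins = nb)
  is_a <- pts$mark == mark_a
  p_a <- mean(is_a)
  p_b <- 1 - p_a
  cross_counts <- function(lab_a) {
    cross <- lab_a[pair_i] != lab_a[pair_j]
    tabulate(pair_bin[cross], nbins = nb)
  }
  cross <- cross_counts(is_a)
  p_cross <- ifelse(total > 0, cross / total, NA_real_)
  norm_const <- 2 * p_a * p_b
  normalised <- p_cross / norm_const
  env_low <- env_high <- rep(NA_real_, nb)
  if (n_permutations > 0) {
    perm <- matrix(NA_real_, n_permutations, nb)
    roi_of <- if (all(is.na(pts$roi))) rep("<all>", nrow(pts)) else pts$roi
    for (p in seq_len(n_permutations)) {
      lab <- is_a
      for (rows in split(seq_along(lab), roi_of))
        lab[rows] <- lab[rows][sample.int(length(rows))]
      pc <- ifelse(total > 0, cross_counts(lab) / total, NA_real_)
      perm[p, ] <- pc / norm_const - 1
    }
    env_low <- apply(perm, 2, stats::quantile, probs = 0.025, na.rm = TRUE,
                     names = FALSE)
    env_high <- apply(perm, 2, stats::quantile, probs = 0.975, na.rm = TRUE,
                      names = FALSE)
    env_low[total == 0] <- NA_real_
    env_high[total == 0] <- NA_real_
  }
  structure(list(mark_a = mark_a, mark_b = mark_b, bin_edges = bin_edges,
                 bin_mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                 n_pairs = total, p_cross = p_cross,
                 normalised = normalised, centred = normalised - 1,
                 envelope_low = env_low, envelope_high = env_high,
                 empty_bins = which(total == 0),
                 p_a = p_a, p_b = p_b,
                 n_permutations = n_permutations,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "mcf_result")
}

#' @export
print.mcf_result <- function(x, ...) {
  cat(sprintf("Mark connection function: %s vs %s, %d bins (%g-%g nm)\n",
              x$mark_a, x$mark_b, length(x$bin_mid), min(x$bin_edges),
              max(x$bin_edges)))
  cat(sprintf("  random-labelling envelope from %d permutations; %d empty bin(s)\n",
              x$n_permutations, length(x$empty_bins)))
  invisible(x)
}

#' @export
write_results.mcf_result <- function(result, path) {
  meta <- list(mark_a = result$mark_a, mark_b = result$mark_b,
               p_a = result$p_a, p_b = result$p_b,
               n_permutations = result$n_permutations, seed = result$seed)
  tab <- data.frame(bin_low = result$bin_edges[-length(result$bin_edges)],
                    bin_high = result$bin_edges[-1],
                    n_pairs = result$n_pairs, p_cross = result$p_cross,
                    normalised = result$normalised, centred = result$centred,
                    envelope_low = result$envelope_low,
                    envelope_high = result$envelope_high)
  write_sections(meta, tab, "mcf_result", path)
}

#' Classify mark connection bins against the null envelope
#'
#' Each bin is called `"repulsion"` if its centred value lies below the
#' lower envelope, `"attraction"` if above the upper envelope, and
#' `"random"` otherwise. The summary is the majority verdict over
#' non-empty bins whose midpoints lie below `scale_limit` (ties resolve
#' to `"random"`).
#'
#' @param mcf An [mark_connection()] result computed with an envelope.
#' @param scale_limit Summary scale in nm (default 200, the cluster
#'   scale at which exclusivity is expected to operate).
#' @return List with `per_bin` (data frame) and `summary`.
#' @export
exclusivity_verdict <- function(mcf, scale_limit = 200) {
  stopifnot(inherits(mcf, "mcf_result"))
  if (all(is.na(mcf$envelope_low)))
    stop("verdict requires an envelope; rerun mark_connection with permutations")
  verdict <- rep("random", length(mcf$bin_mid))
  verdict[!is.na(mcf$centred) & !is.na(mcf$envelope_low) &
            mcf$centred < mcf$envelope_low] <- "repulsion"
  verdict[!is.na(mcf$centred) & !is.na(mcf$envelope_high) &
            mcf$centred > mcf$envelope_high] <- "attraction"
  verdict[is.na(mcf$centred)] <- NA_character_
  in_scale <- mcf$bin_mid < scale_limit & !is.na(verdict)
  if (!any(in_scale))
    stop("no non-empty bins below scale_limit = ", scale_limit, " nm")
  counts <- table(factor(verdict[in_scale],
                         levels = c("repulsion", "random", "attraction")))
  top <- names(counts)[counts == max(counts)]
  summary <- if (length(top) == 1L) top else "random"
  list(per_bin = data.frame(bin_mid = mcf$bin_mid, verdict = verdict,
                            stringsAsFactors = FALSE),
       scale_limit = scale_limit, summary = summary)
}
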