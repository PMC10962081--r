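# k-nearest-neighbour association of histone-mark localisations with
# elongating RNA polymerase II (RPol-PSer2) localisations.

#' k-th nearest-neighbour distances from mark to reference localisations
#'
#' For every localisation of `mark`, computes the Euclidean distance to
#' its k-th nearest `reference` localisation within the same ROI, along
#' with the ECDF, median and 90% quantile per ROI. Using the k-th (rather
#' than first) neighbour makes the measure robust to isolated false
#' localisations; the conventional ranks are k = 5, 9 and 21.
#'
#' @param marks A [localisation_table()] (rows of other marks ignored via
#'   `mark`).
#' @param reference A [localisation_table()] of reference localisations
#'   (rows filtered to `reference_mark` when given).
#' @param k Neighbour rank (>= 1).
#' @param mark,reference_mark Optional labels selecting rows from each
#'   table; default uses all rows of the respective table.
#' @return Object of class `knn_result` with `distances` (per mark
#'   localisation, with `roi`), `per_roi` (data frame: `roi`, `n`,
#'   `median`, `q90`), and pooled `median` / `q90`. Quantiles use the
#'   right-continuous empirical convention (smallest datum with cumulative
#'   probability >= q).
#' @export
knn_distances <- function(marks, reference, k, mark = NULL,
                          reference_mark = NULL) {
  stopifnot(inherits(marks, "localisation_table"),
            inherits(reference, "localisation_table"), k >= 1)
  k <- as.integer(k)
  if (!is.null(mark)) marks <- marks[marks$mark == mark, , drop = FALSE]
  if (!is.null(reference_mark))
    reference <- reference[reference$mark == reference_mark, , drop = FALSE]
  if (nrow(marks) == 0L) stop("no mark localisations to measure from")
  mgroups <- if (all(is.na(marks$roi))) list("<all>" = seq_len(nrow(marks)))
             else split(seq_len(nrow(marks)), marks$roi)
  dist_all <- numeric(0)
  roi_all <- character(0)
  per_roi <- list()
  for (g in names(mgroups)) {
    mrows <- mgroups[[g]]
    rrows <- if (g == "<all>") seq_len(nrow(reference))
             else which(!is.na(reference$roi) & reference$roi == g)
    if (length(rrows) < k)
      stop(sprintf("ROI '%s' has %d reference localisations, fewer than k = %d",
                   g, length(rrows), k))
    d <- vapply(mrows, function(i) {
      d2 <- (reference$x[rrows] - marks$x[i])^2 +
            (reference$y[rrows] - marks$y[i])^2
      sqrt(sort(d2, partial = k)[k])
    }, numeric(1))
    dist_all <- c(dist_all, d)
    roi_all <- c(roi_all, rep(g, length(d)))
    per_roi[[length(per_roi) + 1L]] <- data.frame(
      roi = if (g == "<all>") NA_character_ else g, n = length(d),
      median = ecdf_quantile(d, 0.5), q90 = ecdf_quantile(d, 0.9),
      stringsAsFactors = FALSE)
  }
  per_roi <- do.call(rbind, per_roi)
  structure(list(mark = unique(marks$mark), reference =
                   if (is.null(reference_mark)) unique(reference$mark)
                   else reference_mark,
                 k = k,
                 distances = data.frame(roi = roi_all, distance = dist_all,
                                        stringsAsFactors = FALSE),
                 per_roi = per_roi,
                 median = ecdf_quantile(dist_all, 0.5),
                 q90 = ecdf_quantile(dist_all, 0.9)),
            class = "knn_result")
}

# Right-continuous empirical quantile: smallest datum with cumulative
# probability >= q (R quantile type 1).
ecdf_quantile <- function(x, q) {
  unname(stats::quantile(x, q, type = 1))
}

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf("knn distances (k = %d) from %s to %s: pooled median %.0f nm, q90 %.0f nm (%d points, %d ROI(s))\n",
              x$k, paste(x$mark, collapse = "/"),
              paste(x$reference, collapse = "/"), x$median, x$q90,
              nrow(x$distances), nrow(x$per_roi)))
  invisible(x)
}

#' @export
write_results.knn_result <- function(result, path) {
  meta <- list(mark = paste(result$mark, collapse = "/"),
               reference = paste(result$reference, collapse = "/"),
               k = result$k, median = result$median, q90 = result$q90)
  write_sections(meta, result$per_roi, "knn_result", path)
}

#' Empirical CDF of a knn-distance result
#' @param result A [knn_distances()] result.
#' @return Data frame with sorted `distance` and cumulative `probability`.
#' @export
knn_ecdf <- function(result) {
  stopifnot(inherits(result, "knn_result"))
  d <- sort(result$distances$distance)
  data.frame(distance = d, probability = seq_along(d) / length(d))
}

#' Compare the polymerase association of two marks
#'
#' Takes per-ROI quantile values (default the 90% quantile) of the
#' knn-distance distributions of two marks measured against the same
#' reference, and compares them with a two-sided Welch t-test across
#' ROIs. The mark with the smaller mean quantile is reported as the one
#' closer to the reference.
#'
#' @param a,b [knn_distances()] results with matching `k`, each spanning
#'   at least 2 ROIs.
#' @param quantile Quantile compared per ROI: 0.9 (default) or 0.5.
#' @return Object of class `association_comparison`.
#' @export
compare_association <- function(a, b, quantile = 0.9) {
  stopifnot(inherits(a, "knn_result"), inherits(b, "knn_result"))
  if (a$k != b$k)
    stop(sprintf("mismatched k: %d vs %d", a$k, b$k))
  col <- if (isTRUE(all.equal(quantile, 0.9))) "q90"
         else if (isTRUE(all.equal(quantile, 0.5))) "median"
         else NULL
  qa <- if (!is.null(col)) a$per_roi[[col]] else
    vapply(split(a$distances$distance, a$distances$roi), ecdf_quantile,
           numeric(1), q = quantile)
  qb <- if (!is.null(col)) b$per_roi[[col]] else
    vapply(split(b$distances$distance, b$distances$roi), ecdf_quantile,
           numeric(1), q = quantile)
  if (length(qa) < 2L || length(qb) < 2L)
    stop("association comparison needs >= 2 ROIs per mark")
  tt <- stats::t.test(qa, qb, var.equal = FALSE)
  structure(list(mark_a = paste(a$mark, collapse = "/"),
                 mark_b = paste(b$mark, collapse = "/"),
                 k = a$k, quantile = quantile,
                 per_roi_a = qa, per_roi_b = qb,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 direction = if (mean(qa) < mean(qb))
                   paste(a$mark, collapse = "/") else
                     paste(b$mark, collapse = "/")),
            class = "association_comparison")
}

#' @export
print.association_comparison <- function(x, ...) {
  cat(sprintf("Association at k = %d, q = %g: %s vs %s\n", x$k, x$quantile,
              x$mark_a, x$mark_b))
  cat(sprintf("  closer mark: %s (Welch t = %.3f, p = %.4g)\n",
              x$direction, x$t, x$p_value))
  invisible(x)
}
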