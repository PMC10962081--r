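# 1-D intensity-profile analyses: extraction along polyline ROIs, peak
# detection with an sd-relative prominence tolerance, inter-peak spacing
# statistics, and cross-channel lag via windowed cross-correlation.

#' Extract a paired-channel profile along a polyline ROI
#'
#' Samples both channels of a 2-D image at uniform arc-length steps along
#' the ROI using bilinear interpolation. Pixel `[i, j]` (row, column) is
#' centred at `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` in nm,
#' i.e. rows index y and columns index x. The sample count is
#' `floor(arc_length / step) + 1`.
#'
#' @param grid List with matrices `channel_a` and `channel_b` of equal
#'   dimension, or a 3-d array with the channel as the third index.
#' @param pixel_size Pixel edge in nm.
#' @param roi A [polyline_roi()] lying inside the image.
#' @param step Arc-length sampling interval in nm.
#' @return An [intensity_profile()].
#' @export
extract_profile <- function(grid, pixel_size, roi, step) {
  stopifnot(inherits(roi, "polyline_roi"), step > 0, pixel_size > 0)
  if (is.array(grid) && length(dim(grid)) == 3L)
    grid <- list(channel_a = grid[, , 1], channel_b = grid[, , 2])
  a <- grid$channel_a
  b <- grid$channel_b
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  w <- ncol(a) * pixel_size
  h <- nrow(a) * pixel_size
  v <- roi$vertices
  bad <- which(v[, 1] < 0 | v[, 1] > w | v[, 2] < 0 | v[, 2] > h)
  if (length(bad))
    stop(sprintf("ROI '%s' vertex %d at (%.1f, %.1f) nm lies outside the %g x %g nm image",
                 roi$roi_id, bad[1], v[bad[1], 1], v[bad[1], 2], w, h))
  s <- seq(0, roi$arc_length, by = step)
  if (length(s) < floor(roi$arc_length / step) + 1)
    s <- c(s, roi$arc_length)  # guard against floating shortfall
  s <- s[seq_len(floor(roi$arc_length / step) + 1)]
  pts <- polyline_point(v, s)
  intensity_profile(roi$roi_id, step,
                    bilinear(a, pts, pixel_size),
                    bilinear(b, pts, pixel_size))
}

#' Read a single-plane two-channel image grid from TIFF
#'
#' Accepts either a two-page TIFF (one page per channel) or a single page
#' with two samples per pixel, and returns the grid format consumed by
#' [extract_profile()]. Requires the `tiff` package.
#'
#' @param path TIFF file path.
#' @return List with matrices `channel_a` and `channel_b`.
#' @export
read_image_grid <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF grids requires the 'tiff' package")
  img <- tiff::readTIFF(path, all = TRUE)
  if (is.list(img) && length(img) >= 2L) {
    a <- img[[1]]
    b <- img[[2]]
    if (length(dim(a)) == 3L) a <- a[, , 1]
    if (length(dim(b)) == 3L) b <- b[, , 1]
  } else {
    one <- if (is.list(img)) img[[1]] else img
    if (length(dim(one)) != 3L || dim(one)[3] < 2L)
      stop("TIFF must have two pages or two channels: ", path)
    a <- one[, , 1]
    b <- one[, , 2]
  }
  if (!all(dim(a) == dim(b)))
    stop("channel dimensions differ in ", path)
  list(channel_a = a, channel_b = b)
}

# Points at arc-length positions s along the polyline with vertex matrix v.
polyline_point <- function(v, s) {
  seg <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- pmin(findInterval(s, cum), length(seg))
  f <- (s - cum[i]) / seg[i]
  cbind(v[i, 1] + f * (v[i + 1, 1] - v[i, 1]),
        v[i, 2] + f * (v[i + 1, 2] - v[i, 2]))
}

# Bilinear interpolation at nm coordinates; edge values clamp.
bilinear <- function(mat, pts, pixel_size) {
  u <- pts[, 1] / pixel_size + 0.5   # column coordinate, centres at 1..ncol
  w <- pts[, 2] / pixel_size + 0.5   # row coordinate
  j0 <- pmin(pmax(floor(u), 1), ncol(mat) - 1)
  i0 <- pmin(pmax(floor(w), 1), nrow(mat) - 1)
  fu <- pmin(pmax(u - j0, 0), 1)
  fw <- pmin(pmax(w - i0, 0), 1)
  idx <- function(i, j) mat[cbind(i, j)]
  (1 - fu) * (1 - fw) * idx(i0, j0) + fu * (1 - fw) * idx(i0, j0 + 1) +
    (1 - fu) * fw * idx(i0 + 1, j0) + fu * fw * idx(i0 + 1, j0 + 1)
}

#' Detect intensity peaks with an sd-relative prominence tolerance
#'
#' A local maximum is retained when its prominence — its height above the
#' higher of the two flanking minima separating it from higher terrain (or
#' the profile ends) — is at least `tolerance_factor` times the standard
#' deviation of the channel. Low factors (0.17) are permissive, factors
#' near 1 stringent. Plateaus report their arc-length midpoint; profile
#' endpoints are never peaks.
#'
#' @param profile An [intensity_profile()] with >= 3 samples.
#' @param channel `"a"` or `"b"`.
#' @param tolerance_factor Non-negative prominence multiplier.
#' @return Object of class `peak_set` with strictly increasing `positions`
#'   (nm), `heights`, `prominences`, `tolerance_factor` and `channel`.
#' @export
find_peaks <- function(profile, channel = c("a", "b"),
                       tolerance_factor = 0.17) {
  stopifnot(inherits(profile, "intensity_profile"), tolerance_factor >= 0)
  channel <- match.arg(channel)
  v <- if (channel == "a") profile$channel_a else profile$channel_b
  n <- length(v)
  if (n < 3L) stop("peak detection needs at least 3 samples")
  empty <- function() structure(
    list(roi_id = profile$roi_id, positions = numeric(0),
         heights = numeric(0), prominences = numeric(0),
         tolerance_factor = tolerance_factor, channel = channel,
         profile_length = (n - 1) * profile$step), class = "peak_set")
  sd_v <- stats::sd(v)
  if (sd_v == 0) {
    warning("zero-variance channel: no peaks")
    return(empty())
  }
  # collapse plateaus to runs
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  pos <- numeric(0)
  hgt <- numeric(0)
  prm <- numeric(0)
  for (q in seq_len(k)) {
    if (q == 1L || q == k) next                    # endpoint runs
    if (!(r$values[q] > r$values[q - 1L] && r$values[q] > r$values[q + 1L]))
      next
    peak <- r$values[q]
    # walk left/right to the first strictly higher sample; base = min seen
    li <- starts[q] - 1L
    lb <- v[li]
    while (li >= 1L && v[li] <= peak) {
      lb <- min(lb, v[li])
      li <- li - 1L
    }
    left_base <- lb
    ri <- ends[q] + 1L
    rb <- v[ri]
    while (ri <= n && v[ri] <= peak) {
      rb <- min(rb, v[ri])
      ri <- ri + 1L
    }
    right_base <- rb
    prom <- peak - max(left_base, right_base)
    if (prom >= tolerance_factor * sd_v) {
      pos <- c(pos, (starts[q] + ends[q]) / 2 - 1)  # sample index midpoint
      hgt <- c(hgt, peak)
      prm <- c(prm, prom)
    }
  }
  out <- empty()
  out$positions <- pos * profile$step
  out$heights <- hgt
  out$prominences <- prm
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set '%s' (channel %s, tolerance %g): %d peak(s)\n",
              x$roi_id, x$channel, x$tolerance_factor, length(x$positions)))
  invisible(x)
}

#' Pool inter-peak spacings across ROIs
#'
#' Successive differences of peak positions are pooled over all supplied
#' peak sets; mean and sample (n - 1 denominator) standard deviation are
#' reported.
#'
#' @param peaksets A [find_peaks()] result or a list of them.
#' @return Object of class `spacing_stats` with `spacings`, `mean`, `sd`,
#'   `n`.
#' @export
spacing_stats <- function(peaksets) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  sp <- unlist(lapply(peaksets, function(p) diff(p$positions)))
  if (length(sp) == 0L)
    stop("no ROI contributed >= 2 peaks; cannot compute spacings")
  structure(list(spacings = sp, mean = mean(sp),
                 sd = if (length(sp) > 1L) stats::sd(sp) else NA_real_,
                 n = length(sp)),
            class = "spacing_stats")
}

#' @export
print.spacing_stats <- function(x, ...) {
  cat(sprintf("Peak spacings: mean %.0f +/- %.0f nm (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' @export
write_results.spacing_stats <- function(result, path) {
  meta <- list(mean = result$mean, sd = result$sd, n = result$n)
  write_sections(meta, data.frame(spacing_nm = result$spacings),
                 "spacing_stats", path)
}

#' Cross-correlate the two channels of a profile
#'
#' Computes the Pearson correlation of the overlapping segments of
#' channels A and B at every integer-sample lag within `+/- max_lag`,
#' with mean and standard deviation recomputed per lag on the overlap (so
#' `|corr| <= 1` everywhere). Positive lags mean channel B is displaced
#' towards larger arc length relative to channel A. The best lag maximises
#' `|corr|` (ties resolve to the smallest `|lag|`); its significance flag
#' applies the `1.96 / sqrt(n)` 5% cutoff with `n` the overlap length at
#' the best lag.
#'
#' @param profile An [intensity_profile()].
#' @param max_lag Maximum |lag| in nm; at most half the profile span.
#' @return Object of class `crosscorr_result` with `lags` (nm), `corr`,
#'   `best_lag`, `best_corr`, `n`, `cutoff`, `significant`.
#' @export
cross_correlate <- function(profile, max_lag = 1000) {
  stopifnot(inherits(profile, "intensity_profile"))
  a <- profile$channel_a
  b <- profile$channel_b
  n <- profile$n
  if (n < 3L) stop("cross-correlation needs at least 3 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a channel has zero variance")
  max_shift <- floor(max_lag / profile$step)
  if (max_lag > (n - 1) * profile$step / 2)
    stop("max_lag exceeds half the profile span")
  lags <- (-max_shift):max_shift
  corr <- vapply(lags, function(h) {
    if (h >= 0) {
      ai <- seq_len(n - h)
      bi <- ai + h
    } else {
      bi <- seq_len(n + h)
      ai <- bi - h
    }
    if (length(ai) < 3L) return(NA_real_)
    sa <- a[ai]
    sb <- b[bi]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(NA_real_)
    stats::cor(sa, sb)
  }, numeric(1))
  ok <- which(!is.na(corr))
  ord <- ok[order(-abs(corr[ok]), abs(lags[ok]), lags[ok])]
  best <- ord[1]
  n_overlap <- n - abs(lags[best])
  cutoff <- 1.96 / sqrt(n_overlap)
  structure(list(roi_id = profile$roi_id, step = profile$step,
                 lags = lags * profile$step, corr = corr,
                 best_lag = lags[best] * profile$step,
                 best_corr = corr[best], n = n_overlap, cutoff = cutoff,
                 significant = abs(corr[best]) > cutoff),
            class = "crosscorr_result")
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf("Cross-correlation '%s': best lag %g nm (r = %.3f, %ssignificant at 1.96/sqrt(%d))\n",
              x$roi_id, x$best_lag, x$best_corr,
              if (x$significant) "" else "not ", x$n))
  invisible(x)
}

#' @export
write_results.crosscorr_result <- function(result, path) {
  meta <- list(roi_id = result$roi_id, best_lag = result$best_lag,
               best_corr = result$best_corr, n = result$n,
               cutoff = result$cutoff,
               significant = as.integer(result$significant))
  write_sections(meta, data.frame(lag_nm = result$lags, corr = result$corr),
                 "crosscorr_result", path)
}

#' Summarise absolute displacements of two conditions
#'
#' Keeps only ROIs whose best correlation passed the `1.96 / sqrt(n)`
#' significance cutoff, takes the absolute best lag per ROI, reports each
#' condition's median absolute displacement and compares the two with a
#' two-sided Welch t-test.
#'
#' @param results_a,results_b Lists of [cross_correlate()] results for
#'   conditions A and B.
#' @param label_a,label_b Condition names used in the output.
#' @return Object of class `displacement_summary` with per-condition
#'   `abs_lags` and `median_abs_lag`, the Welch `t`, `df` and `p_value`,
#'   and counts of discarded (non-significant) ROIs.
#' @export
displacement_summary <- function(results_a, results_b,
                                 label_a = "A", label_b = "B") {
  pull <- function(results, label) {
    if (inherits(results, "crosscorr_result")) results <- list(results)
    sig <- vapply(results, `[[`, logical(1), "significant")
    lags <- abs(vapply(results[sig], `[[`, numeric(1), "best_lag"))
    if (length(lags) < 2L)
      stop("condition '", label, "' has fewer than 2 significant ROIs")
    list(lags = lags, discarded = sum(!sig))
  }
  a <- pull(results_a, label_a)
  b <- pull(results_b, label_b)
  tt <- stats::t.test(a$lags, b$lags, var.equal = FALSE)
  structure(list(label_a = label_a, label_b = label_b,
                 abs_lags_a = a$lags, abs_lags_b = b$lags,
                 median_abs_lag_a = stats::median(a$lags),
                 median_abs_lag_b = stats::median(b$lags),
                 discarded_a = a$discarded, discarded_b = b$discarded,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "displacement_summary")
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat(sprintf("Displacement: %s median %g nm (n = %d), %s median %g nm (n = %d)\n",
              x$label_a, x$median_abs_lag_a, length(x$abs_lags_a),
              x$label_b, x$median_abs_lag_b, length(x$abs_lags_b)))
  cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.4g\n", x$t, x$df,
              x$p_value))
  invisible(x)
}
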