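# Synthetic Y-loop data: chains of Gaussian nucleosome clusters along curved
# fibres (localisation tables) and paired-channel peak trains (profiles),
# with ground truth retained for recovery testing.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # FWHM = 2.3548 sigma

#' Configuration for the fibre/localisation simulator
#'
#' Defaults reflect the study conditions the package is built around:
#' Gaussian nucleosome clusters of ~52 nm FWHM (the median total-histone
#' cluster width) spaced 276 +/- 164 nm along a curved fibre, two mark
#' classes occupying mutually exclusive clusters.
#'
#' @param n_rois Number of independent fibres (ROIs) to simulate.
#' @param fibre_length Arc length of each fibre in nm.
#' @param spacing_mean,spacing_sd Mean and SD (nm) of inter-cluster
#'   spacings; spacings are drawn from a gamma distribution matched to
#'   these moments so they are strictly positive.
#' @param cluster_fwhm Full width at half maximum of each cluster's
#'   isotropic Gaussian localisation spread, nm.
#' @param locs_per_cluster_mean Mean localisations per cluster (Poisson).
#' @param class_labels Character pair of mark names.
#' @param exclusivity Probability in \[0, 1\] that a cluster is
#'   single-class; otherwise its localisations are mixed 50/50.
#' @param domain_persistence Probability that a single-class cluster keeps
#'   the class of the previous cluster along the fibre, producing runs of
#'   same-state clusters (chromatin-state domains). The default 0.85 gives
#'   a mean run length of about 6 clusters, the domain size apparent in
#'   dual-colour STORM fibres; 0.5 gives independent classes.
#' @param contamination_fraction Fraction of second-class localisations
#'   relocated into (within 50 nm of) first-class cluster cores,
#'   emulating residual overlap between nominally exclusive marks.
#' @param background_rate Uniform background localisations per square
#'   micrometre, added per class over the fibre bounding box.
#' @param curvature Maximum turning angle (radians) per 10-nm step of the
#'   fibre random walk; 0 gives straight fibres.
#' @param seed Integer seed fixing the full output.
#' @return A validated list of class `fibre_sim_config`.
#' @export
fibre_sim_config <- function(n_rois = 10, fibre_length = 5000,
                             spacing_mean = 276, spacing_sd = 164,
                             cluster_fwhm = 52, locs_per_cluster_mean = 60,
                             class_labels = c("H3K36me3", "H3K27me3"),
                             exclusivity = 1, domain_persistence = 0.85,
                             contamination_fraction = 0,
                             background_rate = 0, curvature = 0.3,
                             seed = 1L) {
  cfg <- list(n_rois = as.integer(n_rois), fibre_length = fibre_length,
              spacing_mean = spacing_mean, spacing_sd = spacing_sd,
              cluster_fwhm = cluster_fwhm,
              locs_per_cluster_mean = locs_per_cluster_mean,
              class_labels = as.character(class_labels),
              exclusivity = exclusivity,
              domain_persistence = domain_persistence,
              contamination_fraction = contamination_fraction,
              background_rate = background_rate, curvature = curvature,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_rois >= 1, fibre_length > 0, spacing_mean > 0,
              spacing_sd > 0, cluster_fwhm > 0, locs_per_cluster_mean > 0,
              length(class_labels) == 2, exclusivity >= 0, exclusivity <= 1,
              domain_persistence >= 0, domain_persistence <= 1,
              contamination_fraction >= 0, contamination_fraction <= 1,
              background_rate >= 0, curvature >= 0)
  })
  if (cfg$spacing_mean <= cfg$cluster_fwhm / 2)
    warning("spacing_mean <= cluster_fwhm/2: clusters will overlap heavily")
  class(cfg) <- "fibre_sim_config"
  cfg
}

# Gamma parameterised by mean and sd: shape = (m/s)^2, rate = m/s^2.
rgamma_ms <- function(n, mean, sd) {
  stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

# Bounded-curvature random walk of `n_steps` steps of `step` nm; returns a
# function mapping arc length to (x, y).
fibre_path <- function(length_nm, curvature, step = 10) {
  n_steps <- ceiling(length_nm / step)
  heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::runif(n_steps, -curvature, curvature)))
  xs <- cumsum(c(0, step * cos(heading[-1])))
  ys <- cumsum(c(0, step * sin(heading[-1])))
  arc <- (0:n_steps) * step
  function(s) {
    s <- pmin(pmax(s, 0), arc[length(arc)])
    i <- pmin(findInterval(s, arc), n_steps)
    f <- (s - arc[i]) / step
    cbind(xs[i] + f * (xs[i + 1] - xs[i]), ys[i] + f * (ys[i + 1] - ys[i]))
  }
}

#' Simulate localisation tables of clustered chromatin fibres
#'
#' Each ROI is a bounded-curvature random-walk fibre along which cluster
#' centres are placed at gamma-distributed arc spacings. Each cluster
#' receives a Poisson number of localisations spread as an isotropic
#' Gaussian of the configured FWHM, and is single-class with probability
#' `exclusivity`, otherwise mixed 50/50 per localisation. Single-class
#' labels follow a two-state Markov chain along the fibre
#' (`domain_persistence`), so marks occupy contiguous domains of clusters
#' rather than alternating at random. A `contamination_fraction` of second-class localisations
#' is then relocated to a uniformly chosen pure-first-class cluster centre
#' (uniform within a 50-nm disc), and uniform background is added per
#' class. The returned truth records centres, classes, spacings, the
#' configured FWHM and contamination, and the indices of relocated rows.
#'
#' @param config A [fibre_sim_config()].
#' @return List with elements `table` (a [localisation_table()]) and
#'   `truth` (class `simulation_truth`).
#' @export
simulate_fibre <- function(config) {
  stopifnot(inherits(config, "fibre_sim_config"))
  set.seed(config$seed)
  sigma <- config$cluster_fwhm * FWHM_TO_SIGMA
  labs <- config$class_labels
  tabs <- vector("list", config$n_rois)
  cents <- vector("list", config$n_rois)
  spacings_all <- list()
  n_relocated <- 0L
  n_b_total <- 0L
  relocated_rows <- list()
  row_offset <- 0L
  for (r in seq_len(config$n_rois)) {
    roi_id <- sprintf("roi%02d", r)
    path <- fibre_path(config$fibre_length, config$curvature)
    # lay centres along the arc until the fibre ends
    sp <- rgamma_ms(ceiling(3 * config$fibre_length / config$spacing_mean) + 8,
                    config$spacing_mean, config$spacing_sd)
    arcpos <- cumsum(c(sp[1] / 2, sp[-1]))
    arcpos <- arcpos[arcpos <= config$fibre_length]
    if (length(arcpos) == 0L) arcpos <- config$fibre_length / 2
    spacings_all[[r]] <- diff(arcpos)
    ctr <- path(arcpos)
    n_c <- nrow(ctr)
    pure <- stats::runif(n_c) < config$exclusivity
    # Markov chain of cluster classes along the fibre: runs of same-state
    # clusters form chromatin-state domains
    keep <- stats::runif(n_c) < config$domain_persistence
    pure_class <- character(n_c)
    prev <- if (stats::runif(1) < 0.5) labs[1] else labs[2]
    for (ci in seq_len(n_c)) {
      if (ci > 1L && !keep[ci]) prev <- setdiff(labs, prev)
      pure_class[ci] <- prev
    }
    cls <- ifelse(pure, pure_class, "mixed")
    n_loc <- stats::rpois(n_c, config$locs_per_cluster_mean)
    idx <- rep.int(seq_len(n_c), n_loc)
    n_pts <- length(idx)
    px <- ctr[idx, 1] + stats::rnorm(n_pts, 0, sigma)
    py <- ctr[idx, 2] + stats::rnorm(n_pts, 0, sigma)
    pm <- ifelse(pure[idx], pure_class[idx],
                 ifelse(stats::runif(n_pts) < 0.5, labs[1], labs[2]))
    # contamination: relocate selected class-B points into class-A cores
    is_b <- pm == labs[2]
    n_b_total <- n_b_total + sum(is_b)
    a_centres <- which(pure & pure_class == labs[1])
    if (config$contamination_fraction > 0 && any(is_b) &&
        length(a_centres) > 0) {
      move <- which(is_b & stats::runif(n_pts) < config$contamination_fraction)
      if (length(move)) {
        tgt <- a_centres[sample.int(length(a_centres), length(move),
                                    replace = TRUE)]
        # core-concentrated placement: isotropic Gaussian (sigma 50/3 nm)
        # truncated to the 50-nm disc, so contaminants sit inside cluster
        # cores rather than hugging the radius boundary
        ox <- stats::rnorm(length(move), 0, 50 / 3)
        oy <- stats::rnorm(length(move), 0, 50 / 3)
        out <- which(ox^2 + oy^2 > 50^2)
        while (length(out)) {
          ox[out] <- stats::rnorm(length(out), 0, 50 / 3)
          oy[out] <- stats::rnorm(length(out), 0, 50 / 3)
          out <- out[ox[out]^2 + oy[out]^2 > 50^2]
        }
        px[move] <- ctr[tgt, 1] + ox
        py[move] <- ctr[tgt, 2] + oy
        n_relocated <- n_relocated + length(move)
        relocated_rows[[r]] <- row_offset + move
      }
    }
    # uniform background per class over the padded fibre bounding box
    if (config$background_rate > 0 && n_pts > 0) {
      pad <- 100
      bb <- c(range(px) + c(-pad, pad), range(py) + c(-pad, pad))
      area_um2 <- (bb[2] - bb[1]) * (bb[4] - bb[3]) / 1e6
      for (lab in labs) {
        n_bg <- stats::rpois(1, config$background_rate * area_um2)
        if (n_bg > 0) {
          px <- c(px, stats::runif(n_bg, bb[1], bb[2]))
          py <- c(py, stats::runif(n_bg, bb[3], bb[4]))
          pm <- c(pm, rep(lab, n_bg))
        }
      }
    }
    tabs[[r]] <- data.frame(x = px, y = py, mark = pm, roi = roi_id,
                            stringsAsFactors = FALSE)
    cents[[r]] <- data.frame(roi = roi_id, x = ctr[, 1], y = ctr[, 2],
                             class = cls, stringsAsFactors = FALSE)
    row_offset <- row_offset + nrow(tabs[[r]])
  }
  all_pts <- do.call(rbind, tabs)
  table <- localisation_table(all_pts$x, all_pts$y, all_pts$mark, all_pts$roi)
  truth <- structure(list(
    cluster_centres = do.call(rbind, cents),
    true_spacings = unlist(spacings_all),
    true_fwhm = config$cluster_fwhm,
    true_shift = NA_real_,
    true_overlap_fraction = config$contamination_fraction,
    relocated_rows = unlist(relocated_rows),
    n_relocated = n_relocated,
    n_second_class = n_b_total,
    config = config), class = "simulation_truth")
  list(table = table, truth = truth)
}

#' Configuration for the paired-profile simulator
#'
#' Emulates STED line scans: channel A is a train of Gaussian intensity
#' peaks (unit amplitude) at gamma-distributed spacings; channel B is
#' channel A translated by `channel_shift` with additive Gaussian noise.
#' Defaults use the 20-nm STED pixel pitch and the histone peak spacing
#' statistics the package targets (276 +/- 164 nm).
#'
#' @param n_profiles Number of profiles.
#' @param profile_length Profile span in nm (must be >= 10 * step).
#' @param step Sampling interval, nm.
#' @param peak_fwhm FWHM of each Gaussian peak, nm.
#' @param spacing_mean,spacing_sd Gamma-matched spacing moments, nm.
#' @param channel_shift Translation of channel B relative to channel A,
#'   nm; must be below `profile_length / 2`.
#' @param noise_sd Noise standard deviation as a fraction of the unit
#'   peak amplitude (so `noise_sd = 0.1` is SNR 10).
#' @param seed Integer seed.
#' @return A validated list of class `profile_sim_config`.
#' @export
profile_sim_config <- function(n_profiles = 20, profile_length = 5000,
                               step = 20, peak_fwhm = 100,
                               spacing_mean = 276, spacing_sd = 164,
                               channel_shift = 0, noise_sd = 0.1,
                               seed = 1L) {
  cfg <- list(n_profiles = as.integer(n_profiles),
              profile_length = profile_length, step = step,
              peak_fwhm = peak_fwhm, spacing_mean = spacing_mean,
              spacing_sd = spacing_sd, channel_shift = channel_shift,
              noise_sd = noise_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_profiles >= 1, step > 0, profile_length >= 10 * step,
              peak_fwhm > 0, spacing_mean > 0, spacing_sd > 0,
              noise_sd >= 0)
  })
  if (abs(cfg$channel_shift) >= cfg$profile_length / 2)
    stop("channel_shift must be smaller than profile_length / 2")
  class(cfg) <- "profile_sim_config"
  cfg
}

#' Simulate paired-channel intensity profiles
#'
#' @param config A [profile_sim_config()]. The channel shift is applied as
#'   a whole number of samples (`round(channel_shift / step)`); both
#'   channels are truncated to the overlapping support so no wrapped
#'   signal survives.
#' @return List with `profiles` (list of [intensity_profile()]) and
#'   `truth` (class `simulation_truth` carrying `true_shift` and
#'   per-profile `true_spacings` and peak positions).
#' @export
simulate_paired_profiles <- function(config) {
  stopifnot(inherits(config, "profile_sim_config"))
  set.seed(config$seed)
  sigma <- config$peak_fwhm * FWHM_TO_SIGMA
  shift_samples <- round(config$channel_shift / config$step)
  profiles <- vector("list", config$n_profiles)
  spacings <- vector("list", config$n_profiles)
  peak_pos <- vector("list", config$n_profiles)
  for (p in seq_len(config$n_profiles)) {
    pos <- seq(0, config$profile_length, by = config$step)
    sp <- rgamma_ms(ceiling(3 * config$profile_length / config$spacing_mean) + 8,
                    config$spacing_mean, config$spacing_sd)
    peaks <- cumsum(c(stats::runif(1, 0, config$spacing_mean), sp[-1]))
    peaks <- peaks[peaks <= config$profile_length]
    if (length(peaks) == 0L) peaks <- config$profile_length / 2
    a <- rowSums(exp(-outer(pos, peaks, "-")^2 / (2 * sigma^2)))
    # integer-sample translation, truncated to common support
    s <- abs(shift_samples)
    n <- length(a)
    if (s >= n) stop("channel shift exceeds profile support")
    if (shift_samples >= 0) {        # chan_b[i] = chan_a[i - s]: b delayed
      chan_a <- a[(s + 1):n]
      chan_b <- a[seq_len(n - s)]
    } else {
      chan_a <- a[seq_len(n - s)]
      chan_b <- a[(s + 1):n]
    }
    if (config$noise_sd > 0)
      chan_b <- chan_b + stats::rnorm(length(chan_b), 0, config$noise_sd)
    chan_b <- pmax(chan_b, 0)
    profiles[[p]] <- intensity_profile(sprintf("profile%02d", p),
                                       config$step, chan_a, chan_b)
    spacings[[p]] <- diff(peaks)
    peak_pos[[p]] <- peaks
  }
  names(profiles) <- vapply(profiles, `[[`, "", "roi_id")
  truth <- structure(list(
    cluster_centres = NULL,
    true_spacings = unlist(spacings),
    per_profile_spacings = spacings,
    peak_positions = peak_pos,
    true_fwhm = config$peak_fwhm,
    true_shift = shift_samples * config$step,
    true_overlap_fraction = NA_real_,
    config = config), class = "simulation_truth")
  list(profiles = profiles, truth = truth)
}
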