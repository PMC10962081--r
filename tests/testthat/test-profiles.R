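test_that("profile extraction interpolates bilinearly along polylines", {
  const <- list(channel_a = matrix(3, 20, 20), channel_b = matrix(7, 20, 20))
  roi <- polyline_roi("r", rbind(c(50, 50), c(350, 250)))
  p <- extract_profile(const, 20, roi, 20)
  expect_equal(p$channel_a, rep(3, p$n))
  expect_equal(p$channel_b, rep(7, p$n))
  expect_equal(p$n, floor(arc_length(roi) / 20) + 1)

  # single bright column: one peak at the column's arc position
  img <- matrix(0, 20, 20)
  img[, 10] <- 1  # column 10 -> x = 190 nm at 20 nm pixels
  grid <- list(channel_a = img, channel_b = img)
  roi2 <- polyline_roi("r2", rbind(c(30, 110), c(370, 110)))
  p2 <- extract_profile(grid, 20, roi2, 20)
  pk <- find_peaks(p2, "a", 0.5)
  expect_equal(length(pk$positions), 1L)
  expect_equal(pk$positions, 190 - 30)  # arc position of the column centre

  # sampling at the pixel pitch on an axis-aligned line hits node values
  set.seed(30)
  rnd <- matrix(runif(400), 20, 20)
  grid3 <- list(channel_a = rnd, channel_b = rnd)
  roi3 <- polyline_roi("r3", rbind(c(10, 150), c(370, 150)))  # row 8 centres
  p3 <- extract_profile(grid3, 20, roi3, 20)
  expect_equal(p3$channel_a, rnd[8, 1:19])

  out <- polyline_roi("out", rbind(c(0, 0), c(1000, 0)))
  expect_error(extract_profile(const, 20, out, 20), "vertex")
})

test_that("two-channel TIFF grids feed profile extraction", {
  skip_if_not_installed("tiff")
  img_a <- matrix(runif(400), 20, 20)
  img_b <- matrix(runif(400), 20, 20)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(img_a, img_b), path, bits.per.sample = 32)
  grid <- read_image_grid(path)
  expect_equal(dim(grid$channel_a), c(20, 20))
  roi <- polyline_roi("r", rbind(c(10, 150), c(370, 150)))
  p <- extract_profile(grid, 20, roi, 20)
  expect_equal(p$channel_a, grid$channel_a[8, 1:19])
  expect_equal(p$channel_b, grid$channel_b[8, 1:19])
})

test_that("peak detection follows the sd-relative prominence rule", {
  p <- intensity_profile("t", 20, c(0, 1, 0, 2, 0), rep(0, 5))
  pk <- find_peaks(p, "a", 0.5)
  expect_equal(pk$positions, c(20, 60))
  expect_equal(find_peaks(p, "a", 3.0)$positions, numeric(0))

  mono <- intensity_profile("m", 20, 1:6, rep(0, 6))
  expect_equal(find_peaks(mono, "a", 0.1)$positions, numeric(0))

  flat <- intensity_profile("f", 20, rep(2, 5), rep(0, 5))
  expect_warning(pkf <- find_peaks(flat, "a", 0.1), "zero-variance")
  expect_equal(pkf$positions, numeric(0))

  # plateaus report their midpoint; endpoints never count
  plat <- intensity_profile("p", 10, c(0, 1, 3, 3, 3, 1, 0, 5), rep(0, 8))
  pkp <- find_peaks(plat, "a", 0.1)
  expect_equal(pkp$positions, 30)  # samples 3-5 -> midpoint index 4 -> 30 nm

  # affine intensity rescaling leaves detections unchanged
  v <- c(0, 3, 1, 4, 0.5, 2, 0)
  p1 <- intensity_profile("s", 20, v, rep(0, 7))
  p2 <- intensity_profile("s", 20, 5 * v + 11, rep(0, 7))
  expect_equal(find_peaks(p1, "a", 0.4)$positions,
               find_peaks(p2, "a", 0.4)$positions)
})

test_that("higher tolerance yields a subset of the peaks", {
  sim <- simulate_paired_profiles(profile_sim_config(n_profiles = 4,
                                                     noise_sd = 0.05,
                                                     seed = 31))
  for (p in sim$profiles) {
    lo <- find_peaks(p, "a", 0.17)$positions
    hi <- find_peaks(p, "a", 1.0)$positions
    expect_true(all(hi %in% lo))
  }
})

test_that("spacing statistics pool successive differences across ROIs", {
  mk <- function(id, pos) {
    structure(list(roi_id = id, positions = pos, heights = pos * 0,
                   prominences = pos * 0, tolerance_factor = 0.17,
                   channel = "a", profile_length = max(pos)),
              class = "peak_set")
  }
  st <- spacing_stats(mk("a", c(0, 100, 300)))
  expect_equal(st$spacings, c(100, 200))
  expect_equal(st$mean, 150)

  st2 <- spacing_stats(list(mk("a", c(0, 100)), mk("b", c(0, 250))))
  expect_equal(st2$spacings, c(100, 250))
  expect_equal(st2$n, 2L)

  expect_error(spacing_stats(mk("a", c(50))), "2 peaks")
})

test_that("recovered spacings agree with simulator truth at high SNR", {
  cfg <- profile_sim_config(n_profiles = 10, spacing_mean = 400,
                            spacing_sd = 80, peak_fwhm = 100,
                            noise_sd = 0.02, seed = 32)
  sim <- simulate_paired_profiles(cfg)
  pk <- lapply(sim$profiles, find_peaks, channel = "a",
               tolerance_factor = 0.17)
  st <- spacing_stats(pk)
  # spacings are well above the resolution limit; only peaks flush with a
  # profile end can be missed, so recall is essentially 1
  expect_gte(st$n, 0.97 * length(sim$truth$true_spacings))
  se <- sd(sim$truth$true_spacings) / sqrt(st$n)
  expect_lt(abs(st$mean - mean(sim$truth$true_spacings)), 3 * se + 5)
})

test_that("cross-correlation recovers identity and pure translations", {
  sim <- simulate_paired_profiles(profile_sim_config(n_profiles = 1,
                                                     channel_shift = 0,
                                                     noise_sd = 0, seed = 33))
  xc0 <- cross_correlate(sim$profiles[[1]], 1000)
  expect_equal(xc0$best_lag, 0)
  expect_equal(xc0$best_corr, 1)

  sim2 <- simulate_paired_profiles(profile_sim_config(n_profiles = 1,
                                                      channel_shift = 200,
                                                      noise_sd = 0,
                                                      seed = 33))
  xc <- cross_correlate(sim2$profiles[[1]], 1000)
  expect_equal(abs(xc$best_lag), 200)
  expect_gt(abs(xc$best_corr), 0.999)

  flat <- intensity_profile("f", 20, rep(1, 10), 1:10)
  expect_error(cross_correlate(flat, 40), "zero variance")
  expect_error(cross_correlate(sim$profiles[[1]],
                               sim$profiles[[1]]$n * 20), "half")
})

test_that("swapping channels negates the best lag", {
  sim <- simulate_paired_profiles(profile_sim_config(n_profiles = 3,
                                                     channel_shift = 160,
                                                     noise_sd = 0.05,
                                                     seed = 34))
  for (p in sim$profiles) {
    sw <- intensity_profile(p$roi_id, p$step, p$channel_b, p$channel_a)
    expect_equal(cross_correlate(p, 800)$best_lag,
                 -cross_correlate(sw, 800)$best_lag)
  }
})

test_that("the 1.96/sqrt(n) significance rule controls white-noise false positives", {
  # the cutoff is the large-sample 5% bound for one correlation, so it is
  # checked at a single lag; searching many lags inflates the best |corr|
  # (multiple comparisons) and is documented as anti-conservative
  set.seed(35)
  flags <- replicate(100, {
    p <- intensity_profile("w", 20, rnorm(100), rnorm(100))
    xc <- cross_correlate(p, 0)
    stopifnot(xc$cutoff == 1.96 / sqrt(100))
    xc$significant
  })
  expect_gte(mean(!flags), 0.9)
})

test_that("displacement summaries keep significant ROIs and apply Welch's test", {
  mk <- function(lag, sig, id) {
    structure(list(roi_id = id, step = 20, lags = 0, corr = 0,
                   best_lag = lag, best_corr = if (sig) 0.9 else 0.05,
                   n = 100, cutoff = 0.196, significant = sig),
              class = "crosscorr_result")
  }
  a <- lapply(c(40, -50, 60), mk, sig = TRUE, id = "a")
  b <- lapply(c(180, -200, 220), mk, sig = TRUE, id = "b")
  ds <- displacement_summary(a, b, "H3K27me3", "H3K4me3")
  expect_equal(ds$median_abs_lag_a, 50)
  expect_equal(ds$median_abs_lag_b, 200)
  oracle <- welch_oracle(c(40, 50, 60), c(180, 200, 220))
  expect_equal(ds$t, oracle$t, tolerance = 1e-12)
  expect_equal(ds$p_value, oracle$p, tolerance = 1e-12)

  same <- displacement_summary(a, a, "x", "y")
  expect_equal(same$p_value, 1)

  too_few <- c(a[1], lapply(c(10, 20), mk, sig = FALSE, id = "c"))
  expect_error(displacement_summary(too_few, b), "fewer than 2 significant")
})

test_that("true channel shifts are recovered within one sampling step", {
  for (shift in c(60, 200)) {
    sim <- simulate_paired_profiles(profile_sim_config(
      n_profiles = 6, channel_shift = shift, noise_sd = 0.1,
      seed = 36 + shift))
    xc <- lapply(sim$profiles, cross_correlate, max_lag = 1000)
    lags <- abs(vapply(xc[vapply(xc, `[[`, logical(1), "significant")],
                       `[[`, numeric(1), "best_lag"))
    expect_lt(abs(median(lags) - shift), 20 + 1e-9)
  }
})
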