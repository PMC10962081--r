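test_that("fibre simulation is seed-deterministic", {
  cfg <- fibre_sim_config(n_rois = 2, seed = 42)
  a <- simulate_fibre(cfg)
  b <- simulate_fibre(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$cluster_centres, b$truth$cluster_centres)
  c <- simulate_fibre(fibre_sim_config(n_rois = 2, seed = 43))
  expect_false(identical(a$table, c$table))
})

test_that("fully exclusive fibres have no cross-class contamination of isolated clusters", {
  sim <- simulate_fibre(fibre_sim_config(n_rois = 3, exclusivity = 1,
                                         contamination_fraction = 0,
                                         background_rate = 0, seed = 5))
  tr <- sim$truth$cluster_centres
  tab <- sim$table
  pure <- tr[tr$class != "mixed", ]
  checked <- 0L
  for (i in seq_len(nrow(pure))) {
    # only centres far from any other-class cluster are clear-cut: closer
    # neighbours leak Gaussian-tail localisations into the 50-nm disc
    opp <- pure[pure$class != pure$class[i], ]
    d_opp <- sqrt((opp$x - pure$x[i])^2 + (opp$y - pure$y[i])^2)
    if (!nrow(opp) || min(d_opp) <= 300) next
    other <- tab[tab$mark != pure$class[i], ]
    d <- sqrt((other$x - pure$x[i])^2 + (other$y - pure$y[i])^2)
    expect_true(all(d > 50))
    checked <- checked + 1L
  }
  expect_gt(checked, 5L)
})

test_that("contamination relocates the configured fraction of second-class points", {
  cfg <- fibre_sim_config(n_rois = 6, exclusivity = 1,
                          contamination_fraction = 0.07, seed = 8)
  sim <- simulate_fibre(cfg)
  expect_equal(sim$truth$true_overlap_fraction, 0.07)
  emp <- sim$truth$n_relocated / sim$truth$n_second_class
  se <- sqrt(0.07 * 0.93 / sim$truth$n_second_class)
  expect_lt(abs(emp - 0.07), 4 * se)
  # relocated rows really sit within 50 nm of a first-class centre
  tr <- sim$truth$cluster_centres
  a_ctr <- tr[tr$class == cfg$class_labels[1], ]
  rows <- sim$truth$relocated_rows
  for (i in rows[seq_len(min(20, length(rows)))]) {
    d <- sqrt((a_ctr$x - sim$table$x[i])^2 + (a_ctr$y - sim$table$y[i])^2)
    expect_lte(min(d), 50 + 1e-9)
  }
})

test_that("gamma spacing sampler matches requested moments", {
  cfg <- fibre_sim_config(n_rois = 60, fibre_length = 10000,
                          spacing_mean = 276, spacing_sd = 164, seed = 2)
  sim <- simulate_fibre(cfg)
  sp <- sim$truth$true_spacings
  expect_gt(length(sp), 500)
  se <- 164 / sqrt(length(sp))
  # truncation at the fibre end censors long gaps, so allow a small bias
  expect_lt(abs(mean(sp) - 276), 3 * se + 0.05 * 276)
  expect_lt(abs(sd(sp) - 164), 0.15 * 164)
})

test_that("paired profiles encode the configured channel shift exactly", {
  cfg0 <- profile_sim_config(n_profiles = 1, channel_shift = 0,
                             noise_sd = 0, seed = 4)
  p0 <- simulate_paired_profiles(cfg0)$profiles[[1]]
  expect_identical(p0$channel_a, p0$channel_b)

  cfg <- profile_sim_config(n_profiles = 1, channel_shift = 200, step = 20,
                            noise_sd = 0, seed = 4)
  sim <- simulate_paired_profiles(cfg)
  p <- sim$profiles[[1]]
  expect_equal(sim$truth$true_shift, 200)
  n <- p$n
  expect_equal(p$channel_b[11:n], p$channel_a[1:(n - 10)])
})

test_that("profile spacing truth obeys the law of large numbers", {
  cfg <- profile_sim_config(n_profiles = 60, profile_length = 10000,
                            spacing_mean = 276, spacing_sd = 164,
                            seed = 13)
  sim <- simulate_paired_profiles(cfg)
  sp <- sim$truth$true_spacings
  se <- 164 / sqrt(length(sp))
  expect_lt(abs(mean(sp) - 276), 3 * se + 0.05 * 276)
})

test_that("invalid configurations are refused", {
  expect_error(profile_sim_config(profile_length = 100, step = 20),
               "profile_length")
  expect_error(profile_sim_config(channel_shift = 3000,
                                  profile_length = 5000), "channel_shift")
  expect_warning(fibre_sim_config(spacing_mean = 20, cluster_fwhm = 52),
                 "overlap")
})

test_that("generated clusters are recovered by clustering at defaults", {
  # spacing >= 4 x fwhm, no background: detection recall above 95%
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    cfg <- fibre_sim_config(n_rois = 2, fibre_length = 4000,
                            spacing_mean = 260, spacing_sd = 50,
                            cluster_fwhm = 52, locs_per_cluster_mean = 60,
                            exclusivity = 1, background_rate = 0, seed = s)
    sim <- simulate_fibre(cfg)
    tr <- sim$truth$cluster_centres
    for (lab in cfg$class_labels) {
      cs <- mean_shift_cluster(sim$table, lab)
      ctr <- tr[tr$class == lab, ]
      total <- total + nrow(ctr)
      for (i in seq_len(nrow(ctr))) {
        d <- sqrt((cs$clusters$x - ctr$x[i])^2 + (cs$clusters$y - ctr$y[i])^2)
        if (length(d) && min(d) < 50) hits <- hits + 1L
      }
    }
  }
  expect_gt(hits / total, 0.95)
})
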