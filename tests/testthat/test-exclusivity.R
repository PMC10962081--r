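test_that("overlap fractions hit the exact extremes and counted cases", {
  centres <- rbind(c(0, 0), c(400, 0))
  clustered <- blob_table(centres, 30, 10, "A", seed = 1)
  cs <- mean_shift_cluster(clustered, "A")
  expect_equal(nrow(cs$clusters), 2L)

  far <- localisation_table(seq(1000, 1190, 10), rep(500, 20), rep("B", 20))
  both <- localisation_table(c(clustered$x, far$x), c(clustered$y, far$y),
                             c(clustered$mark, far$mark))
  expect_equal(overlap_fraction(cs, both, "B")$median_fraction, 0)

  at_ctr <- localisation_table(rep(cs$clusters$x, 10), rep(cs$clusters$y, 10),
                               rep("B", 20))
  expect_equal(overlap_fraction(cs, at_ctr, "B")$median_fraction, 1)

  # 3 of 20 points within the 50-nm radius -> 0.15 (brute-force checked)
  bx <- c(cs$clusters$x[1] + c(10, -20, 30), seq(2000, 2160, 10))
  by <- c(cs$clusters$y[1] + c(5, 10, -20), rep(800, 17))
  b <- localisation_table(bx, by, rep("B", 20))
  ov <- overlap_fraction(cs, b, "B")
  d_near <- vapply(seq_len(20), function(i)
    min(sqrt((cs$clusters$x - bx[i])^2 + (cs$clusters$y - by[i])^2)),
    numeric(1))
  expect_equal(sum(d_near <= 50), 3L)
  expect_equal(ov$median_fraction, 0.15)

  empty <- mean_shift_cluster(localisation_table(1, 1, "A"), "A")
  expect_error(overlap_fraction(empty, b, "B"), "empty")
})

test_that("mark connection matches exhaustive pair counting", {
  # 4-point fixture: all 6 pairs enumerable by hand
  tab <- localisation_table(c(0, 30, 100, 250), c(0, 0, 0, 0),
                            c("A", "B", "A", "B"))
  edges <- c(0, 50, 150, 300)
  m <- mark_connection(tab, "A", "B", bin_edges = edges, n_permutations = 0)
  # bin [0,50): 30(AB); bin [50,150): 70(AB) 100(AA);
  # bin [150,300]: 150(AB) 220(BB) 250(AB)
  expect_equal(m$n_pairs, c(1L, 2L, 3L))
  expect_equal(m$p_cross, c(1, 1 / 2, 2 / 3))
  oracle <- brute_mcf(tab, "A", "B", edges)
  expect_equal(m$n_pairs, oracle$total)
  expect_equal(m$p_cross, oracle$p_cross)

  # larger random instance, exact agreement with the O(n^2) oracle
  set.seed(14)
  tab2 <- localisation_table(runif(150, 0, 1000), runif(150, 0, 1000),
                             sample(c("A", "B"), 150, replace = TRUE),
                             rep(c("r1", "r2"), length.out = 150))
  edges2 <- seq(0, 500, 50)
  m2 <- mark_connection(tab2, "A", "B", bin_edges = edges2,
                        n_permutations = 0)
  oracle2 <- brute_mcf(tab2, "A", "B", edges2)
  expect_identical(m2$n_pairs, oracle2$total)
  expect_equal(m2$p_cross, oracle2$p_cross)
})

test_that("mark connection is symmetric in its two marks and flags empty bins", {
  set.seed(15)
  tab <- localisation_table(runif(60, 0, 300), runif(60, 0, 300),
                            sample(c("A", "B"), 60, replace = TRUE))
  edges <- c(0, 50, 100, 1000, 2000)
  ab <- mark_connection(tab, "A", "B", edges, n_permutations = 39, seed = 3)
  ba <- mark_connection(tab, "B", "A", edges, n_permutations = 39, seed = 3)
  expect_equal(ab$p_cross, ba$p_cross)
  expect_equal(ab$normalised, ba$normalised)
  expect_equal(ab$envelope_low, ba$envelope_low)
  expect_equal(ab$empty_bins, 4L)  # no pairs beyond the window diagonal
  expect_true(is.na(ab$p_cross[4]))

  single <- localisation_table(1:10, 1:10, rep("A", 10))
  expect_error(mark_connection(single, "A", "B", edges), "both marks")
})

test_that("random labelling centres the normalised statistic at 1", {
  set.seed(16)
  centres <- grid_centres(12, 400)
  base <- blob_table(centres, 40, 22, "X", seed = 16)
  means <- replicate(10, {
    lab <- ifelse(runif(nrow(base)) < 0.5, "A", "B")
    tab <- localisation_table(base$x, base$y, lab)
    mean(mark_connection(tab, "A", "B", n_permutations = 0)$normalised,
         na.rm = TRUE)
  })
  expect_lt(abs(mean(means) - 1), 0.05)
})

test_that("the null envelope has close to nominal pointwise coverage", {
  set.seed(17)
  centres <- grid_centres(8, 400)
  inside <- 0L
  total <- 0L
  for (s in 1:6) {
    base <- blob_table(centres, 30, 22, "X", seed = 100 + s)
    lab <- ifelse(runif(nrow(base)) < 0.5, "A", "B")
    tab <- localisation_table(base$x, base$y, lab)
    m <- mark_connection(tab, "A", "B", bin_edges = seq(0, 400, 40),
                         n_permutations = 99, seed = s)
    ok <- !is.na(m$centred)
    inside <- inside + sum(m$centred[ok] >= m$envelope_low[ok] &
                             m$centred[ok] <= m$envelope_high[ok])
    total <- total + sum(ok)
  }
  expect_gt(inside / total, 0.85)
  expect_lte(inside / total, 1)
})

test_that("verdicts separate exclusive, random and co-clustered organisations", {
  sim <- simulate_fibre(fibre_sim_config(n_rois = 4, exclusivity = 1,
                                         seed = 19))
  m <- mark_connection(sim$table, "H3K36me3", "H3K27me3",
                       n_permutations = 99, seed = 2)
  v <- exclusivity_verdict(m, scale_limit = 200)
  expect_equal(v$summary, "repulsion")

  # all centred values forced inside the envelope -> random
  fake <- m
  fake$centred <- (fake$envelope_low + fake$envelope_high) / 2
  expect_equal(exclusivity_verdict(fake, 200)$summary, "random")

  # co-clustered marks (B points sharing A clusters, plus diffuse A
  # background so labels are not exchangeable) -> attraction at small r
  set.seed(20)
  shared <- grid_centres(6, 600)
  a_tab <- blob_table(shared, 30, 22, "A", seed = 21)
  b_tab <- blob_table(shared, 30, 22, "B", seed = 22)
  bg_n <- 180
  tab <- localisation_table(c(a_tab$x, b_tab$x, runif(bg_n, 0, 1800)),
                            c(a_tab$y, b_tab$y, runif(bg_n, 0, 1800)),
                            c(a_tab$mark, b_tab$mark, rep("A", bg_n)))
  m2 <- mark_connection(tab, "A", "B", n_permutations = 99, seed = 4)
  v2 <- exclusivity_verdict(m2, scale_limit = 100)
  expect_equal(v2$summary, "attraction")
})

test_that("zero simulated contamination implies near-zero measured overlap and repulsion", {
  sim <- simulate_fibre(fibre_sim_config(n_rois = 5, exclusivity = 1,
                                         contamination_fraction = 0,
                                         seed = 23))
  cs <- mean_shift_cluster(sim$table, "H3K36me3")
  # an all-H3K27me3 fibre has no H3K36me3 clusters and is skipped
  ov <- suppressWarnings(overlap_fraction(cs, sim$table, "H3K27me3"))
  expect_lt(ov$median_fraction, 0.01)
  m <- mark_connection(sim$table, "H3K36me3", "H3K27me3",
                       n_permutations = 99, seed = 5)
  expect_equal(exclusivity_verdict(m, 200)$summary, "repulsion")
})
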