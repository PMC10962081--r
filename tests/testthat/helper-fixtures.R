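# Shared fixture builders. Everything is generated in code; no stored data.

# Isotropic Gaussian blobs at given centres; one mark.
blob_table <- function(centres, n_per, sigma, mark = "histone", seed = NULL,
                       roi = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- rep(seq_len(nrow(centres)), each = n_per)
  n <- length(idx)
  localisation_table(centres[idx, 1] + rnorm(n, 0, sigma),
                     centres[idx, 2] + rnorm(n, 0, sigma),
                     rep(mark, n), roi)
}

# Grid of cluster centres at least `min_sep` apart.
grid_centres <- function(n, min_sep = 300) {
  side <- ceiling(sqrt(n))
  cbind(rep(seq_len(side), each = side)[seq_len(n)] * min_sep,
        rep(seq_len(side), times = side)[seq_len(n)] * min_sep)
}

# Exhaustive kernel-density mode search on a 1-nm grid: the independent
# oracle for mean-shift on small instances.
grid_modes <- function(x, y, bandwidth, pad = 150, pitch = 1) {
  gx <- seq(min(x) - pad, max(x) + pad, by = pitch)
  gy <- seq(min(y) - pad, max(y) + pad, by = pitch)
  dens <- matrix(0, length(gx), length(gy))
  for (i in seq_along(x))
    dens <- dens + exp(-outer((gx - x[i])^2, (gy - y[i])^2, "+") /
                         (2 * bandwidth^2))
  nr <- length(gx)
  nc <- length(gy)
  inner <- dens[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner >= dens[1:(nr - 2), 2:(nc - 1)] &
    inner >= dens[3:nr, 2:(nc - 1)] &
    inner >= dens[2:(nr - 1), 1:(nc - 2)] &
    inner >= dens[2:(nr - 1), 3:nc] &
    inner >= dens[1:(nr - 2), 1:(nc - 2)] &
    inner >= dens[3:nr, 3:nc] &
    inner >= dens[1:(nr - 2), 3:nc] &
    inner >= dens[3:nr, 1:(nc - 2)] &
    inner > 0.05 * max(dens)
  w <- which(is_max, arr.ind = TRUE)
  cbind(gx[w[, 1] + 1], gy[w[, 2] + 1])
}

# Brute-force cross-class pair counting: the O(n^2) oracle for the mark
# connection function.
brute_mcf <- function(table, mark_a, mark_b, bin_edges) {
  pts <- table[table$mark %in% c(mark_a, mark_b), , drop = FALSE]
  nb <- length(bin_edges) - 1
  total <- cross <- integer(nb)
  groups <- if (all(is.na(pts$roi))) list(seq_len(nrow(pts)))
            else split(seq_len(nrow(pts)), pts$roi)
  for (rows in groups) {
    m <- length(rows)
    if (m < 2) next
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- sqrt((pts$x[rows[i]] - pts$x[rows[j]])^2 +
                  (pts$y[rows[i]] - pts$y[rows[j]])^2)
        b <- findInterval(d, bin_edges, rightmost.closed = TRUE)
        if (b >= 1 && b <= nb) {
          total[b] <- total[b] + 1L
          if (pts$mark[rows[i]] != pts$mark[rows[j]])
            cross[b] <- cross[b] + 1L
        }
      }
    }
  }
  list(total = total, cross = cross,
       p_cross = ifelse(total > 0, cross / total, NA_real_))
}

# Brute-force k-th nearest neighbour distances by full sorting.
brute_knn <- function(marks, reference, k) {
  vapply(seq_len(nrow(marks)), function(i) {
    d <- sqrt((reference$x - marks$x[i])^2 + (reference$y - marks$y[i])^2)
    sort(d)[k]
  }, numeric(1))
}

# Welch t statistic and p-value from first principles.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
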