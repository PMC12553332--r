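# Fixtures are built in code; nothing binary ships with the package.

# Tiny deterministic count matrix: 4 peaks x 6 cells over 3 samples.
toy_counts <- function() {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2, 3, 3, 4, 4),
                            j = c(1, 2, 3, 4, 5, 5, 6),
                            x = c(2, 1, 1, 3, 1, 1, 2), dims = c(4, 6))
  peaks <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                      end = c(50, 150, 250, 350))
  count_matrix(m, peaks, sprintf("bc%d", 1:6))
}

toy_samples <- function(n_cells = 6, n_samples = 3, phenotype = NULL) {
  sid <- sprintf("s%d", seq_len(n_samples))
  if (is.null(phenotype)) phenotype <- rep_len(0:1, n_samples)
  sample_table(
    cells = data.frame(barcode = sprintf("bc%d", seq_len(n_cells)),
                       sample = rep_len(sid, n_cells)),
    samples = data.frame(sample = sid, phenotype = phenotype))
}

# Random row-stochastic walk matrix from a random symmetric weighted graph.
random_walk_matrix <- function(m, density = 0.4) {
  a <- matrix(0, m, m)
  upper <- which(upper.tri(a))
  on <- sample(upper, max(m, ceiling(density * length(upper))))
  a[on] <- runif(length(on))
  a <- a + t(a)
  # guarantee positive degree everywhere via a ring
  for (i in seq_len(m)) {
    j <- i %% m + 1L
    if (a[i, j] == 0) a[i, j] <- a[j, i] <- runif(1, 0.1, 1)
  }
  a / rowSums(a)
}

# Independent closed-form RWR oracle:
#   r^s = alpha * sum_{t=0}^{s-1} (1-alpha)^t W^t + (1-alpha)^s W^s
# built from explicit matrix powers, never from the recursion under test.
rwr_closed_form <- function(W, alpha, s) {
  m <- nrow(W)
  acc <- matrix(0, m, m)
  wt <- diag(m)                       # W^t, starting at t = 0
  for (t in seq_len(s) - 1L) {
    acc <- acc + (1 - alpha)^t * wt
    wt <- wt %*% W
  }
  alpha * acc + (1 - alpha)^s * wt    # wt is now W^s
}

# Small simulated dataset for pipeline-level tests (seconds, not minutes).
small_sim <- function(seed = 1, da_effect = 3, ...) {
  simulate_dataset(sim_config(n_samples_per_condition = 3,
                              cells_per_sample = 150, n_peaks = 600,
                              da_effect = da_effect, seed = seed, ...))
}

expect_rows_sum_to <- function(x, target, tol = 1e-10) {
  expect_lt(max(abs(rowSums(as.matrix(x)) - target)), tol)
}
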