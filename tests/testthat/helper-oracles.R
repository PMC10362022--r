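# Independent oracles and tiny fixture builders used across the suite.

# dense-grid brute-force minimizer of |r - 1.24 m - m ln m|: a coarse
# pass over [lo, hi] followed by a zoomed pass around the coarse argmin
grid_lea_coulson <- function(r, lo = 1e-3, hi = 50, n = 1e6) {
  obj <- function(m) abs(r - 1.24 * m - m * log(m))
  grid <- seq(lo, hi, length.out = n)
  i <- which.min(obj(grid))
  step <- grid[2L] - grid[1L]
  fine <- seq(max(lo, grid[i] - 2 * step), min(hi, grid[i] + 2 * step),
              length.out = n)
  fine[which.min(obj(fine))]
}

# exact first/second-moment recursion for the synchronous-doubling
# fluctuation model: each generation every cell divides; a wild-type
# division mutates with probability mu making both daughters mutant.
# State: (a, b) mean/var of wild-type count, (c, d) mean/var of mutant
# count, e their covariance.
fluctuation_moments <- function(n0, generations, mu) {
  a <- n0; b <- 0; c <- 0; d <- 0; e <- 0
  for (g in seq_len(generations)) {
    a2 <- 2 * (1 - mu) * a
    c2 <- 2 * c + 2 * mu * a
    b2 <- 4 * mu * (1 - mu) * a + 4 * (1 - mu)^2 * b
    d2 <- 4 * mu * (1 - mu) * a + 4 * d + 4 * mu^2 * b + 8 * mu * e
    e2 <- -4 * mu * (1 - mu) * a + 4 * (1 - mu) * (e + mu * b)
    a <- a2; b <- b2; c <- c2; d <- d2; e <- e2
  }
  list(mean_mutants = c, var_mutants = d, mean_wt = a)
}

# small count matrix with named dims
tiny_counts <- function(x, genes = NULL, samples = NULL) {
  m <- as.matrix(x)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  count_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-strain paired-chase sheet for n replicates
chase_sheet <- function(strains, n_replicates = 3) {
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      timepoint = c("T0", "T4"),
                      strain = strains, stringsAsFactors = FALSE)
  rows$sample_id <- sprintf("%s_%s_r%d", rows$strain, rows$timepoint,
                            rows$replicate)
  sample_sheet(rows[, c("sample_id", "strain", "timepoint", "replicate")])
}
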