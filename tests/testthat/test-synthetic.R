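# synthetic-data generators: determinism, truth bookkeeping, decay law,
# forward fluctuation model against the moment-recursion oracle

test_that("simulate_expression is seeded-deterministic and books truth", {
  spec <- expression_sim_spec(n_genes = 1000, seed = 11)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)

  # ~100 true DEGs per non-reference strain at deg_fraction 0.1
  expect_equal(sum(a$truth$is_deg_dpnp), 100)
  expect_equal(sum(a$truth$is_deg_PNPT1Ec), 100)
  expect_equal(true_log2fc(a$truth, "dpnp", "pnp+"), a$truth$shift_dpnp)
  expect_equal(true_log2fc(a$truth, "dpnp", "PNPT1Ec"),
               a$truth$shift_dpnp - a$truth$shift_PNPT1Ec)

  # null limit: no dispersion, no DEGs -> strain CPM agree to Poisson noise
  null_spec <- expression_sim_spec(n_genes = 200, strains = c("A", "B"),
                                   dispersion = 0, deg_fraction = 0,
                                   library_size = 1e6, seed = 5)
  sim <- simulate_expression(null_spec)
  cpm_means <- vapply(c("A", "B"), function(s)
    rowMeans(cpm(sim$matrix)[, sim$sheet$sample_id[sim$sheet$strain == s]]),
    numeric(200))
  keep <- rowMeans(cpm_means) > 50
  rel_diff <- abs(cpm_means[keep, 1] - cpm_means[keep, 2]) /
    rowMeans(cpm_means)[keep]
  expect_lt(median(rel_diff), 0.1)
})

test_that("simulate_decay obeys the decay law and its truth categories", {
  # 2^(-4/1) = 6.25% remaining, category 4; t_half = 4 -> exactly 50%
  expect_equal(100 * 2^(-4 / 1), 6.25)
  base <- tiny_counts(matrix(rep(10000L, 6), ncol = 2),
                      samples = c("A", "B"))
  spec <- decay_sim_spec(
    category_proportions = list(A = c(1, 0, 0, 0), B = c(0, 0, 0, 1)),
    noise = 0, n_replicates = 2, seed = 3)
  sim <- simulate_decay(spec, base)
  cpm_mat <- cpm(sim$matrix)
  truth_a <- sim$truth[sim$truth$strain == "A", ]
  pct_a <- 100 * cpm_mat[, "A_T4_r1"] / cpm_mat[, "A_T0_r1"]
  expect_equal(pct_a, setNames(truth_a$pct_remaining_true, truth_a$gene),
               tolerance = 1e-10)
  expect_true(all(truth_a$category == 1L))
  expect_true(all(sim$truth$category[sim$truth$strain == "B"] == 4L))
  expect_true(all(assign_category(truth_a$pct_remaining_true) == 1L))

  # stable limit: half-life far above the chase time -> ~100%, category 1
  spec_inf <- decay_sim_spec(
    category_proportions = list(A = c(1, 0, 0, 0), B = c(1, 0, 0, 0)),
    halflife_ranges = list(c(1e6, 1e6), c(4.4, 9), c(2.1, 3.8), c(0.5, 1.9)),
    noise = 0, n_replicates = 1, seed = 3)
  sim_inf <- simulate_decay(spec_inf, base)
  expect_equal(unname(sim_inf$matrix$counts[, "A_T4_r1"] /
                        sim_inf$matrix$counts[, "A_T0_r1"]),
               rep(1, 3), tolerance = 1e-4)

  # seeded determinism with noise
  spec_n <- decay_sim_spec(category_proportions = list(A = c(.25, .25, .25, .25),
                                                       B = c(.25, .25, .25, .25)),
                           noise = 0.05, seed = 9)
  expect_identical(simulate_decay(spec_n, base)$matrix$counts,
                   simulate_decay(spec_n, base)$matrix$counts)
  expect_error(decay_sim_spec(halflife_ranges = list(c(-1, 2), c(4.4, 9),
                                                     c(2.1, 3.8), c(0.5, 1.9))))
})

test_that("fluctuation simulator matches its forced outcomes and oracle moments", {
  # no mutation -> r identically zero
  fd0 <- simulate_fluctuation(fluctuation_sim_spec(mu = 0, seed = 1))
  expect_true(all(fd0$r_values == 0))

  # mu = 1, one generation from a single cell -> both daughters mutant
  fd1 <- simulate_fluctuation(fluctuation_sim_spec(n0 = 1, nf = 2, mu = 1,
                                                   seed = 1))
  expect_true(all(fd1$r_values == 2))
  expect_equal(fd1$generations, 1L)

  # distribution mean/variance against the moment-recursion oracle
  spec <- fluctuation_sim_spec(n_cultures = 1000, n0 = 100, nf = 1e5,
                               mu = 1e-4, seed = 42)
  fd <- simulate_fluctuation(spec)
  mom <- fluctuation_moments(100, fd$generations, 1e-4)
  expect_equal(mean(fd$r_values), mom$mean_mutants, tolerance = 0.15)
  # LD distributions are heavy-tailed: check the variance on log scale
  expect_equal(log(var(fd$r_values)), log(mom$var_mutants), tolerance = 0.5)
  expect_equal(fd$realized_nf, 100 * 2^fd$generations)

  # expected mutant count grows monotonically with mu
  mu_grid <- c(1e-5, 1e-4, 1e-3, 1e-2)
  means <- vapply(mu_grid, function(m)
    fluctuation_moments(100, 10, m)$mean_mutants, numeric(1))
  expect_true(all(diff(means) > 0))
  sim_means <- vapply(seq_along(mu_grid), function(i)
    mean(simulate_fluctuation(fluctuation_sim_spec(
      n_cultures = 300, n0 = 100, nf = 1e5, mu = mu_grid[i],
      seed = 100 + i))$r_values), numeric(1))
  expect_true(all(diff(sim_means) > 0))
})

test_that("measurement generator encodes its stated truths", {
  g <- simulate_measurements("growth", list(noise = 0), seed = 1)
  d <- g[g$replicate == 1, ]
  expect_equal(d$value[d$time == 30] / d$value[d$time == 0], 2)
  expect_equal(d$value[d$time == 60] / d$value[d$time == 0], 4)

  w <- simulate_measurements("western_decay", list(noise = 0), seed = 1)
  sig <- w[w$group == "signal" & w$replicate == 1, ]
  expect_equal(sig$value / sig$value[sig$time == 0], 2^(-sig$time / 78))

  dot <- simulate_measurements("dotblot", list(noise = 0), seed = 1)
  m <- vapply(split(dot$value, dot$group), mean, numeric(1))
  expect_equal(unname(m["PNPT1Ec"] / m["pnp+"]), 6)

  expect_identical(simulate_measurements("ros", seed = 4),
                   simulate_measurements("ros", seed = 4))
  expect_error(simulate_measurements("growth", list(bogus = 1)),
               "unknown parameter")
})
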