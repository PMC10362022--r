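# CPM, TMM, the NB two-group test, BH, DEG selection, overlaps, enrichment

test_that("cpm satisfies its normalization identities", {
  m <- tiny_counts(matrix(c(30, 70, 100, 900), 2))
  x <- cpm(m)
  expect_equal(unname(x[, 1]), c(3e5, 7e5))
  expect_equal(unname(colSums(x)), c(1e6, 1e6), tolerance = 1e-9)
  expect_equal(x["g1", "s2"], 1e5)
  zero <- suppressWarnings(tiny_counts(matrix(c(0, 0, 5, 5), 2)))
  expect_error(cpm(zero), "zero or negative library size")
})

test_that("tmm_factors handles symmetry, pure depth and composition shift", {
  # identical columns -> both factors exactly 1
  m <- tiny_counts(matrix(rep(c(5, 10, 50, 100, 500), 2), ncol = 2))
  expect_equal(unname(tmm_factors(m)$factors), c(1, 1))

  # column B = 2 x column A: a pure depth difference, factors stay 1
  a <- c(5, 10, 50, 100, 500)
  m2 <- tiny_counts(cbind(a, 2 * a))
  expect_equal(unname(tmm_factors(m2)$factors), c(1, 1))

  # composition shift: one gene dominating B pulls B's factor below 1
  comp <- tiny_counts(cbind(c(100, 100, 100, 100, 100),
                            c(100, 100, 100, 100, 5000)))
  f <- tmm_factors(comp)$factors
  expect_lt(f[["s2"]] / f[["s1"]], 1)

  # geometric mean of factors is 1 after centering
  set.seed(20)
  big <- tiny_counts(matrix(rnbinom(400 * 4, mu = rep(rlnorm(400, 4, 1.5), 4),
                                    size = 10), 400, 4))
  fb <- tmm_factors(big)$factors
  expect_equal(exp(mean(log(fb))), 1, tolerance = 1e-12)

  # disjoint supports cannot be normalized
  disj <- tiny_counts(matrix(c(10, 0, 0, 10), 2))
  expect_error(tmm_factors(disj, reference = "s1"), "no nonzero genes")
})

test_that("tmm_factors reproduces the reference implementation", {
  skip_if_not_installed("edgeR")
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 500
    mu <- rlnorm(n, 4, 1.5)
    depth <- c(1, 0.5, 2, 1.3)
    x <- vapply(depth, function(d) rnbinom(n, mu = mu * d, size = 1 / 0.05),
                numeric(n))
    m <- tiny_counts(x)
    mine <- tmm_factors(m)$factors
    ref <- edgeR::calcNormFactors(edgeR::DGEList(m$counts))$samples$norm.factors
    expect_equal(unname(mine), ref, tolerance = 1e-10)
  }
})

test_that("tmm_factors is invariant to gene order and per-sample scaling", {
  set.seed(31)
  x <- matrix(rnbinom(300 * 3, mu = rep(rlnorm(300, 4, 1.2), 3), size = 20),
              300, 3, dimnames = list(sprintf("g%03d", 1:300), c("s1", "s2", "s3")))
  m <- count_matrix(x)
  f <- tmm_factors(m)$factors
  perm <- sample(nrow(x))
  expect_equal(tmm_factors(count_matrix(x[perm, ]))$factors, f)
  # doubling one sample's counts (depth absorbed by its library size);
  # invariance is approximate only: the precision weights shrink with depth
  x2 <- x; x2[, 2] <- x2[, 2] * 2L
  f2 <- tmm_factors(count_matrix(x2))$factors
  expect_equal(f2, f, tolerance = 0.01)
})

test_that("bh_adjust implements the step-up rule", {
  # hand-derived: p(i) * n / i then cumulative min from the top
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # equals the reference implementation, order-invariant under permutation
  set.seed(8)
  for (i in 1:5) {
    p <- runif(97)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("nb_two_group_test identities on degenerate input", {
  x <- matrix(c(100, 0, 50, 100, 0, 50, 200, 0, 100, 200, 0, 100), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  m <- count_matrix(x, library_sizes = setNames(c(1e4, 1e4, 2e4, 2e4),
                                                paste0("s", 1:4)))
  res <- nb_two_group_test(m, c("s1", "s2"), c("s3", "s4"))
  # equal effective expression in the two groups
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-9)
  expect_true(all(res$pvalue > 0.5))
  # all-zero gene: p = 1, lfc = 0
  expect_equal(res$pvalue[res$gene == "g2"], 1)

  # group B exactly double group A at equal library sizes -> log2fc = 1
  x2 <- matrix(c(100, 40, 100, 40, 200, 80, 200, 80), nrow = 2,
               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m2 <- count_matrix(x2, library_sizes = setNames(rep(1e4, 4), paste0("s", 1:4)))
  res2 <- nb_two_group_test(m2, c("s1", "s2"), c("s3", "s4"))
  expect_equal(res2$log2fc, c(1, 1), tolerance = 0.01)
})

test_that("nb_two_group_test null p-values are calibrated (single-seed check)", {
  spec <- expression_sim_spec(n_genes = 800, strains = c("A", "B"),
                              deg_fraction = 0, library_size = 1e6, seed = 77)
  sim <- simulate_expression(spec)
  ids <- sim$sheet$sample_id
  res <- nb_two_group_test(sim$matrix, ids[1:3], ids[4:6],
                           factors = tmm_factors(sim$matrix))
  expect_lt(abs(mean(res$pvalue < 0.05) - 0.05), 0.025)
  expect_equal(attr(res, "dispersion"), 0.05, tolerance = 0.5)
})

test_that("select_degs is the pure threshold predicate", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(0.9, -1.0, 3, 0.2),
                    fdr = c(0.005, 0.005, 0.5, 0.001))
  out <- select_degs(tab, analysis_config())
  expect_equal(out$is_deg, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("none", "down", "none", "none"))
  # thresholds are config-overridable
  out2 <- select_degs(tab, analysis_config(fdr_threshold = 0.6,
                                           lfc_threshold = 0.1))
  expect_equal(out2$is_deg, c(TRUE, TRUE, TRUE, TRUE))
})

test_that("overlap_sets equals brute-force membership enumeration", {
  expect_equal(overlap_sets(list(A = "a", B = "b"))$count, c(1L, 1L, 0L))
  same <- overlap_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$count[same$region == "A&B"], 2L)
  expect_equal(sum(same$count), 2L)

  set.seed(13)
  pool <- sprintf("g%02d", 1:40)
  sets <- list(A = sample(pool, 15), B = sample(pool, 20), C = sample(pool, 10))
  ov <- overlap_sets(sets)
  # brute force over every gene of the union
  uni <- unique(unlist(sets))
  brute <- table(vapply(uni, function(g) {
    inn <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    paste(inn, collapse = "&")
  }, character(1)))
  for (i in seq_len(nrow(ov))) {
    expected <- if (ov$region[i] %in% names(brute)) unname(brute[[ov$region[i]]]) else 0L
    expect_equal(ov$count[i], as.integer(expected))
  }
  expect_equal(sum(ov$count), length(uni))
})

test_that("regulon_enrichment matches the hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  degs <- universe[1:5]
  regs <- list(inside = universe[1:4],      # regulon fully inside the DEGs
               outside = universe[11:15],   # disjoint from the DEGs
               empty = "not_in_universe")
  expect_warning(res <- regulon_enrichment(degs, universe, regs),
                 "empty within the universe")
  # hand-computed hypergeometric tail: P(X >= 4), X ~ Hyper(4, 16, 5)
  p_hand <- sum(dhyper(4, 4, 16, 5))
  expect_equal(res$pvalue[res$regulon == "inside"], p_hand, tolerance = 1e-12)
  expect_gt(res$pvalue[res$regulon == "outside"], 0.95)
  expect_equal(nrow(res), 2L)
  expect_equal(res$fdr, bh_adjust(res$pvalue))
  expect_error(regulon_enrichment(c(degs, "zzz"), universe, regs), "subset")
})

test_that("de_contrast recovers simulated DEGs with controlled FDR", {
  spec <- expression_sim_spec(n_genes = 1200, strains = c("ref", "mut"),
                              deg_fraction = 0.1, effect_size = 2,
                              library_size = 2e6, seed = 19)
  sim <- simulate_expression(spec)
  deg <- de_contrast(sim$matrix, sim$sheet, "mut", "ref")
  truth <- sim$truth$is_deg_mut
  called <- deg$is_deg[match(sim$truth$gene, deg$gene)]
  sens <- sum(called & truth) / sum(truth)
  fdr_obs <- if (sum(called)) sum(called & !truth) / sum(called) else 0
  expect_gt(sens, 0.5)
  expect_lt(fdr_obs, 0.1)
  # direction follows the true shift for the clear calls
  up <- deg$gene[deg$direction == "up"]
  expect_true(all(sim$truth$shift_mut[match(up, sim$truth$gene)] > 0))
})
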