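# percent remaining, category scheme, distributions, pairwise calls,
# chi-square

test_that("percent_remaining arithmetic, cap and assessability floor", {
  pr <- percent_remaining(c(80, 100, 50, 0.5, 10), c(20, 100, 0, 0.4, 15))
  expect_equal(pr$pct, c(25, 100, 0, NA, 100))
  expect_equal(pr$pct_raw, c(25, 100, 0, NA, 150))
  expect_equal(pr$assessable, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  # zero T0 never divides
  expect_silent(pr0 <- percent_remaining(0, 5))
  expect_true(is.na(pr0$pct))
  # cap is configurable
  expect_equal(percent_remaining(10, 15, cap = Inf)$pct, 150)
})

test_that("assign_category uses half-open intervals closed on the lower bound", {
  expect_equal(assign_category(c(80, 10, 50, 25, 75, 100, 0, 74.999)),
               c(1L, 4L, 2L, 3L, 1L, 1L, 4L, 2L))
  expect_true(is.na(assign_category(NA_real_)))
  expect_error(assign_category(-5), ">= 0")
})

test_that("halflife back-calculation inverts the decay law", {
  expect_equal(halflife_from_pct(50, 4), 4)
  expect_equal(halflife_from_pct(6.25, 4), 1)
  expect_equal(halflife_from_pct(100), Inf)
  expect_equal(halflife_from_pct(0), 0)
})

test_that("category distributions partition assessable genes", {
  base <- tiny_counts(matrix(rep(20000L, 10), ncol = 2), samples = c("X", "Y"))
  spec <- decay_sim_spec(
    category_proportions = list(X = c(0.4, 0.3, 0.2, 0.1),
                                Y = c(0.1, 0.2, 0.3, 0.4)),
    noise = 0, n_replicates = 2, seed = 21)
  sim <- simulate_decay(spec, base)
  tab <- stability_table(sim$matrix, sim$sheet)
  for (s in c("X", "Y")) {
    dist <- category_distribution(tab, s)
    expect_equal(sum(dist), sum(!is.na(tab[[paste0("category_", s)]])))
    truth_s <- sim$truth[sim$truth$strain == s, ]
    expect_equal(unname(dist),
                 unname(table(factor(truth_s$category, levels = 1:4))[1:4]),
                 ignore_attr = TRUE)
  }
  expect_error(category_distribution(tab, "nope"), "no such strain")
})

test_that("noiseless end-to-end recovery is exact and monotone in half-life", {
  set.seed(2)
  base <- tiny_counts(matrix(round(rlnorm(400, 8, 1)), ncol = 2),
                      samples = c("X", "Y"))
  spec <- decay_sim_spec(
    category_proportions = list(X = c(.25, .25, .25, .25),
                                Y = c(.4, .3, .2, .1)),
    noise = 0, seed = 5)
  sim <- simulate_decay(spec, base)
  tab <- stability_table(sim$matrix, sim$sheet)
  for (s in c("X", "Y")) {
    truth_s <- sim$truth[sim$truth$strain == s, ]
    got <- tab[[paste0("category_", s)]][match(truth_s$gene, tab$gene)]
    ok <- !is.na(got)
    expect_true(all(got[ok] == truth_s$category[ok]))
    # raising t_half never raises the category number
    o <- order(truth_s$t_half[ok])
    expect_true(all(diff(got[ok][o]) <= 0L))
  }
})

test_that("compare_strains is rule-faithful and antisymmetric", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    category_X = c(1L, 4L, 2L, NA),
                    category_Y = c(4L, 1L, 2L, 3L))
  class(tab) <- c("stability_table", "data.frame")
  cmp <- compare_strains(tab, "X", "Y")
  expect_equal(unname(cmp$calls), c("H", "L", "="))
  expect_equal(unname(cmp$totals), c(1L, 1L, 1L))
  rev_cmp <- compare_strains(tab, "Y", "X")
  expect_equal(rev_cmp$totals[["L"]], cmp$totals[["H"]])
  expect_equal(rev_cmp$totals[["H"]], cmp$totals[["L"]])

  # brute force on a synthetic full table
  base <- tiny_counts(matrix(rep(30000L, 600), ncol = 2),
                      samples = c("X", "Y"))
  sim <- simulate_decay(decay_sim_spec(
    category_proportions = list(X = c(.25, .25, .25, .25),
                                Y = c(.25, .25, .25, .25)),
    noise = 0, seed = 7), base)
  tab2 <- stability_table(sim$matrix, sim$sheet)
  cmp2 <- compare_strains(tab2, "X", "Y")
  cx <- tab2$category_X; cy <- tab2$category_Y
  both <- !is.na(cx) & !is.na(cy)
  expect_equal(cmp2$totals[["H"]], sum(cx[both] < cy[both]))
  expect_equal(cmp2$totals[["L"]], sum(cx[both] > cy[both]))
  expect_equal(cmp2$totals[["="]], sum(cx[both] == cy[both]))
})

test_that("chi_square_distributions matches closed form and the reference", {
  # identical distributions: statistic 0, p 1
  same <- chi_square_distributions(list(c(100, 100, 100, 100),
                                        c(100, 100, 100, 100)))
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)
  expect_equal(same$dof, 3L)

  # 2x2 closed form n(ad-bc)^2 / (r1 r2 c1 c2) on the worked table
  got <- chi_square_distributions(list(c(10, 20), c(20, 10)))
  expect_equal(got$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30))
  expect_equal(got$statistic, 20 / 3)
  ref <- suppressWarnings(chisq.test(rbind(c(10, 20), c(20, 10)),
                                     correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$pvalue, unname(ref$p.value))

  expect_error(chi_square_distributions(list(c(0, 10), c(0, 20))),
               "expected counts")
})

test_that("run_stability assembles consistent stage output", {
  base <- tiny_counts(matrix(rep(25000L, 900), ncol = 3),
                      samples = c("pnp+", "dpnp", "PNPT1Ec"))
  sim <- simulate_decay(decay_sim_spec(seed = 4), base)
  out <- run_stability(sim$matrix, sim$sheet)
  expect_named(out, c("table", "distributions", "chi_square", "pairwise"))
  expect_equal(length(out$pairwise), 6L)
  # each strain's distribution sums to its assessable genes
  for (s in names(out$distributions))
    expect_equal(sum(out$distributions[[s]]),
                 sum(!is.na(out$table[[paste0("category_", s)]])))
  expect_gt(out$chi_square$statistic, 0)
})
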