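# Normalization and threshold-based differential expression.
#
# CPM and TMM follow the conventional definitions (trim 30% of the M tails
# and 5% of the A tails, precision weights from the delta-method binomial
# variance, factors centered to geometric mean 1). The two-group test is a
# documented exact-style negative-binomial test conditional on each gene's
# total pseudo-count at a common method-of-moments dispersion; it stands in
# for a quasi-likelihood GLM fit, keeping the thresholding and set logic
# that carry the scientific content.

#' Counts per million
#'
#' `cpm = count / effective_library_size * 1e6`, where the effective
#' library size is `library_size * factor` when TMM factors are supplied
#' and the plain library size otherwise (in which case every column sums
#' to exactly 1e6 whenever its library size equals its column sum).
#'
#' @param mat a [count_matrix()].
#' @param factors optional [tmm_factors()] result.
#' @return numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm <- function(mat, factors = NULL) {
  stopifnot(inherits(mat, "count_matrix"))
  eff <- effective_lib_sizes(mat, factors)
  if (any(eff <= 0)) stop("zero or negative library size for sample: ",
                          paste(names(eff)[eff <= 0], collapse = ", "))
  t(t(mat$counts) / eff) * 1e6
}

effective_lib_sizes <- function(mat, factors = NULL) {
  eff <- mat$library_sizes
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "norm_factors"))
    f <- factors$factors[colnames(mat$counts)]
    if (anyNA(f)) stop("normalization factors missing for some samples")
    eff <- eff * f
  }
  eff
}

#' Trimmed mean of M-values normalization factors
#'
#' Per-sample scaling factors from pairwise trimmed, precision-weighted
#' means of log2 expression ratios against a reference sample. The
#' reference defaults to the sample whose upper-quartile CPM is closest to
#' the mean upper quartile. Genes with a zero in either member of a pair
#' are excluded. Factors are centered so their geometric mean is 1.
#'
#' @param mat a [count_matrix()] with at least two samples.
#' @param reference `"auto"` or a sample id.
#' @param logratio_trim fraction trimmed from each tail of the M values.
#' @param sum_trim fraction trimmed from each tail of the A values.
#' @return an object of class `norm_factors`: list with `factors` (named,
#'   geometric mean 1), `effective_lib_sizes` and `reference`.
#' @export
tmm_factors <- function(mat, reference = "auto",
                        logratio_trim = 0.3, sum_trim = 0.05) {
  stopifnot(inherits(mat, "count_matrix"))
  x <- mat$counts
  lib <- mat$library_sizes
  if (ncol(x) < 2L) stop("TMM needs at least two samples")
  if (any(lib <= 0)) stop("TMM needs positive library sizes")
  if (identical(reference, "auto")) {
    uq <- apply(x, 2L, quantile, probs = 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- match(reference, colnames(x))
    if (is.na(ref)) stop("reference sample not found: ", reference)
  }
  f <- vapply(seq_len(ncol(x)), function(j)
    .tmm_pair(x[, j], x[, ref], lib[j], lib[ref],
              logratio_trim, sum_trim, colnames(x)[j]),
    numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  structure(list(factors = f,
                 effective_lib_sizes = lib * f,
                 reference = colnames(x)[ref]),
            class = "norm_factors")
}

# one obs-vs-ref TMM factor (conventional algorithm, un-centered)
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim, id) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  if (!any(fin))
    stop("sample '", id, "' shares no nonzero genes with the reference")
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  if (!any(keep)) {
    warning("TMM trimming removed all genes for sample '", id,
            "'; factor set to 1")
    return(1)
  }
  fval <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (is.na(fval)) fval <- 0
  2^fval
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment: sort p ascending (ties broken by position, stable),
#' multiply by `n / rank`, enforce monotonicity by a reverse cumulative
#' minimum, cap at 1, and map back to the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return numeric vector of FDR values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  n <- length(pvalues)
  if (n == 0L) return(numeric(0L))
  o <- order(pvalues, seq_len(n), method = "radix")
  adj <- pvalues[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  adj[order(o)]
}

#' Exact-style negative-binomial two-group test
#'
#' For each gene, replicate counts are scaled to a common pseudo-library
#' (the geometric mean of the effective library sizes), rounded, and summed
#' within groups. Under the null the two group sums, conditional on their
#' total, follow the distribution induced by sums of iid NB variables at a
#' common dispersion; the two-sided p-value is the total conditional
#' probability of outcomes no more likely than the observed split. The
#' common dispersion is estimated by method of moments on the normalized
#' counts pooled within groups (floored at 1e-8) unless supplied.
#'
#' The log2 fold change is `log2(meanB / meanA)` — group B relative to
#' group A. When either group mean is zero, a pseudo-count equal to half
#' the smallest nonzero normalized group mean in the contrast is added to
#' both means, avoiding infinite fold changes while preserving ordering;
#' genes with both means positive are left untouched so that exact ratios
#' stay exact.
#'
#' @param mat a [count_matrix()].
#' @param groupA,groupB character vectors of sample ids, at least 2 each.
#' @param factors optional [tmm_factors()] result.
#' @param dispersion optional common NB dispersion; estimated when `NULL`.
#' @return data.frame `gene`, `log2fc`, `pvalue`, plus attribute
#'   `dispersion`.
#' @export
nb_two_group_test <- function(mat, groupA, groupB, factors = NULL,
                              dispersion = NULL) {
  stopifnot(inherits(mat, "count_matrix"),
            length(groupA) >= 2, length(groupB) >= 2,
            !anyDuplicated(c(groupA, groupB)))
  eff <- effective_lib_sizes(mat, factors)
  missing <- setdiff(c(groupA, groupB), colnames(mat$counts))
  if (length(missing))
    stop("sample(s) not in count matrix: ", paste(missing, collapse = ", "))
  eff <- eff[c(groupA, groupB)]
  L <- exp(mean(log(eff)))
  norm <- t(t(mat$counts[, c(groupA, groupB), drop = FALSE]) / eff) * L
  nA <- length(groupA); nB <- length(groupB)
  normA <- norm[, groupA, drop = FALSE]
  normB <- norm[, groupB, drop = FALSE]
  mA <- rowMeans(normA); mB <- rowMeans(normB)

  if (is.null(dispersion)) {
    phi_of <- function(m, v) (v - m) / m^2
    ests <- c(phi_of(mA, .row_vars(normA)), phi_of(mB, .row_vars(normB)))
    use <- is.finite(ests) & c(mA, mB) >= 1
    dispersion <- if (any(use)) mean(ests[use]) else 0
  }
  dispersion <- max(dispersion, 1e-8)

  nz <- c(mA[mA > 0], mB[mB > 0])
  pc <- if (length(nz)) min(nz) / 2 else 0.5
  needs_pc <- mA == 0 | mB == 0
  log2fc <- ifelse(needs_pc,
                   log2((mB + pc) / (mA + pc)),
                   log2(mB / mA))

  sA <- round(rowSums(normA)); sB <- round(rowSums(normB))
  pvalue <- vapply(seq_along(sA), function(i)
    .nb_exact_p(sA[i], sB[i], nA, nB, dispersion), numeric(1L))
  all_zero <- mA == 0 & mB == 0
  log2fc[all_zero] <- 0
  pvalue[all_zero] <- 1

  out <- data.frame(gene = rownames(mat$counts), log2fc = log2fc,
                    pvalue = pvalue, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "dispersion") <- dispersion
  out
}

.row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

# two-sided conditional NB test on the split (sA, sB) of s = sA + sB
.nb_exact_p <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  muA <- s * nA / (nA + nB)
  muB <- s * nB / (nA + nB)
  sizeA <- nA / phi
  sizeB <- nB / phi
  if (s > 5000) {
    lo <- max(0, qnbinom(1e-14, size = sizeB, mu = muB),
              s - qnbinom(1e-14, size = sizeA, mu = muA, lower.tail = FALSE))
    hi <- min(s, qnbinom(1e-14, size = sizeB, mu = muB, lower.tail = FALSE),
              s - qnbinom(1e-14, size = sizeA, mu = muA))
    ys <- sort(unique(c(lo:hi, sB)))
  } else {
    ys <- 0:s
  }
  logp <- dnbinom(ys, size = sizeB, mu = muB, log = TRUE) +
          dnbinom(s - ys, size = sizeA, mu = muA, log = TRUE)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  pobs <- pr[ys == sB]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#' Apply DEG thresholds to a test table
#'
#' A gene is a DEG iff `fdr < fdr_threshold` and
#' `|log2fc| >= lfc_threshold` (defaults 0.01 and 1). Pure predicate on the
#' `(fdr, log2fc)` columns; `direction` is the sign of the fold change.
#'
#' @param table data.frame with columns `log2fc` and `fdr`.
#' @param config an [analysis_config()].
#' @return the table with logical `is_deg` and character `direction`
#'   (`"up"`, `"down"`, `"none"`) columns set.
#' @export
select_degs <- function(table, config = analysis_config()) {
  stopifnot(all(c("log2fc", "fdr") %in% names(table)),
            inherits(config, "analysis_config"))
  table$is_deg <- table$fdr < config$fdr_threshold &
    abs(table$log2fc) >= config$lfc_threshold
  table$direction <- ifelse(!table$is_deg, "none",
                            ifelse(table$log2fc > 0, "up", "down"))
  table
}

#' Differential expression for one strain contrast
#'
#' Convenience wrapper: subsets the samples of the two strains, computes
#' TMM factors on that subset, runs [nb_two_group_test()] with the contrast
#' oriented as X relative to Y (`log2fc > 0` means higher in X), adjusts by
#' [bh_adjust()] and applies [select_degs()].
#'
#' @param mat a [count_matrix()].
#' @param sheet a [sample_sheet()] covering the matrix samples.
#' @param strainX,strainY strain labels of the contrast "X vs Y".
#' @param config an [analysis_config()].
#' @param timepoint timepoint label to restrict to (default `"T0"`).
#' @return a DEG table: `gene`, `log2fc`, `pvalue`, `fdr`, `is_deg`,
#'   `direction`.
#' @export
de_contrast <- function(mat, sheet, strainX, strainY,
                        config = analysis_config(), timepoint = "T0") {
  stopifnot(inherits(sheet, "sample_sheet"))
  sx <- sheet$sample_id[sheet$strain == strainX & sheet$timepoint == timepoint]
  sy <- sheet$sample_id[sheet$strain == strainY & sheet$timepoint == timepoint]
  if (length(sx) < 2 || length(sy) < 2)
    stop("each strain needs at least two samples at ", timepoint)
  sub <- subset_samples(mat, c(sy, sx))
  factors <- tmm_factors(sub)
  res <- nb_two_group_test(sub, groupA = sy, groupB = sx, factors = factors)
  res$fdr <- bh_adjust(res$pvalue)
  select_degs(res, config)
}

#' Counts for every region of a Venn partition of gene sets
#'
#' @param deg_sets named list of at least two character vectors.
#' @return data.frame with one row per non-empty membership pattern plus
#'   all single/complete patterns: columns `region` (e.g. `"A&B"` for genes
#'   in exactly A and B) and `count`. Region counts sum to the union size.
#' @export
overlap_sets <- function(deg_sets) {
  stopifnot(is.list(deg_sets), length(deg_sets) >= 2,
            !is.null(names(deg_sets)), all(nzchar(names(deg_sets))))
  deg_sets <- lapply(deg_sets, unique)
  universe <- unique(unlist(deg_sets))
  member <- vapply(deg_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L)
    member <- matrix(logical(0), 0, length(deg_sets),
                     dimnames = list(NULL, names(deg_sets)))
  k <- length(deg_sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(patterns) <- names(deg_sets)
  region <- apply(patterns, 1L, function(p)
    paste(names(deg_sets)[as.logical(p)], collapse = "&"))
  count <- apply(patterns, 1L, function(p)
    sum(apply(member, 1L, function(row) all(row == as.logical(p)))))
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher-exact regulon enrichment
#'
#' For each regulon, a one-sided (enrichment) Fisher exact test of the
#' 2x2 table DEG-membership x regulon-membership over the gene universe,
#' with BH adjustment across tested regulons. A generic stand-in for
#' curated-pathway enrichment tools.
#'
#' @param deg_set character vector of DEGs, a subset of `universe`.
#' @param universe character vector of all assessed genes.
#' @param regulons named list of gene sets.
#' @return data.frame `regulon`, `n_regulon` (within universe), `n_overlap`,
#'   `odds_ratio` (conditional MLE), `pvalue`, `fdr`. Regulons empty within
#'   the universe are skipped with a warning.
#' @export
regulon_enrichment <- function(deg_set, universe, regulons) {
  stopifnot(is.list(regulons), !is.null(names(regulons)))
  deg_set <- unique(deg_set)
  universe <- unique(universe)
  if (length(setdiff(deg_set, universe)))
    stop("'deg_set' must be a subset of 'universe'")
  rows <- lapply(names(regulons), function(nm) {
    reg <- intersect(unique(regulons[[nm]]), universe)
    if (length(reg) == 0L) {
      warning("regulon '", nm, "' is empty within the universe; skipped")
      return(NULL)
    }
    a <- length(intersect(deg_set, reg))
    b <- length(deg_set) - a
    c_ <- length(reg) - a
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L),
                      alternative = "greater")
    data.frame(regulon = nm, n_regulon = length(reg), n_overlap = a,
               odds_ratio = unname(ft$estimate), pvalue = ft$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("no testable regulon")
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out
}
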