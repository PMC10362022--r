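# Rifampicin-chase stability pipeline: percent of T0 CPM remaining at T4,
# four-category classification, per-strain distributions, pairwise
# lower/equal/higher stability calls and Pearson chi-square comparison of
# the category distributions.

#' Percent of T0 expression remaining at T4
#'
#' `pct = 100 * cpm_t4 / cpm_t0` computed on replicate-averaged CPM.
#' Genes whose mean T0 CPM falls below the detectability floor are flagged
#' not assessable (ratios of near-zero CPM are noise). Apparent
#' stabilization above the cap (default 100) is capped, with the raw value
#' retained, because the categorical scheme has no class above 100.
#'
#' @param cpm_t0,cpm_t4 numeric vectors of per-gene mean CPM at T0 and T4
#'   (same length, same gene order).
#' @param floor minimum mean T0 CPM for assessability.
#' @param cap percent value at which `pct` is capped; `Inf` disables.
#' @return data.frame `pct` (capped, `NA` when not assessable), `pct_raw`,
#'   `assessable`.
#' @export
percent_remaining <- function(cpm_t0, cpm_t4, floor = 1, cap = 100) {
  stopifnot(length(cpm_t0) == length(cpm_t4),
            all(cpm_t0 >= 0), all(cpm_t4 >= 0))
  assessable <- cpm_t0 >= floor & cpm_t0 > 0
  raw <- ifelse(assessable, 100 * cpm_t4 / cpm_t0, NA_real_)
  data.frame(pct = pmin(raw, cap), pct_raw = raw, assessable = assessable)
}

#' Assign a stability category from percent remaining
#'
#' Four categories, 1 the most stable: 1 for `pct >= 75`, 2 for
#' `[50, 75)`, 3 for `[25, 50)`, 4 for `< 25` (half-open intervals closed
#' on the lower bound, so the partition is total and deterministic).
#'
#' @param pct numeric vector of percent remaining (`NA` passes through).
#' @param bounds strictly increasing cut points, default `c(25, 50, 75)`.
#' @return integer vector of categories in `1:4` (`NA` where `pct` is
#'   `NA`).
#' @export
assign_category <- function(pct, bounds = c(25, 50, 75)) {
  stopifnot(length(bounds) == 3L, all(diff(bounds) > 0))
  if (any(pct < 0, na.rm = TRUE)) stop("'pct' must be >= 0")
  out <- 4L - findInterval(pct, bounds)
  as.integer(out)
}

#' Back-calculated half-life from percent remaining
#'
#' Auxiliary extension, not part of the categorical scheme: inverts the
#' decay law at the chase duration, `t_half = decay_time / -log2(pct/100)`.
#' Returns `Inf` at `pct >= 100` and `0` at `pct = 0`.
#'
#' @param pct percent remaining.
#' @param decay_time chase duration in minutes.
#' @return half-life estimates in minutes.
#' @export
halflife_from_pct <- function(pct, decay_time = 4) {
  ifelse(pct <= 0, 0,
         ifelse(pct >= 100, Inf, decay_time / -log2(pct / 100)))
}

#' Build the per-gene stability table for all strains
#'
#' CPM here uses plain library sizes (no TMM), matching the convention of
#' normalizing chase libraries by size only. Replicate CPMs are averaged
#' per (strain, timepoint) before the T4/T0 ratio.
#'
#' @param mat a [count_matrix()] holding paired T0/T4 samples.
#' @param sheet a [sample_sheet()] covering the matrix samples.
#' @param config an [analysis_config()] (category bounds, assessability
#'   floor, cap).
#' @return an object of class `stability_table`: a data.frame with `gene`
#'   and per strain `pct_remaining_<s>`, `pct_raw_<s>`, `category_<s>`,
#'   `t_half_est_<s>` columns; strains recorded in attribute `strains`.
#' @export
stability_table <- function(mat, sheet, config = analysis_config()) {
  stopifnot(inherits(mat, "count_matrix"), inherits(sheet, "sample_sheet"))
  cpm_all <- cpm(mat)
  strains <- unique(sheet$strain)
  out <- data.frame(gene = rownames(mat$counts), stringsAsFactors = FALSE)
  for (s in strains) {
    s0 <- sheet$sample_id[sheet$strain == s & sheet$timepoint == "T0"]
    s4 <- sheet$sample_id[sheet$strain == s & sheet$timepoint == "T4"]
    if (length(s0) == 0L || length(s4) == 0L)
      stop("strain '", s, "' lacks a T0/T4 pair")
    m0 <- rowMeans(cpm_all[, s0, drop = FALSE])
    m4 <- rowMeans(cpm_all[, s4, drop = FALSE])
    pr <- percent_remaining(m0, m4, floor = config$t0_cpm_floor,
                            cap = config$pct_cap)
    out[[paste0("pct_remaining_", s)]] <- pr$pct
    out[[paste0("pct_raw_", s)]] <- pr$pct_raw
    out[[paste0("category_", s)]] <- assign_category(pr$pct,
                                                     config$category_bounds)
    out[[paste0("t_half_est_", s)]] <- halflife_from_pct(pr$pct,
                                                         config$decay_time)
  }
  structure(out, strains = strains,
            class = c("stability_table", "data.frame"))
}

#' Category distribution of one strain
#'
#' @param table a [stability_table()].
#' @param strain strain label present in the table.
#' @return named integer vector of counts over categories 1-4; sums to the
#'   number of assessable genes for that strain.
#' @export
category_distribution <- function(table, strain) {
  col <- paste0("category_", strain)
  if (!col %in% names(table)) stop("no such strain in table: ", strain)
  cats <- table[[col]]
  if (all(is.na(cats))) stop("strain '", strain, "' has no assessable gene")
  setNames(vapply(1:4, function(k) sum(cats == k, na.rm = TRUE),
                  integer(1L)),
           paste0("cat", 1:4))
}

#' Pairwise stability comparison of two strains
#'
#' Per gene assessable in both strains, calls `H` (higher stability in X:
#' category(X) < category(Y)), `L` (lower) or `=` (equal categories).
#' Antisymmetric by construction: swapping X and Y swaps L and H.
#'
#' @param table a [stability_table()].
#' @param strainX,strainY strain labels.
#' @return list with `calls` (named character vector per assessable gene)
#'   and `totals` (counts of `L`, `=`, `H`).
#' @export
compare_strains <- function(table, strainX, strainY) {
  cx <- table[[paste0("category_", strainX)]]
  cy <- table[[paste0("category_", strainY)]]
  if (is.null(cx)) stop("no such strain in table: ", strainX)
  if (is.null(cy)) stop("no such strain in table: ", strainY)
  both <- !is.na(cx) & !is.na(cy)
  calls <- ifelse(cx[both] < cy[both], "H",
                  ifelse(cx[both] > cy[both], "L", "="))
  names(calls) <- table$gene[both]
  totals <- setNames(vapply(c("L", "=", "H"), function(k) sum(calls == k),
                            integer(1L)),
                     c("L", "=", "H"))
  list(calls = calls, totals = totals)
}

#' Pearson chi-square comparison of category distributions
#'
#' @param dist_list list of at least two category count vectors of equal
#'   length (rows of a strains-by-categories contingency table).
#' @return list with `statistic`, `dof`, `pvalue`.
#' @export
chi_square_distributions <- function(dist_list) {
  stopifnot(is.list(dist_list), length(dist_list) >= 2)
  tab <- do.call(rbind, dist_list)
  if (any(tab < 0)) stop("negative cell count")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0))
    stop("expected counts must be positive in every cell; drop empty categories")
  stat <- sum((tab - expected)^2 / expected)
  dof <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, dof = dof,
       pvalue = pchisq(stat, df = dof, lower.tail = FALSE))
}

#' Full stability stage: table, distributions, pairwise calls, chi-square
#'
#' @param mat,sheet,config as in [stability_table()].
#' @return list with `table`, `distributions` (named list per strain),
#'   `chi_square`, and `pairwise` (named list `X_vs_Y` of
#'   [compare_strains()] results over all ordered strain pairs).
#' @export
run_stability <- function(mat, sheet, config = analysis_config()) {
  tab <- stability_table(mat, sheet, config)
  strains <- attr(tab, "strains")
  dists <- lapply(setNames(strains, strains),
                  function(s) category_distribution(tab, s))
  chi <- if (length(strains) >= 2) chi_square_distributions(dists) else NULL
  pairwise <- list()
  if (length(strains) >= 2) {
    for (i in seq_along(strains)) for (j in seq_along(strains)) {
      if (i == j) next
      pairwise[[paste0(strains[i], "_vs_", strains[j])]] <-
        compare_strains(tab, strains[i], strains[j])
    }
  }
  list(table = tab, distributions = dists, chi_square = chi,
       pairwise = pairwise)
}
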