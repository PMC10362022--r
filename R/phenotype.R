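# Phenotype quantifications: generation time from exponential growth,
# protein half-life from chase densitometry, ROS normalization, relative
# densitometry, molecules-per-cell arithmetic, and the shared one-way
# ANOVA / Tukey HSD / compact-letter-display helper (with two-group
# dispatch to the Student t-test).

#' Generation time from an OD600 growth series
#'
#' Fits log2(OD) against time by least squares over the exponential
#' window, per replicate; g = 1/slope in minutes. The window may be an OD
#' range `c(lo, hi)` or `"auto"`: the longest contiguous run of at least
#' 4 points whose log-linear fit reaches R-squared >= 0.99 (ties broken by
#' the better fit).
#'
#' @param series a measurement series data.frame (`time` minutes, `value`
#'   OD600, `replicate`), e.g. from [simulate_measurements()].
#' @param window `"auto"` or numeric `c(od_lo, od_hi)`.
#' @return list with `g` (mean over replicates, minutes), `sd`, and
#'   `per_replicate`.
#' @export
generation_time <- function(series, window = "auto") {
  stopifnot(all(c("time", "value", "replicate") %in% names(series)))
  per_rep <- vapply(split(series, series$replicate), function(d) {
    d <- d[order(d$time), ]
    if (is.numeric(window)) {
      d <- d[d$value >= window[1L] & d$value <= window[2L], ]
      if (nrow(d) < 3L) stop("fewer than 3 points in the OD window")
      idx <- seq_len(nrow(d))
    } else {
      idx <- .auto_exp_window(d$time, d$value)
    }
    if (any(d$value[idx] <= 0)) stop("non-positive OD inside the window")
    fit <- lm(log2(value) ~ time, data = d[idx, ])
    slope <- coef(fit)[["time"]]
    if (slope <= 0) stop("non-positive growth slope; no exponential phase found")
    1 / slope
  }, numeric(1L))
  list(g = mean(per_rep), sd = if (length(per_rep) > 1) sd(per_rep) else NA_real_,
       per_replicate = per_rep)
}

# longest contiguous run (>= 4 points) with log-linear R^2 >= 0.99
.auto_exp_window <- function(time, value) {
  n <- length(time)
  if (n < 4L) stop("need at least 4 points for automatic window selection")
  ok <- value > 0
  best <- NULL; best_len <- 0L; best_r2 <- -Inf
  for (i in seq_len(n - 3L)) {
    for (j in seq(i + 3L, n)) {
      if (!all(ok[i:j])) next
      y <- log2(value[i:j]); x <- time[i:j]
      if (stats::var(y) == 0) next  # flat run: no growth
      r2 <- suppressWarnings(stats::cor(x, y)^2)
      if (is.finite(r2) && r2 >= 0.99 && stats::cor(x, y) > 0) {
        len <- j - i + 1L
        if (len > best_len || (len == best_len && r2 > best_r2)) {
          best <- i:j; best_len <- len; best_r2 <- r2
        }
      }
    }
  }
  if (is.null(best))
    stop("no exponential phase found: no contiguous run of >= 4 points ",
         "fits log-linear growth with R^2 >= 0.99")
  best
}

#' Protein half-life from chase densitometry
#'
#' Signals are divided by the paired loading control, normalized to the
#' first time point (100%), and ln(ratio) is fitted against time by
#' unweighted least squares, replicates pooled. A non-negative slope is
#' reported as "stable" (infinite half-life); otherwise
#' `t_half = ln(2) / |slope|`, returned in hours.
#'
#' @param series measurement series with `group == "signal"` rows.
#' @param loading_control series with the control values; defaults to the
#'   `group == "control"` rows of `series`. Must pair with the signal rows
#'   by (replicate, time).
#' @return list with `t_half_hours`, `stable` (logical), `slope_per_min`.
#' @export
protein_half_life <- function(series, loading_control = NULL) {
  sig <- series[series$group == "signal", , drop = FALSE]
  ctl <- if (is.null(loading_control))
    series[series$group == "control", , drop = FALSE]
  else
    loading_control
  if (nrow(sig) == 0L) stop("no signal rows in series")
  key <- function(d) paste(d$replicate, d$time)
  ctl <- ctl[match(key(sig), key(ctl)), , drop = FALSE]
  if (anyNA(ctl$value)) stop("loading control does not pair with every signal point")
  if (any(ctl$value <= 0)) stop("loading control must be positive")
  ratio <- sig$value / ctl$value
  t0 <- min(sig$time)
  norm <- unlist(lapply(split(seq_len(nrow(sig)), sig$replicate), function(i) {
    r0 <- ratio[i][sig$time[i] == t0][1L]
    if (!is.finite(r0) || r0 <= 0) stop("first time point defines 100% and must be positive")
    ratio[i] / r0
  }), use.names = FALSE)
  tt <- unlist(lapply(split(sig$time, sig$replicate), identity), use.names = FALSE)
  fit <- lm(log(norm) ~ tt)
  slope <- coef(fit)[["tt"]]
  if (slope >= 0)
    return(list(t_half_hours = Inf, stable = TRUE, slope_per_min = slope))
  list(t_half_hours = log(2) / abs(slope) / 60, stable = FALSE,
       slope_per_min = slope)
}

#' Normalize fluorescence by culture density
#'
#' `nf = fluorescence / od600`, the ROS readout per unit biomass.
#'
#' @param fluorescence fluorescence values (arbitrary units), >= 0.
#' @param od600 matching OD600 values, > 0.
#' @return normalized fluorescence values.
#' @export
normalize_ros <- function(fluorescence, od600) {
  stopifnot(length(fluorescence) == length(od600) || length(od600) == 1L)
  if (any(od600 <= 0)) stop("OD600 must be positive")
  if (any(fluorescence < 0)) stop("fluorescence must be non-negative")
  fluorescence / od600
}

#' Relative quantification against a reference sample
#'
#' `ra_i = signal_i / signal_reference`; the reference maps to exactly 1.
#'
#' @param signals named numeric vector of densitometry signals.
#' @param reference name of the reference sample.
#' @return named numeric vector of relative amounts.
#' @export
relative_quant <- function(signals, reference) {
  if (!reference %in% names(signals))
    stop("reference sample not found: ", reference)
  if (signals[[reference]] <= 0) stop("reference signal must be positive")
  signals / signals[[reference]]
}

#' Molecules-per-cell estimate from fold-difference arithmetic
#'
#' Given the absolute abundance of the benchmark enzyme (molecules/cell),
#' the fold-excess of its tagged form over the tagged query protein, and
#' the fold-excess of the untagged query over its own tagged form, the net
#' abundance deficit of the query is their ratio and the estimate follows:
#' `fold_deficit = tagged_fold / untagged_fold`;
#' `estimate = benchmark_molecules / fold_deficit`. Exact arithmetic on the
#' inputs.
#'
#' @param ec_molecules benchmark molecules per cell (> 0).
#' @param tagged_fold_ec_over_h fold-excess of tagged benchmark over tagged
#'   query (> 0).
#' @param untagged_fold_h_over_tagged fold-excess of untagged query over
#'   tagged query (> 0).
#' @return list with `fold_deficit` and `estimate`.
#' @export
molecules_per_cell <- function(ec_molecules, tagged_fold_ec_over_h,
                               untagged_fold_h_over_tagged) {
  stopifnot(ec_molecules > 0, tagged_fold_ec_over_h > 0,
            untagged_fold_h_over_tagged > 0)
  fold_deficit <- tagged_fold_ec_over_h / untagged_fold_h_over_tagged
  list(fold_deficit = fold_deficit, estimate = ec_molecules / fold_deficit)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Three or more groups: one-way ANOVA F and p, Tukey HSD pairwise
#' p-values, and letters such that groups sharing a letter are not
#' significantly different at `alpha`. Exactly two groups dispatch to a
#' two-tailed pooled-variance Student t-test (whose p equals the two-group
#' ANOVA p through the F = t^2 identity).
#'
#' @param groups named list of numeric replicate vectors (>= 2 values
#'   each).
#' @param alpha significance level for the letter display.
#' @return list with `method` (`"anova_tukey"` or `"t_test"`), `statistic`
#'   (F or t), `pvalue`, `pairwise` (data.frame `groupA`, `groupB`,
#'   `pvalue`; `NULL` for two groups the Tukey table degenerates to the
#'   single comparison), `letters` (named character vector) and
#'   `means`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), !is.null(names(groups)),
            all(vapply(groups, length, integer(1L)) >= 2))
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1L))
  if (k < 2) stop("need at least two groups")
  if (k == 2) {
    tt <- t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
    sig <- tt$p.value < alpha
    letters <- if (sig) c("a", "b") else c("a", "a")
    names(letters) <- names(groups)
    return(list(method = "t_test", statistic = unname(tt$statistic),
                pvalue = tt$p.value,
                pairwise = data.frame(groupA = names(groups)[1L],
                                      groupB = names(groups)[2L],
                                      pvalue = tt$p.value,
                                      stringsAsFactors = FALSE),
                letters = letters, means = means))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  fstat <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  tk <- TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- data.frame(groupA = vapply(pairs, `[`, character(1L), 1L),
                         groupB = vapply(pairs, `[`, character(1L), 2L),
                         pvalue = tk[, "p adj"],
                         stringsAsFactors = FALSE, row.names = NULL)
  # identical groups: the F ratio is 0/0; report F = 0, p = 1, all tied
  if (stats::var(df$value) == 0) {
    fstat <- 0; pval <- 1; pairwise$pvalue <- 1
  }
  letters <- .compact_letters(names(groups), means, pairwise, alpha)
  list(method = "anova_tukey", statistic = fstat, pvalue = pval,
       pairwise = pairwise, letters = letters, means = means)
}

# greedy compact letter display from the pairwise significance matrix:
# sweep groups by decreasing mean; each maximal run of mutually
# non-significant groups gets one letter; runs that add no new group are
# dropped.
.compact_letters <- function(names_, means, pairwise, alpha) {
  ord <- names_[order(-means[names_])]
  nonsig <- matrix(TRUE, length(ord), length(ord),
                   dimnames = list(ord, ord))
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$groupA[i]; b <- pairwise$groupB[i]
    ns <- pairwise$pvalue[i] >= alpha
    nonsig[a, b] <- ns; nonsig[b, a] <- ns
  }
  sets <- list()
  for (i in seq_along(ord)) {
    run <- ord[i]
    for (j in seq_along(ord)[-seq_len(i)]) {
      if (all(nonsig[ord[j], run])) run <- c(run, ord[j]) else break
    }
    covered <- any(vapply(sets, function(s) all(run %in% s), logical(1L)))
    if (!covered) sets[[length(sets) + 1L]] <- run
  }
  letters <- setNames(rep("", length(ord)), ord)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) letters[g] <- paste0(letters[g], letters_alpha(s))
  }
  letters[names_]
}

letters_alpha <- function(i) {
  if (i <= 26L) letters[i] else paste0(letters[(i - 1L) %/% 26L], letters[(i - 1L) %% 26L + 1L])
}
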