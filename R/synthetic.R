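# Seeded generators emulating the statistical structure the analysis
# assumes: negative-binomial bulk RNA-Seq counts for three strains, a
# rifampicin-chase T0/T4 pair with gene-specific exponential decay,
# synchronous-doubling Luria-Delbrueck cultures, and phenotype measurement
# series. Every generator records its ground truth and is a deterministic
# function of (spec, seed).

#' Specification for a bulk expression simulation
#'
#' Defaults emulate the assumed real-data design: three strains
#' (`pnp+`, `dpnp`, `PNPT1Ec`) with three replicate cultures each, roughly
#' an E. coli-sized gene set, log-normal relative abundances, a common
#' negative-binomial dispersion of 0.05 (typical bulk RNA-Seq
#' overdispersion) and 5e6 assigned reads per library.
#'
#' @param n_genes number of genes.
#' @param strains strain labels; the first is the reference strain carrying
#'   no expression shift.
#' @param n_replicates replicate cultures per strain.
#' @param mean_log_expression named vector `c(meanlog=, sdlog=)` of the
#'   log-normal law for relative gene abundances (only `sdlog` shapes the
#'   dynamic range; abundances are renormalized).
#' @param dispersion common NB dispersion (variance = mu + dispersion*mu^2);
#'   0 gives Poisson counts.
#' @param deg_fraction per non-reference strain, the fraction of genes with
#'   a true expression shift versus the reference.
#' @param effect_size absolute true log2 fold change of shifted genes.
#' @param library_size expected assigned reads per sample.
#' @param seed integer seed.
#' @return a list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 4000,
                                strains = c("pnp+", "dpnp", "PNPT1Ec"),
                                n_replicates = 3,
                                mean_log_expression = c(meanlog = 3, sdlog = 1.5),
                                dispersion = 0.05,
                                deg_fraction = 0.1,
                                effect_size = 1,
                                library_size = 5e6,
                                seed = 1L) {
  stopifnot(n_genes >= 2, length(strains) >= 1, !anyDuplicated(strains),
            n_replicates >= 1, dispersion >= 0,
            deg_fraction >= 0, deg_fraction <= 1,
            effect_size >= 0, library_size > 0)
  structure(as.list(environment()), class = "expression_sim_spec")
}

.sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

.rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a gene-by-sample count matrix with known differential expression
#'
#' Relative abundances are drawn log-normal and shared across strains;
#' per non-reference strain, a `deg_fraction` of genes gets a true log2
#' shift of `+/- effect_size` (sign equiprobable). Counts are
#' gamma-Poisson. Expression shifts are not re-normalized within a strain,
#' so a strain's realized library composition shifts the way real libraries
#' do; the truth table stores the per-strain shift so the true log2 fold
#' change of any contrast A vs B is `shift[A] - shift[B]`.
#'
#' @param spec an [expression_sim_spec()].
#' @return list with elements `matrix` (a [count_matrix()]), `sheet` (a
#'   [sample_sheet()], all samples labelled `T0`), and `truth` (data.frame:
#'   `gene`, one `shift_<strain>` column per non-reference strain, and one
#'   logical `is_deg_<strain>` column).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  genes <- .sim_gene_ids(spec$n_genes)
  w <- rlnorm(spec$n_genes,
              meanlog = spec$mean_log_expression[["meanlog"]],
              sdlog = spec$mean_log_expression[["sdlog"]])
  rel <- w / sum(w)

  shifts <- matrix(0, nrow = spec$n_genes, ncol = length(spec$strains),
                   dimnames = list(genes, spec$strains))
  n_deg <- round(spec$deg_fraction * spec$n_genes)
  for (s in spec$strains[-1L]) {
    if (n_deg > 0) {
      idx <- sample.int(spec$n_genes, n_deg)
      sgn <- sample(c(-1, 1), n_deg, replace = TRUE)
      shifts[idx, s] <- sgn * spec$effect_size
    }
  }

  sample_ids <- as.vector(vapply(spec$strains, function(s)
    paste0(s, "_T0_r", seq_len(spec$n_replicates)),
    character(spec$n_replicates)))
  counts <- matrix(0, nrow = spec$n_genes, ncol = length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (s in spec$strains) {
    mu <- rel * 2^shifts[, s] * spec$library_size
    for (r in seq_len(spec$n_replicates)) {
      counts[, paste0(s, "_T0_r", r)] <- .rcounts(spec$n_genes, mu, spec$dispersion)
    }
  }

  sheet <- sample_sheet(data.frame(
    sample_id = sample_ids,
    strain = rep(spec$strains, each = spec$n_replicates),
    timepoint = "T0",
    replicate = rep(seq_len(spec$n_replicates), times = length(spec$strains)),
    stringsAsFactors = FALSE))

  truth <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in spec$strains[-1L]) {
    truth[[paste0("shift_", s)]] <- shifts[, s]
    truth[[paste0("is_deg_", s)]] <- shifts[, s] != 0
  }
  list(matrix = count_matrix(counts), sheet = sheet, truth = truth)
}

#' True log2 fold change of a contrast from an expression truth table
#' @param truth truth data.frame from [simulate_expression()].
#' @param strainX,strainY strain labels; the reference strain has shift 0.
#' @return numeric vector of true `log2(X/Y)` per gene.
#' @export
true_log2fc <- function(truth, strainX, strainY) {
  get_shift <- function(s) {
    col <- paste0("shift_", s)
    if (col %in% names(truth)) truth[[col]] else rep(0, nrow(truth))
  }
  get_shift(strainX) - get_shift(strainY)
}

#' Specification for a rifampicin-chase decay simulation
#'
#' Each strain draws per-gene stability categories from its own proportion
#' vector; half-lives are then drawn uniformly within the category's range.
#' Default ranges map, through the decay law `f = 2^(-t / t_half)` at
#' t = 4 min, strictly inside the 25/50/75 percent-remaining bounds, so a
#' gene's half-life always implies its truth category with margin. Default
#' proportions are qualitative presets shaped like the study system: the
#' strain expressing the human enzyme is rich in stable category-1 RNAs,
#' the wild type rich in unstable category-4 RNAs.
#'
#' @param category_proportions named list, per strain a length-4 proportion
#'   vector over categories 1 (most stable) to 4 (least stable), summing
#'   to 1.
#' @param halflife_ranges list of 4 `c(lo, hi)` half-life ranges in minutes,
#'   one per category.
#' @param decay_time minutes between T0 and T4.
#' @param noise NB dispersion used to resample the T4 counts; 0 means
#'   noiseless (T4 counts are the real-valued expectations). T0 counts are
#'   always the baseline expectations: the chase is anchored at the
#'   measured T0 profile and only the decayed timepoint is re-drawn.
#' @param n_replicates replicate cultures per strain and timepoint.
#' @param seed integer seed.
#' @return a list of class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(category_proportions = list(
                             "pnp+"    = c(0.15, 0.20, 0.25, 0.40),
                             "dpnp"    = c(0.25, 0.30, 0.25, 0.20),
                             "PNPT1Ec" = c(0.45, 0.30, 0.15, 0.10)),
                           halflife_ranges = list(c(12, 40), c(4.4, 9),
                                                  c(2.1, 3.8), c(0.5, 1.9)),
                           decay_time = 4,
                           noise = 0.05,
                           n_replicates = 3,
                           seed = 1L) {
  stopifnot(length(halflife_ranges) == 4L, noise >= 0, decay_time > 0,
            n_replicates >= 1)
  for (p in category_proportions) {
    stopifnot(length(p) == 4L, abs(sum(p) - 1) < 1e-8, all(p >= 0))
  }
  for (h in halflife_ranges) stopifnot(length(h) == 2L, h[1L] > 0, h[2L] >= h[1L])
  # every half-life range must land inside its category's percent bounds
  bounds <- c(25, 50, 75)
  for (k in 1:4) {
    pct <- 100 * 2^(-decay_time / halflife_ranges[[k]])
    lo_ok <- if (k == 4L) min(pct) >= 0 else min(pct) >= bounds[4L - k]
    hi_ok <- if (k == 1L) TRUE else max(pct) < bounds[5L - k]
    if (!lo_ok || !hi_ok)
      stop(sprintf("halflife range for category %d maps outside its percent bounds", k))
  }
  structure(as.list(environment())[names(formals(decay_sim_spec))],
            class = "decay_sim_spec")
}

#' Simulate a paired T0/T4 rifampicin-chase experiment
#'
#' The baseline matrix supplies the expected T0 expression, one column per
#' strain; T0 replicate columns carry these expectations unchanged.
#' Expected T4 counts follow `T0 * 2^(-decay_time / t_half)`. With
#' `noise > 0` the T4 counts are NB-resampled around their expectations;
#' with `noise = 0` the expectations themselves are returned (real-valued;
#' noiseless output is an expectation, not a realizable read count).
#' Library sizes of all output samples are pinned to the baseline column
#' sum of their strain, emulating equal sequencing depth anchored at T0 so
#' that CPM ratios estimate true RNA decay.
#'
#' @param spec a [decay_sim_spec()].
#' @param baseline a [count_matrix()] whose columns are the strains named in
#'   `spec$category_proportions`.
#' @return list with `matrix` (T0/T4 [count_matrix()]), `sheet` (a
#'   [sample_sheet()]), and `truth` (data.frame `gene`, `strain`, `t_half`,
#'   `category`, `pct_remaining_true`).
#' @export
simulate_decay <- function(spec, baseline) {
  stopifnot(inherits(spec, "decay_sim_spec"), inherits(baseline, "count_matrix"))
  strains <- names(spec$category_proportions)
  missing <- setdiff(strains, colnames(baseline$counts))
  if (length(missing))
    stop("baseline lacks strain column(s): ", paste(missing, collapse = ", "))
  set.seed(spec$seed)
  genes <- rownames(baseline$counts)
  n <- length(genes)
  noiseless <- spec$noise <= 0

  cols <- list(); libs <- c(); sheet_rows <- list(); truth_rows <- list()
  for (s in strains) {
    mu0 <- baseline$counts[, s]
    cat_s <- sample.int(4L, n, replace = TRUE, prob = spec$category_proportions[[s]])
    lo <- vapply(spec$halflife_ranges, `[`, numeric(1L), 1L)[cat_s]
    hi <- vapply(spec$halflife_ranges, `[`, numeric(1L), 2L)[cat_s]
    t_half <- runif(n, lo, hi)
    f <- 2^(-spec$decay_time / t_half)
    depth <- sum(mu0)
    for (r in seq_len(spec$n_replicates)) {
      for (tp in c("T0", "T4")) {
        mu <- if (tp == "T0") mu0 else mu0 * f
        v <- if (noiseless || tp == "T0") mu else .rcounts(n, mu, spec$noise)
        id <- sprintf("%s_%s_r%d", s, tp, r)
        cols[[id]] <- v
        libs[id] <- depth
        sheet_rows[[id]] <- data.frame(sample_id = id, strain = s,
                                       timepoint = tp, replicate = r,
                                       stringsAsFactors = FALSE)
      }
    }
    truth_rows[[s]] <- data.frame(gene = genes, strain = s, t_half = t_half,
                                  category = cat_s,
                                  pct_remaining_true = 100 * f,
                                  stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes
  mat <- count_matrix(counts, library_sizes = pmax(libs, colSums(counts)),
                      integer = !noiseless)
  list(matrix = mat,
       sheet = sample_sheet(do.call(rbind, sheet_rows)),
       truth = do.call(rbind, c(truth_rows, make.row.names = FALSE)))
}

#' Specification for a Luria-Delbrueck fluctuation simulation
#'
#' @param n_cultures number of independent parallel cultures (default 12,
#'   the usual bench design).
#' @param n0 initial cells per culture.
#' @param nf final cells per culture; rounded to the nearest whole number
#'   of doublings of `n0`.
#' @param mu per-division mutation probability (small).
#' @param plating_fraction fraction of each culture plated on selective
#'   medium (default 1: undiluted cultures plated).
#' @param seed integer seed.
#' @return a list of class `fluctuation_sim_spec`.
#' @export
fluctuation_sim_spec <- function(n_cultures = 12, n0 = 100, nf = 1e5,
                                 mu = 1e-4, plating_fraction = 1, seed = 1L) {
  stopifnot(n_cultures >= 2, n0 >= 1, nf > n0, mu >= 0, mu <= 1,
            plating_fraction > 0, plating_fraction <= 1)
  structure(as.list(environment()), class = "fluctuation_sim_spec")
}

#' Simulate parallel cultures of a fluctuation assay
#'
#' Synchronous-doubling model: each generation every cell divides; each
#' wild-type division mutates with probability `mu`, in which case both
#' daughters are mutant; mutants breed true. The number of generations is
#' `round(log2(nf / n0))` and the realized final population is exactly
#' `n0 * 2^generations`. Mutant counts are binomially thinned by the
#' plating fraction.
#'
#' @param spec a [fluctuation_sim_spec()].
#' @return an object of class `fluctuation_data`: list with `r_values`
#'   (mutant colonies per culture), `titers` (viable counts per culture),
#'   `generations`, `realized_nf` and `true_mu`.
#' @export
simulate_fluctuation <- function(spec) {
  stopifnot(inherits(spec, "fluctuation_sim_spec"))
  set.seed(spec$seed)
  gens <- max(1L, as.integer(round(log2(spec$nf / spec$n0))))
  realized_nf <- spec$n0 * 2^gens
  r <- integer(spec$n_cultures)
  for (i in seq_len(spec$n_cultures)) {
    w <- spec$n0; m <- 0
    for (g in seq_len(gens)) {
      k <- rbinom(1L, w, spec$mu)
      m <- 2 * m + 2 * k
      w <- 2 * (w - k)
    }
    r[i] <- if (spec$plating_fraction < 1)
      rbinom(1L, m, spec$plating_fraction) else m
  }
  fluctuation_data(r_values = r,
                   titers = rep(round(realized_nf * spec$plating_fraction),
                                spec$n_cultures),
                   true_mu = spec$mu,
                   generations = gens,
                   realized_nf = realized_nf)
}

#' Construct fluctuation-assay data
#' @param r_values non-negative integer mutant colony counts, one per
#'   culture.
#' @param titers positive viable counts per culture (permissive plates).
#' @param true_mu optional per-division mutation probability when simulated.
#' @param generations,realized_nf optional simulation provenance.
#' @return a list of class `fluctuation_data`.
#' @export
fluctuation_data <- function(r_values, titers, true_mu = NULL,
                             generations = NULL, realized_nf = NULL) {
  stopifnot(length(r_values) >= 2, length(titers) == length(r_values),
            all(r_values >= 0), all(r_values == round(r_values)),
            all(titers > 0))
  structure(list(r_values = as.integer(r_values), titers = titers,
                 true_mu = true_mu, generations = generations,
                 realized_nf = realized_nf),
            class = "fluctuation_data")
}

#' Simulate a phenotype measurement series
#'
#' Generates the four series types consumed by the phenotype stage, each
#' with multiplicative log-normal noise (`noise` is the sdlog; 0 means
#' exact). Ground-truth parameters are attached as the `truth` attribute.
#'
#' * `growth`: OD600 growing as `od0 * 2^(t / g)`; defaults g = 30 min,
#'   sampled every 10 min for 150 min, 3 replicates.
#' * `western_decay`: antigen signal decaying as `2^(-t / t_half_min)` over
#'   a constant loading control; defaults t_half 78 min (1.3 h) sampled at
#'   0/20/40/60 min, the study's chase design.
#' * `ros`: fluorescence = true normalized fluorescence x OD600 per group;
#'   5 replicates.
#' * `dotblot`: densitometry signals at true ratios versus a reference
#'   sample; 6 replicates.
#'
#' @param kind one of `"growth"`, `"western_decay"`, `"ros"`, `"dotblot"`.
#' @param params named list overriding kind-specific defaults (see Details).
#' @param seed integer seed.
#' @return a data.frame (`time`, `value`, `replicate`, `group`) of class
#'   `c("measurement_series","data.frame")`, time in minutes, with
#'   attributes `truth` and `unit`.
#' @export
simulate_measurements <- function(kind = c("growth", "western_decay",
                                           "ros", "dotblot"),
                                  params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  defaults <- switch(kind,
    growth = list(od0 = 0.05, g = 30, t_max = 150, dt = 10,
                  n_replicates = 3, noise = 0),
    western_decay = list(t_half_min = 78, times = c(0, 20, 40, 60),
                         signal0 = 100, control = 100,
                         n_replicates = 3, noise = 0),
    ros = list(groups = c("pnp+" = 2000, "dpnp" = 2500, "PNPT1Ec" = 6000),
               od600 = 0.8, n_replicates = 5, noise = 0.1),
    dotblot = list(ratios = c("pnp+" = 1, "dpnp" = 1, "PNPT1Ec" = 6),
                   reference = "pnp+", signal_ref = 1000,
                   n_replicates = 6, noise = 0.1))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  lnoise <- function(n) if (p$noise > 0) rlnorm(n, 0, p$noise) else rep(1, n)

  df <- switch(kind,
    growth = {
      tt <- seq(0, p$t_max, by = p$dt)
      do.call(rbind, lapply(seq_len(p$n_replicates), function(r)
        data.frame(time = tt, value = p$od0 * 2^(tt / p$g) * lnoise(length(tt)),
                   replicate = r, group = "culture",
                   stringsAsFactors = FALSE)))
    },
    western_decay = {
      do.call(rbind, lapply(seq_len(p$n_replicates), function(r) {
        frac <- 2^(-p$times / p$t_half_min)
        rbind(
          data.frame(time = p$times, value = p$signal0 * frac * lnoise(length(p$times)),
                     replicate = r, group = "signal", stringsAsFactors = FALSE),
          data.frame(time = p$times, value = p$control * lnoise(length(p$times)),
                     replicate = r, group = "control", stringsAsFactors = FALSE))
      }))
    },
    ros = {
      do.call(rbind, lapply(names(p$groups), function(s)
        data.frame(time = 0, value = p$groups[[s]] * p$od600 * lnoise(p$n_replicates),
                   replicate = seq_len(p$n_replicates), group = s,
                   stringsAsFactors = FALSE)))
    },
    dotblot = {
      do.call(rbind, lapply(names(p$ratios), function(s)
        data.frame(time = 0, value = p$signal_ref * p$ratios[[s]] * lnoise(p$n_replicates),
                   replicate = seq_len(p$n_replicates), group = s,
                   stringsAsFactors = FALSE)))
    })
  rownames(df) <- NULL
  structure(df, truth = p, unit = "min", kind = kind,
            class = c("measurement_series", "data.frame"))
}
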