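# Orchestration: simulate -> differential expression -> stability ->
# fluctuation -> phenotype -> report, all driven by one configuration and
# one seed, with a run manifest recording file digests for reproducibility
# checks. Stages are pure functions of (inputs, config); this layer owns
# all I/O.

#' Run the full synthetic-data pipeline
#'
#' Generates every synthetic dataset from a single seed (sub-seeds are
#' derived deterministically), writes all inputs and stage outputs as TSV
#' under `workdir`, and records a manifest of MD5 digests. Re-running with
#' the same config and seed reproduces byte-identical outputs.
#'
#' @param workdir output directory (created if absent).
#' @param config an [analysis_config()].
#' @param seed master integer seed.
#' @param n_genes number of simulated genes.
#' @param library_size simulated reads per sample.
#' @return invisibly, the manifest data.frame (`key`, `value`).
#' @export
run_pipeline <- function(workdir, config = analysis_config(), seed = 1L,
                         n_genes = 2000, library_size = 5e6) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4L)
  paths <- c()
  say <- function(fmt, ...) message(sprintf(fmt, ...))

  # -- expression + DE -------------------------------------------------
  t0 <- Sys.time()
  es <- expression_sim_spec(n_genes = n_genes, library_size = library_size,
                            seed = seeds[1L])
  expr <- simulate_expression(es)
  paths["counts"] <- file.path(workdir, "counts.tsv")
  write_count_table(expr$matrix, paths["counts"])
  paths["sheet"] <- file.path(workdir, "samples.tsv")
  write_results(expr$sheet, paths["sheet"])
  paths["expr_truth"] <- file.path(workdir, "expression_truth.tsv")
  write_results(expr$truth, paths["expr_truth"])

  strains <- unique(expr$sheet$strain)
  deg_sets <- list()
  for (i in seq_along(strains)) for (j in seq_along(strains)) {
    if (j <= i) next
    key <- paste0(strains[i], "_vs_", strains[j])
    deg <- de_contrast(expr$matrix, expr$sheet, strains[i], strains[j],
                       config)
    paths[paste0("de_", key)] <-
      file.path(workdir, paste0("de_", gsub("[^A-Za-z0-9_]", "", key), ".tsv"))
    write_results(deg, paths[paste0("de_", key)])
    deg_sets[[key]] <- deg$gene[deg$is_deg]
    say("de %s: %d DEGs (%d up, %d down) [%d genes]", key, sum(deg$is_deg),
        sum(deg$direction == "up"), sum(deg$direction == "down"), nrow(deg))
  }
  ov <- overlap_sets(deg_sets)
  paths["overlaps"] <- file.path(workdir, "deg_overlaps.tsv")
  write_results(ov, paths["overlaps"])
  say("expression stage done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  # -- stability -------------------------------------------------------
  t0 <- Sys.time()
  baseline_counts <- vapply(strains, function(s) {
    ids <- expr$sheet$sample_id[expr$sheet$strain == s]
    round(rowMeans(expr$matrix$counts[, ids, drop = FALSE]))
  }, numeric(n_genes))
  baseline <- count_matrix(baseline_counts)
  ds <- decay_sim_spec(seed = seeds[2L])
  decay <- simulate_decay(ds, baseline)
  paths["chase_counts"] <- file.path(workdir, "chase_counts.tsv")
  write_count_table(decay$matrix, paths["chase_counts"])
  paths["chase_truth"] <- file.path(workdir, "chase_truth.tsv")
  write_results(decay$truth, paths["chase_truth"])
  stab <- run_stability(decay$matrix, decay$sheet, config)
  paths["stability"] <- file.path(workdir, "stability_table.tsv")
  write_results(as.data.frame(stab$table), paths["stability"])
  dist_df <- data.frame(strain = names(stab$distributions),
                        do.call(rbind, stab$distributions),
                        stringsAsFactors = FALSE, row.names = NULL)
  paths["distributions"] <- file.path(workdir, "category_distributions.tsv")
  write_results(dist_df, paths["distributions"])
  pw_df <- data.frame(pair = names(stab$pairwise),
                      do.call(rbind, lapply(stab$pairwise, `[[`, "totals")),
                      stringsAsFactors = FALSE, row.names = NULL,
                      check.names = FALSE)
  paths["pairwise"] <- file.path(workdir, "pairwise_stability.tsv")
  write_results(pw_df, paths["pairwise"])
  say("stability stage done in %.1f s (chi-square %.1f, p %.3g)",
      as.numeric(Sys.time() - t0, units = "secs"),
      stab$chi_square$statistic, stab$chi_square$pvalue)

  # -- fluctuation -----------------------------------------------------
  t0 <- Sys.time()
  flux_rows <- lapply(seq_along(strains), function(i) {
    fs <- fluctuation_sim_spec(seed = seeds[3L] + i - 1L)
    fd <- simulate_fluctuation(fs)
    est <- estimate_from_cultures(fd)
    data.frame(strain = strains[i], m = est$m, mu = est$mu,
               r_median = est$r_median, n_median = est$n_median,
               true_mu = fd$true_mu, stringsAsFactors = FALSE)
  })
  flux_df <- do.call(rbind, flux_rows)
  paths["fluctuation"] <- file.path(workdir, "fluctuation_estimates.tsv")
  write_results(flux_df, paths["fluctuation"])
  say("fluctuation stage done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  # -- phenotype -------------------------------------------------------
  t0 <- Sys.time()
  growth <- simulate_measurements("growth", list(g = 24.7, noise = 0.01),
                                  seed = seeds[4L])
  g_fit <- generation_time(growth)
  west <- simulate_measurements("western_decay", seed = seeds[4L] + 1L)
  hl <- protein_half_life(west)
  ros <- simulate_measurements("ros", seed = seeds[4L] + 2L)
  ros_groups <- split(normalize_ros(ros$value, attr(ros, "truth")$od600),
                      ros$group)
  ros_stat <- anova_tukey(ros_groups)
  dot <- simulate_measurements("dotblot", seed = seeds[4L] + 3L)
  dot_means <- vapply(split(dot$value, dot$group), mean, numeric(1L))
  ra <- relative_quant(dot_means, attr(dot, "truth")$reference)
  mpc <- molecules_per_cell(5700, 30, 5)
  phen_df <- data.frame(
    quantity = c("generation_time_min", "protein_half_life_h",
                 paste0("ros_nf_", names(ros_groups)),
                 paste0("dotblot_ra_", names(ra)),
                 "molecules_per_cell_fold_deficit", "molecules_per_cell"),
    value = c(g_fit$g, hl$t_half_hours,
              vapply(ros_groups, mean, numeric(1L)), ra,
              mpc$fold_deficit, mpc$estimate),
    stringsAsFactors = FALSE)
  paths["phenotype"] <- file.path(workdir, "phenotype_results.tsv")
  write_results(phen_df, paths["phenotype"])
  say("phenotype stage done in %.1f s (ANOVA p %.3g)",
      as.numeric(Sys.time() - t0, units = "secs"), ros_stat$pvalue)

  # -- manifest --------------------------------------------------------
  paths["config"] <- file.path(workdir, "config.txt")
  write_config(config, paths["config"])
  digests <- md5sum(unname(paths))
  manifest <- data.frame(
    key = c("tool_version", "seed", paste0("digest_", names(paths))),
    value = c(as.character(utils::packageVersion("rifchase")),
              as.character(seed), unname(digests)),
    stringsAsFactors = FALSE)
  write_results(manifest[order(manifest$key), ],
                file.path(workdir, "manifest.tsv"))
  invisible(manifest)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Keeps all derived seeds inside the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 2654435761 + 97 * seq_len(n)) %% .Machine$integer.max)
}

#' Summarize a pipeline run directory
#'
#' Reads the stage outputs written by [run_pipeline()] and composes a
#' single human-readable summary (DEG counts per contrast, stability
#' category distributions, pairwise L/=/H totals, mutation-rate estimates,
#' phenotype table), written to `report.txt` in the directory.
#'
#' @param workdir directory of a completed [run_pipeline()] run.
#' @return invisibly, the report lines.
#' @export
report <- function(workdir) {
  need <- file.path(workdir, c("manifest.tsv", "deg_overlaps.tsv",
                               "category_distributions.tsv",
                               "pairwise_stability.tsv",
                               "fluctuation_estimates.tsv",
                               "phenotype_results.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing stage output(s): ", paste(basename(missing), collapse = ", "))
  lines <- c("pipeline run summary", "====================", "")
  de_files <- list.files(workdir, pattern = "^de_.*\\.tsv$", full.names = TRUE)
  for (f in de_files) {
    deg <- read_results(f)
    lines <- c(lines, sprintf("%s: %d DEGs (%d up, %d down) of %d genes",
                              sub("^de_(.*)\\.tsv$", "\\1", basename(f)),
                              sum(deg$is_deg), sum(deg$direction == "up"),
                              sum(deg$direction == "down"), nrow(deg)))
  }
  lines <- c(lines, "", "stability category distributions:")
  dist_df <- read_results(file.path(workdir, "category_distributions.tsv"))
  lines <- c(lines, utils::capture.output(print(dist_df)))
  lines <- c(lines, "", "pairwise stability (L/=/H):")
  lines <- c(lines, utils::capture.output(
    print(read_results(file.path(workdir, "pairwise_stability.tsv")))))
  lines <- c(lines, "", "mutation-rate estimates:")
  lines <- c(lines, utils::capture.output(
    print(read_results(file.path(workdir, "fluctuation_estimates.tsv")))))
  lines <- c(lines, "", "phenotype quantities:")
  lines <- c(lines, utils::capture.output(
    print(read_results(file.path(workdir, "phenotype_results.tsv")))))
  writeLines(lines, file.path(workdir, "report.txt"))
  invisible(lines)
}
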