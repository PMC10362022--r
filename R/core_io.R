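# Data model and tabular I/O shared by all pipeline stages.
#
# One tabular dialect everywhere: tab-separated plain text with a header
# row, decimal point, no quoting. All downstream stages consume the typed
# containers built here; no stage reads files directly.

#' Construct a count matrix container
#'
#' Bundles an integer gene-by-sample read-count matrix with per-sample
#' library sizes. Library sizes default to column sums; explicitly supplied
#' values may exceed column sums (e.g. total rather than assigned reads, or
#' a simulation's common depth anchor) but may never fall below them.
#'
#' @param counts numeric matrix, genes in rows, samples in columns; must
#'   carry unique rownames (gene ids) and colnames (sample ids); values
#'   non-negative and, unless `integer = FALSE`, whole numbers.
#' @param library_sizes optional named numeric vector, one positive value
#'   per sample, each at least the corresponding column sum.
#' @param integer require integral counts (the default, matching real read
#'   counts). Noiseless simulations may carry real-valued expectations.
#' @return an object of class `count_matrix`: a list with elements `counts`,
#'   `library_sizes` and logical `all_zero` (TRUE when every count is 0).
#' @export
count_matrix <- function(counts, library_sizes = NULL, integer = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         rownames(counts)[anyDuplicated(rownames(counts))])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[anyDuplicated(colnames(counts))])
  if (anyNA(counts)) stop("'counts' contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (integer && any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  csum <- colSums(counts)
  if (is.null(library_sizes)) {
    library_sizes <- csum
    if (any(csum == 0))
      warning("sample(s) with zero total counts: ",
              paste(colnames(counts)[csum == 0], collapse = ", "))
  } else {
    if (is.null(names(library_sizes)))
      names(library_sizes) <- colnames(counts)
    library_sizes <- library_sizes[colnames(counts)]
    if (anyNA(library_sizes) || any(library_sizes <= 0))
      stop("'library_sizes' must provide a positive value for every sample")
    if (any(library_sizes < csum - 1e-8))
      stop("supplied library size below column sum for sample: ",
           paste(colnames(counts)[library_sizes < csum - 1e-8],
                 collapse = ", "))
  }
  structure(list(counts = counts,
                 library_sizes = library_sizes,
                 all_zero = all(counts == 0)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:",
      paste(sprintf("%s=%g", names(x$library_sizes), x$library_sizes),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by samples
#'
#' @param mat a [count_matrix()].
#' @param samples character vector of sample ids to keep.
#' @return a `count_matrix` restricted to `samples`, library sizes carried
#'   over unchanged.
#' @export
subset_samples <- function(mat, samples) {
  stopifnot(inherits(mat, "count_matrix"))
  missing <- setdiff(samples, colnames(mat$counts))
  if (length(missing))
    stop("sample(s) not in count matrix: ", paste(missing, collapse = ", "))
  count_matrix(mat$counts[, samples, drop = FALSE],
               library_sizes = mat$library_sizes[samples],
               integer = FALSE)
}

#' Validate and construct a sample sheet
#'
#' A sample sheet maps sample ids to strain, chase timepoint and replicate.
#' Timepoints are labels of the form `T<minutes>` (`T0` immediately before
#' rifampicin addition, `T4` four minutes after).
#'
#' @param df data.frame with columns `sample_id`, `strain`, `timepoint`,
#'   `replicate`.
#' @return the validated data.frame, class `c("sample_sheet","data.frame")`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "strain", "timepoint", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$strain <- as.character(df$strain)
  df$timepoint <- as.character(df$timepoint)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[anyDuplicated(df$sample_id)])
  if (any(!grepl("^T[0-9]+$", df$timepoint)))
    stop("timepoint labels must look like 'T0', 'T4', ...")
  if (any(df$replicate < 1L)) stop("replicate numbers must be >= 1")
  key <- paste(df$strain, df$timepoint, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (strain, timepoint, replicate) triple: ",
         key[anyDuplicated(key)])
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Minutes after rifampicin addition encoded in a timepoint label
#' @param timepoint character vector of labels such as "T0", "T4".
#' @return integer vector of minutes.
#' @export
timepoint_minutes <- function(timepoint) {
  as.integer(sub("^T", "", timepoint))
}

#' Read a sample sheet from a TSV file
#' @param path file path to a tab-separated sheet with header
#'   `sample_id, strain, timepoint, replicate`.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE))
}

#' Read a gene-by-sample count table
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row names the samples. When a sample sheet is given, the returned
#' matrix contains exactly the sheet's samples, in sheet order.
#'
#' @param path file path.
#' @param sheet optional [sample_sheet()]; its sample set must be present in
#'   the table.
#' @return a [count_matrix()] with library sizes equal to column sums.
#' @export
read_count_table <- function(path, sheet = NULL) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("count table needs a gene id column plus samples")
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in count table: ",
         gene_ids[anyDuplicated(gene_ids)])
  samples <- names(raw)[-1L]
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf(
        "invalid count '%s' at gene '%s', sample '%s' (must be a non-negative integer)",
        raw[[j + 1L]][bad[1L]], gene_ids[bad[1L]], samples[j]))
    mat[, j] <- v
  }
  if (!is.null(sheet)) {
    stopifnot(inherits(sheet, "sample_sheet"))
    missing <- setdiff(sheet$sample_id, samples)
    if (length(missing))
      stop("sample(s) in sheet but not in count table: ",
           paste(missing, collapse = ", "))
    mat <- mat[, sheet$sample_id, drop = FALSE]
  }
  count_matrix(mat)
}

#' Write a count matrix as TSV
#' @param mat a [count_matrix()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_count_table <- function(mat, path) {
  stopifnot(inherits(mat, "count_matrix"))
  df <- data.frame(gene = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_results(df, path)
}

#' Write a results table as deterministic TSV
#'
#' Rows are ordered ascending by the first column (the gene or record id),
#' so that repeated runs produce byte-identical files. Values round-trip
#' through [read_results()] exactly for integers and to better than 1e-9
#' relative for reals.
#'
#' @param table non-empty data.frame.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a non-empty data.frame")
  ord <- order(as.character(table[[1L]]), method = "radix")
  table <- table[ord, , drop = FALSE]
  num <- vapply(table, is.numeric, logical(1L))
  for (j in which(num)) {
    table[[j]] <- vapply(table[[j]], function(v) {
      if (is.na(v)) return("NA")
      if (is.finite(v) && v == round(v) && abs(v) < 2^52)
        sprintf("%.0f", v)
      else
        format(v, digits = 17, scientific = NA)
    }, character(1L))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path file path.
#' @return a data.frame.
#' @export
read_results <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Analysis configuration
#'
#' Every threshold of the analysis appears here with the value used in the
#' underlying study as its default: DEG selection at FDR < 0.01 and
#' |log2 fold change| >= 1; stability categories cut at 25/50/75 percent
#' remaining; the chase sampled 4 minutes after rifampicin addition.
#'
#' @param fdr_threshold FDR cutoff for DEG selection, in (0, 1).
#' @param lfc_threshold minimum |log2 fold change| for DEG selection, >= 0.
#' @param category_bounds strictly increasing percent-remaining cut points
#'   within (0, 100) delimiting the four stability categories.
#' @param decay_time minutes of rifampicin chase between T0 and T4.
#' @param t0_cpm_floor minimum mean T0 CPM for a gene to be assessable in
#'   the stability analysis.
#' @param pct_cap cap applied to percent remaining (`Inf` keeps raw values).
#' @param rng_seed optional integer seed recorded for provenance.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(fdr_threshold = 0.01,
                            lfc_threshold = 1,
                            category_bounds = c(25, 50, 75),
                            decay_time = 4,
                            t0_cpm_floor = 1,
                            pct_cap = 100,
                            rng_seed = NULL) {
  if (!(fdr_threshold > 0 && fdr_threshold < 1))
    stop("'fdr_threshold' must lie in (0, 1)")
  if (lfc_threshold < 0) stop("'lfc_threshold' must be >= 0")
  if (length(category_bounds) < 1L ||
      any(diff(category_bounds) <= 0) ||
      any(category_bounds <= 0) || any(category_bounds >= 100))
    stop("'category_bounds' must be strictly increasing within (0, 100)")
  if (decay_time <= 0) stop("'decay_time' must be positive minutes")
  structure(list(fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold,
                 category_bounds = category_bounds,
                 decay_time = decay_time,
                 t0_cpm_floor = t0_cpm_floor,
                 pct_cap = pct_cap,
                 rng_seed = rng_seed),
            class = "analysis_config")
}

#' Write an analysis configuration as a flat key: value file
#' @param config an [analysis_config()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  keep <- !vapply(config, is.null, logical(1L))
  lines <- vapply(names(config)[keep], function(k) {
    paste0(k, ": ", paste(format(config[[k]], digits = 17), collapse = ", "))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an analysis configuration from a flat key: value file
#'
#' The file format is one `key: value` pair per line; comma-separated
#' values become numeric vectors. Unknown keys raise an error.
#'
#' @param path file path.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line: ",
                                   lines[which(lengths(kv) != 3L)[1L]])
  vals <- lapply(kv, function(m) {
    parts <- trimws(strsplit(m[3L], ",")[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else num
  })
  names(vals) <- vapply(kv, `[`, character(1L), 2L)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}
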