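# Readers/writers for the formats the tool touches, and the two validated
# input containers: a peak-by-cell count matrix and the cell/sample/phenotype
# design. Matrix Market (10x-style triplet + sidecar files) is the canonical
# interchange; a dense-TSV loader exists for tiny fixtures.

#' Construct a validated peak-by-cell count matrix
#'
#' @param counts sparse (or dense) non-negative integer matrix, peaks in rows,
#'   cells in columns.
#' @param peaks `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open, as in BED), one row per peak. Coordinates are carried as
#'   labels; the core algorithm treats peaks as opaque features.
#' @param barcodes character vector of unique cell barcodes, one per column.
#' @return An object of class `reda_counts` with elements `counts`, `peaks`,
#'   `barcodes`.
#' @export
count_matrix <- function(counts, peaks, barcodes) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0))
    stop("count matrix has negative entries", call. = FALSE)
  barcodes <- as.character(barcodes)
  if (anyDuplicated(barcodes))
    stop("duplicate cell barcodes: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "),
         call. = FALSE)
  if (ncol(counts) != length(barcodes))
    stop(sprintf("count matrix has %d columns but %d barcodes",
                 ncol(counts), length(barcodes)), call. = FALSE)
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) != nrow(counts))
    stop(sprintf("count matrix has %d rows but %d peaks",
                 nrow(counts), nrow(peaks)), call. = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    stop("peaks need columns chrom, start, end", call. = FALSE)
  rownames(counts) <- peak_ids(peaks)
  colnames(counts) <- barcodes
  structure(list(counts = counts, peaks = peaks, barcodes = barcodes),
            class = "reda_counts")
}

peak_ids <- function(peaks) sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)

#' @export
print.reda_counts <- function(x, ...) {
  cat(sprintf("reda_counts: %d peaks x %d cells, %d nonzeros (%.2f%% per-cell detection)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              100 * mean(Matrix::colMeans(x$counts > 0))))
  invisible(x)
}

#' Read a 10x-style sparse count matrix
#'
#' Reads a Matrix Market coordinate file with its barcode and peak sidecar
#' files. Dimensions declared in the `.mtx` header must match the line counts
#' of the sidecars; mismatches are reported naming the offending file.
#'
#' @param mtx_path Matrix Market coordinate file (peaks x cells).
#' @param barcodes_path one barcode per line, no header.
#' @param peaks_path BED/TSV with at least 3 columns (chrom, start, end;
#'   0-based half-open), no header.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(mtx_path, barcodes_path, peaks_path) {
  m <- Matrix::readMM(mtx_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(barcodes) != ncol(m))
    stop(sprintf("format error: %s declares %d cells but %s has %d barcodes",
                 mtx_path, ncol(m), barcodes_path, length(barcodes)),
         call. = FALSE)
  pk <- utils::read.table(peaks_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(pk) < 3)
    stop(sprintf("format error: %s has fewer than 3 columns", peaks_path),
         call. = FALSE)
  if (nrow(pk) != nrow(m))
    stop(sprintf("format error: %s declares %d peaks but %s has %d rows",
                 mtx_path, nrow(m), peaks_path, nrow(pk)), call. = FALSE)
  peaks <- data.frame(chrom = pk[[1]], start = pk[[2]], end = pk[[3]],
                      stringsAsFactors = FALSE)
  count_matrix(m, peaks, barcodes)
}

#' Read a dense TSV count matrix (fixture convenience)
#'
#' Rows are peaks, columns are cells; first column holds `chrom:start-end`
#' peak labels and the header holds barcodes.
#'
#' @param path TSV file.
#' @return A [count_matrix()] object.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  coord <- strsplit(rownames(x), "[:-]")
  peaks <- data.frame(chrom = vapply(coord, `[`, "", 1L),
                      start = as.integer(vapply(coord, `[`, "", 2L)),
                      end = as.integer(vapply(coord, `[`, "", 3L)),
                      stringsAsFactors = FALSE)
  count_matrix(Matrix::Matrix(as.matrix(x), sparse = TRUE), peaks, colnames(x))
}

#' Write a count matrix as Matrix Market plus sidecars
#'
#' Inverse of [read_count_matrix()]: writes `matrix.mtx`, `barcodes.tsv` and
#' `peaks.bed` into `dir`.
#'
#' @param counts a [count_matrix()] object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_count_matrix <- function(counts, dir) {
  stopifnot(inherits(counts, "reda_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "peaks.bed"))
  Matrix::writeMM(counts$counts, paths[1])
  writeLines(counts$barcodes, paths[2])
  utils::write.table(counts$peaks[, c("chrom", "start", "end")], paths[3],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}

#' Construct a validated sample table
#'
#' Binds each cell to a sample and each sample to a numeric phenotype, with
#' optional numeric covariates and a batch label. Two-condition designs are
#' coded 0/1; continuous phenotypes pass through unchanged (the association
#' test is correlation-based and agnostic). A table with as few as 2 samples
#' is accepted here — neighborhood abundance can be computed — but the
#' association test itself rejects designs with fewer than 4 samples.
#'
#' @param cells `data.frame` with columns `barcode`, `sample`.
#' @param samples `data.frame` with columns `sample`, `phenotype`, optionally
#'   `batch`, and any further numeric columns treated as sample covariates.
#' @return An object of class `reda_samples` with elements `cells`, `samples`,
#'   `covariate_names`.
#' @export
sample_table <- function(cells, samples) {
  cells <- as.data.frame(cells)
  samples <- as.data.frame(samples)
  stopifnot(all(c("barcode", "sample") %in% names(cells)),
            all(c("sample", "phenotype") %in% names(samples)))
  cells$barcode <- as.character(cells$barcode)
  cells$sample <- as.character(cells$sample)
  samples$sample <- as.character(samples$sample)
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in sample table", call. = FALSE)
  unknown <- setdiff(cells$sample, samples$sample)
  if (length(unknown))
    stop("cells reference unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.numeric(samples$phenotype))
    stop("phenotype must be numeric (code two conditions as 0/1)",
         call. = FALSE)
  if (anyNA(samples$phenotype)) stop("phenotype has missing values", call. = FALSE)
  samples$phenotype <- as.numeric(samples$phenotype)
  if (length(unique(samples$phenotype)) < 2)
    stop("phenotype has no variation", call. = FALSE)
  covariate_names <- setdiff(names(samples), c("sample", "phenotype", "batch"))
  for (cv in covariate_names)
    if (!is.numeric(samples[[cv]]))
      stop("covariate '", cv, "' is not numeric", call. = FALSE)
  structure(list(cells = cells, samples = samples,
                 covariate_names = covariate_names),
            class = "reda_samples")
}

#' @export
print.reda_samples <- function(x, ...) {
  tab <- table(x$cells$sample)
  cat(sprintf("reda_samples: %d cells over %d samples (cells/sample: %d-%d)\n",
              nrow(x$cells), nrow(x$samples), min(tab), max(tab)))
  if (length(x$covariate_names))
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read the cell/sample/phenotype design from two CSV files
#'
#' @param cells_csv CSV with header columns `barcode,sample`.
#' @param samples_csv CSV with header columns `sample,phenotype` and any
#'   optional `batch` / numeric covariate columns.
#' @return A [sample_table()] object.
#' @export
read_sample_table <- function(cells_csv, samples_csv) {
  cells <- utils::read.csv(cells_csv, stringsAsFactors = FALSE)
  samples <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  sample_table(cells, samples)
}

# Order sample ids as first seen in the cell table; used everywhere a
# sample-indexed matrix is built so row order is reproducible.
sample_ids_in_order <- function(samples) {
  unique(samples$cells$sample)
}

#' Read an externally computed cell embedding
#'
#' Headerless TSV, one row per cell in barcode order, numeric columns. Used
#' to bypass TF-IDF/LSI, e.g. to supply a batch-corrected embedding.
#'
#' @param path TSV file.
#' @param barcodes expected barcodes (row order contract).
#' @return A `reda_embedding` object (see [lsi()]).
#' @export
read_embedding <- function(path, barcodes) {
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (nrow(x) != length(barcodes))
    stop(sprintf("embedding %s has %d rows but %d barcodes expected",
                 path, nrow(x), length(barcodes)), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("embedding contains NA/Inf", call. = FALSE)
  rownames(x) <- barcodes
  structure(list(coords = x, dims_used = seq_len(ncol(x)),
                 variance = rep(NA_real_, ncol(x))),
            class = "reda_embedding")
}

#' Write association results to a directory
#'
#' Writes `cells.tsv` (barcode, coefficient, passes_fdr_05), `summary.json`
#' (global p-value, selected NAM-PC rank k, selected walk step s, restart
#' probability, permutation count, seed, FDR threshold) and `fdr_table.tsv`.
#' The files round-trip losslessly through [read_results()].
#'
#' @param result a `reda_result` from [association_test()] or [reda_run()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the file paths.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "reda_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- data.frame(barcode = names(result$coefficients),
                      coefficient = unname(result$coefficients),
                      passes_fdr_05 = names(result$coefficients) %in%
                        result$passing_cells)
  f_cells <- file.path(out_dir, "cells.tsv")
  f_sum <- file.path(out_dir, "summary.json")
  f_fdr <- file.path(out_dir, "fdr_table.tsv")
  utils::write.table(format(cells, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     f_cells, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(global_p = result$global_p, k_selected = result$k_selected,
                  s_selected = result$s_selected, alpha = result$alpha,
                  n_permutations = result$n_permutations, seed = result$seed,
                  fdr = result$fdr, t_star = result$t_star,
                  n_passing = length(result$passing_cells),
                  config = result$config)
  jsonlite::write_json(summary, f_sum, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  utils::write.table(format(result$fdr_table, digits = 17,
                            scientific = FALSE, trim = TRUE),
                     f_fdr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f_cells, f_sum, f_fdr))
}

#' Re-read results written by [write_results()]
#'
#' @param out_dir directory previously passed to [write_results()].
#' @return A list with `cells` (data.frame), `summary` (list), `fdr_table`.
#' @export
read_results <- function(out_dir) {
  cells <- utils::read.table(file.path(out_dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  summary <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                                 simplifyVector = TRUE)
  fdr_table <- utils::read.table(file.path(out_dir, "fdr_table.tsv"),
                                 sep = "\t", header = TRUE)
  list(cells = cells, summary = summary, fdr_table = fdr_table)
}
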