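# TF-IDF normalization and LSI (truncated SVD) of the peak-by-cell matrix.
# This is the standard scATAC-seq reduction: term-frequency scaling per cell,
# inverse-document-frequency weighting per peak, log transform, then a
# truncated SVD whose first component (which tracks sequencing depth) is
# dropped by default.

#' TF-IDF transform of a peak-by-cell count matrix
#'
#' Computes `log(1 + TF * IDF * scale_factor)` per entry, where
#' `TF = count / cell total` and `IDF = n_cells / n_cells detecting the peak`.
#' Counts are binarized first by default, reflecting the near-binary nature of
#' scATAC-seq. Zero entries stay zero, so sparsity is preserved. Peaks
#' detected in no cell have undefined IDF and are dropped with a warning.
#'
#' @param counts a [count_matrix()] object or a sparse peaks x cells matrix.
#' @param scale_factor scale inside the log; 1e4 by default.
#' @param binarize logical; replace counts by detection indicators first.
#' @return A sparse peaks x cells matrix of TF-IDF values.
#' @export
tfidf <- function(counts, scale_factor = 1e4, binarize = TRUE) {
  m <- if (inherits(counts, "reda_counts")) counts$counts else counts
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (binarize) m@x <- as.numeric(m@x > 0)
  cell_tot <- Matrix::colSums(m)
  if (any(cell_tot == 0))
    stop(sprintf("%d cell(s) have zero total count; remove them first",
                 sum(cell_tot == 0)), call. = FALSE)
  detected <- Matrix::rowSums(m > 0)
  if (any(detected == 0)) {
    warning(sprintf("dropping %d peak(s) detected in no cell",
                    sum(detected == 0)), call. = FALSE)
    m <- m[detected > 0, , drop = FALSE]
    detected <- detected[detected > 0]
  }
  tf <- m %*% Matrix::Diagonal(x = 1 / cell_tot)
  out <- Matrix::Diagonal(x = ncol(m) / detected) %*% tf
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x * scale_factor)
  dimnames(out) <- dimnames(m)
  out
}

#' Latent semantic indexing of a TF-IDF matrix
#'
#' Truncated SVD of the peaks x cells TF-IDF matrix; cell coordinates are the
#' right singular vectors scaled by the singular values. The first component
#' correlates with per-cell sequencing depth and is dropped by default, so a
#' 30-component run retains dimensions 2-30.
#'
#' @param x sparse TF-IDF matrix from [tfidf()] (peaks x cells).
#' @param n_components number of SVD components to compute (default 30).
#' @param drop_first drop component 1 from the embedding (default TRUE).
#' @param seed integer seed for the randomized SVD solver; fixed seed gives a
#'   deterministic embedding.
#' @return `reda_embedding`: list with `coords` (cells x d), `dims_used`
#'   (retained component indices), `variance` (all singular values).
#' @export
lsi <- function(x, n_components = 30, drop_first = TRUE, seed = 1) {
  if (inherits(x, "reda_counts"))
    stop("pass the TF-IDF matrix (see tfidf()), not raw counts", call. = FALSE)
  if (n_components >= min(dim(x)))
    stop(sprintf(paste0("n_components = %d must be smaller than the matrix ",
                        "rank bound min(%d, %d); choose a smaller value"),
                 n_components, nrow(x), ncol(x)), call. = FALSE)
  if (n_components < 2 || (drop_first && n_components < 3))
    stop("need at least 2 retained components", call. = FALSE)
  # irlba is only worthwhile (and only converges reliably) when the requested
  # rank is well below the matrix size; fall back to exact svd on small input
  small <- min(dim(x)) < 100 || n_components > min(dim(x)) / 3
  sv <- if (small) {
    s <- svd(as.matrix(x), nu = 0, nv = n_components)
    list(d = s$d[seq_len(n_components)], v = s$v)
  } else {
    with_seed(seed, irlba::irlba(x, nv = n_components, nu = n_components))
  }
  coords <- sv$v %*% diag(sv$d[seq_len(n_components)], n_components)
  dims_used <- if (drop_first) 2:n_components else 1:n_components
  coords <- coords[, dims_used, drop = FALSE]
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("embedding contains NA/Inf", call. = FALSE)
  rownames(coords) <- colnames(x)
  structure(list(coords = coords, dims_used = dims_used,
                 variance = sv$d[seq_len(n_components)]),
            class = "reda_embedding")
}

#' @export
print.reda_embedding <- function(x, ...) {
  cat(sprintf("reda_embedding: %d cells x %d dims (components %s)\n",
              nrow(x$coords), ncol(x$coords),
              paste(range(x$dims_used), collapse = "-")))
  invisible(x)
}
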