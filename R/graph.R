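# Shared-nearest-neighbor graph over cells. Edge weight between two cells is
# the Jaccard overlap of their k-nearest-neighbor sets (each set including
# the cell itself), pruned below a threshold. Exact kNN with a deterministic
# tie rule keeps runs reproducible.

#' Exact k-nearest neighbors in the embedding
#'
#' Euclidean distances in the LSI (or user-supplied) embedding, self
#' excluded. Ties — including exactly duplicated coordinates — are broken by
#' lower cell index, so results are deterministic.
#'
#' @param embedding a `reda_embedding` or a cells x d numeric matrix.
#' @param k number of neighbors (must be `<` number of cells).
#' @return Integer matrix, cells x k, of neighbor indices.
#' @export
knn_cells <- function(embedding, k = 20) {
  coords <- if (inherits(embedding, "reda_embedding")) embedding$coords
            else as.matrix(embedding)
  m <- nrow(coords)
  if (k >= m) stop(sprintf("k = %d must be < number of cells (%d)", k, m),
                   call. = FALSE)
  rn <- rowSums(coords^2)
  nn <- matrix(0L, m, k)
  chunk <- 256L
  for (lo in seq(1L, m, by = chunk)) {
    idx <- lo:min(lo + chunk - 1L, m)
    d2 <- outer(rn[idx], rn, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE],
                                                   coords)
    for (r in seq_along(idx)) {
      # radix order is stable: equal distances resolve to the lower index
      o <- order(d2[r, ], method = "radix")
      o <- o[o != idx[r]]
      nn[idx[r], ] <- o[seq_len(k)]
    }
  }
  rownames(nn) <- rownames(coords)
  nn
}

#' Shared-nearest-neighbor graph from kNN lists
#'
#' Edge weight between cells i and j is the Jaccard overlap of their
#' neighborhoods (the k neighbors plus the cell itself, so sets of size
#' k+1). Weights below `prune` are removed. Should pruning isolate a cell,
#' its strongest pre-prune edge is restored (with a warning) so every cell
#' keeps degree > 0, which the random walk requires.
#'
#' @param neighbors integer cells x k matrix from [knn_cells()].
#' @param prune Jaccard cutoff; Seurat/Signac-conventional 1/15 by default.
#' @return `reda_graph`: list with sparse symmetric `adjacency` (zero
#'   diagonal, weights in `[0,1]`), `k`, `prune`.
#' @export
snn_from_knn <- function(neighbors, prune = 1 / 15) {
  neighbors <- as.matrix(neighbors)
  m <- nrow(neighbors)
  k <- ncol(neighbors)
  sets <- k + 1  # each neighborhood includes the anchor cell
  b <- Matrix::sparseMatrix(i = rep(seq_len(m), sets),
                            j = c(as.integer(neighbors), seq_len(m)),
                            x = 1, dims = c(m, m))
  inter <- Matrix::tcrossprod(b)              # |Ni ∩ Nj|, symmetric
  jac <- methods::as(methods::as(inter, "generalMatrix"), "CsparseMatrix")
  jac@x <- jac@x / (2 * sets - jac@x)         # |∩| / |∪|
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  adj <- jac
  adj@x[adj@x < prune] <- 0
  adj <- Matrix::drop0(adj)
  deg <- Matrix::rowSums(adj)
  if (any(deg == 0)) {
    iso <- which(deg == 0)
    warning(sprintf("%d cell(s) isolated after pruning; restoring strongest edge",
                    length(iso)), call. = FALSE)
    for (i in iso) {
      wrow <- jac[i, ]
      j <- which.max(wrow)
      adj[i, j] <- adj[j, i] <- wrow[j]
    }
    adj <- Matrix::drop0(adj)
  }
  adj <- methods::as(methods::as(Matrix::forceSymmetric(adj, uplo = "U"),
                                 "generalMatrix"), "CsparseMatrix")
  dimnames(adj) <- list(rownames(neighbors), rownames(neighbors))
  structure(list(adjacency = adj, k = k, prune = prune),
            class = "reda_graph")
}

#' Build the SNN graph straight from an embedding
#'
#' Convenience wrapper: [knn_cells()] then [snn_from_knn()].
#'
#' @inheritParams knn_cells
#' @inheritParams snn_from_knn
#' @return A `reda_graph`.
#' @export
snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  snn_from_knn(knn_cells(embedding, k = k), prune = prune)
}

#' @export
print.reda_graph <- function(x, ...) {
  cat(sprintf("reda_graph: %d cells, %d edges (k=%d, prune=%.4g)\n",
              nrow(x$adjacency), length(x$adjacency@x) / 2, x$k, x$prune))
  invisible(x)
}

#' Export / import the SNN graph as Matrix Market
#'
#' For debugging and for bypassing graph construction in the pipeline.
#'
#' @param graph a `reda_graph`.
#' @param path `.mtx` file path.
#' @return `write_graph` invisibly returns `path`; `read_graph` returns a
#'   `reda_graph`.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "reda_graph"))
  Matrix::writeMM(methods::as(graph$adjacency, "symmetricMatrix"), path)
  invisible(path)
}

#' @rdname write_graph
#' @param barcodes optional barcodes to attach as dimnames.
#' @export
read_graph <- function(path, barcodes = NULL) {
  a <- methods::as(methods::as(methods::as(Matrix::readMM(path), "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  if (!isTRUE(all.equal(a, Matrix::t(a), tolerance = 0)))
    stop("imported graph is not symmetric", call. = FALSE)
  if (!is.null(barcodes)) dimnames(a) <- list(barcodes, barcodes)
  structure(list(adjacency = a, k = NA_integer_, prune = NA_real_),
            class = "reda_graph")
}
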