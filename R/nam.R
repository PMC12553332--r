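# Neighborhood abundance matrix (NAM) via random walk with restart (RWR).
#
# From the SNN adjacency A, the walk matrix is W = D^-1 A. A walker started
# at cell i moves along W and returns to i with restart probability alpha at
# each step:
#
#     r^s = (1 - alpha) W r^{s-1} + alpha I,      r^0 = I
#
# so r^s[i, i'] is the probability mass started at i that sits on i' after s
# steps — a soft neighborhood for every cell. Summing rows over the cells of
# each sample gives R[n, i], the mass sample n places on cell i's
# neighborhood; row-normalizing R gives the NAM Q. The walk length s is the
# smallest s at which neighborhoods stop being dominated by a few samples,
# measured by the kurtosis of each NAM column across samples.

#' Row-stochastic walk matrix of an SNN graph
#'
#' `W = D^-1 A` with `D` the diagonal matrix of edge-weight sums; row i of
#' `W` is cell i's adjacency row divided by its degree, so every row sums
#' to 1.
#'
#' @param graph a `reda_graph` (all degrees must be positive).
#' @return Sparse row-stochastic matrix `W`.
#' @export
walk_matrix <- function(graph) {
  a <- if (inherits(graph, "reda_graph")) graph$adjacency else graph
  deg <- Matrix::rowSums(a)
  if (any(deg <= 0))
    stop(sprintf("%d cell(s) have zero degree; the walk matrix is undefined",
                 sum(deg <= 0)), call. = FALSE)
  w <- Matrix::Diagonal(x = 1 / deg) %*% a
  w <- methods::as(w, "CsparseMatrix")
  dimnames(w) <- dimnames(a)
  w
}

#' Initialize a restart-walk state
#'
#' The state holds the full M x M matrix `r` (`r[i, i']` = mass started at
#' cell i sitting on cell i' after `s` steps), the step count `s`, and the
#' restart probability `alpha`. At `s = 0`, `r` is the identity.
#'
#' @param n_cells number of cells M.
#' @param alpha restart probability in `[0, 1]`.
#' @param barcodes optional dimnames.
#' @return A `reda_walk` state.
#' @export
rwr_init <- function(n_cells, alpha = 0.3, barcodes = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  r <- diag(n_cells)
  if (!is.null(barcodes)) dimnames(r) <- list(barcodes, barcodes)
  structure(list(r = r, s = 0L, alpha = alpha), class = "reda_walk")
}

#' One step of the random walk with restart
#'
#' Applies `r <- (1 - alpha) W r + alpha I` and increments `s`. Rows of `r`
#' remain probability distributions (they sum to 1), and for `s >= 1` every
#' diagonal entry is at least `alpha` — the walker sits on its start cell
#' with at least the restart mass.
#'
#' @param state a `reda_walk` from [rwr_init()].
#' @param W row-stochastic walk matrix from [walk_matrix()].
#' @return The advanced `reda_walk` state.
#' @export
rwr_step <- function(state, W) {
  stopifnot(inherits(state, "reda_walk"))
  alpha <- state$alpha
  r <- (1 - alpha) * as.matrix(W %*% state$r)
  diag(r) <- diag(r) + alpha
  state$r <- r
  state$s <- state$s + 1L
  state
}

#' Run the restart walk for a fixed number of steps
#'
#' @inheritParams rwr_step
#' @param s number of steps.
#' @param alpha restart probability.
#' @return A `reda_walk` at step `s`.
#' @export
rwr_walk <- function(W, s, alpha = 0.3) {
  state <- rwr_init(nrow(W), alpha = alpha, barcodes = rownames(W))
  for (i in seq_len(s)) state <- rwr_step(state, W)
  state
}

# Cells x samples indicator matrix, sample order taken from the design
# table. Errors if a sample has no cells or a cell is missing from the walk.
sample_indicator <- function(samples, barcodes) {
  stopifnot(inherits(samples, "reda_samples"))
  ids <- samples$samples$sample
  pos <- match(samples$cells$barcode, barcodes)
  if (anyNA(pos))
    stop("cells in the sample table are missing from the graph/walk: ",
         paste(utils::head(samples$cells$barcode[is.na(pos)], 3), collapse = ", "),
         call. = FALSE)
  counts <- table(factor(samples$cells$sample, levels = ids))
  if (any(counts == 0))
    stop("sample(s) with zero cells: ",
         paste(ids[counts == 0], collapse = ", "), call. = FALSE)
  s <- matrix(0, length(barcodes), length(ids),
              dimnames = list(barcodes, ids))
  s[cbind(pos, match(samples$cells$sample, ids))] <- 1
  s
}

new_nam <- function(R, sample_ids, barcodes, s, alpha, trace = NULL) {
  rs <- rowSums(R)
  Q <- R / rs
  stopifnot(all(abs(rowSums(Q) - 1) < 1e-10))
  dimnames(Q) <- dimnames(R) <- list(sample_ids, barcodes)
  structure(list(Q = Q, R_raw = R, sample_ids = sample_ids,
                 cell_barcodes = barcodes, s_selected = s, alpha = alpha,
                 kurtosis_trace = trace),
            class = "reda_nam")
}

#' Neighborhood abundance matrix from a walk state
#'
#' `R[n, i]` sums `r[i', i]` over the start cells i' belonging to sample n:
#' how much probability mass sample n's cells place on cell i's
#' neighborhood. `Q` is `R` with each row normalized to sum 1. Because every
#' row of `r` is a probability distribution, the row-n normalizer equals the
#' number of cells in sample n — asserted.
#'
#' @param state a `reda_walk` at the selected step.
#' @param samples a [sample_table()].
#' @param barcodes cell barcodes in walk row order; defaults to the walk's
#'   dimnames.
#' @return A `reda_nam`: `Q` (samples x cells, rows sum to 1), `R_raw`,
#'   `sample_ids`, `cell_barcodes`, `s_selected`, `alpha`.
#' @export
nam_from_walk <- function(state, samples, barcodes = rownames(state$r)) {
  stopifnot(inherits(state, "reda_walk"))
  if (is.null(barcodes)) barcodes <- as.character(seq_len(nrow(state$r)))
  s_ind <- sample_indicator(samples, barcodes)
  R <- crossprod(s_ind, state$r)                 # N x M
  cell_counts <- colSums(s_ind)
  if (!all(abs(rowSums(R) - cell_counts) < 1e-8))
    stop("NAM conservation violated: row sums of R do not match sample cell counts",
         call. = FALSE)
  new_nam(R, colnames(s_ind), barcodes, state$s, state$alpha)
}

#' Run the restart walk with automatic step selection
#'
#' Iterates the walk and, after each step, builds the NAM and scores how
#' strongly single samples dominate neighborhoods via the kurtosis of each
#' NAM column across samples. Walking stops at the first step s where the
#' median column kurtosis either decreased by less than `kurt_drop` (a
#' plateau; needs s >= 2) or is below `kurt_low` — the smallest
#' neighborhoods that are already sample-balanced. If neither fires by
#' `s_max`, the walk stops there with a warning.
#'
#' Internally the recursion is run on the N x M matrix `R` directly
#' (`R_s = (1 - alpha) R_{s-1} W + alpha S^T`, `S` the cell-sample
#' indicator), which is algebraically identical to summing the full M x M
#' walk — both equal `S^T p(W)` for the same matrix polynomial — at
#' O(N * edges) per step, so the M x M matrix is never materialized unless
#' `keep_walk = TRUE`.
#'
#' @inheritParams nam_from_walk
#' @param W walk matrix from [walk_matrix()].
#' @param alpha restart probability; 0.3 by default (0 disables the
#'   restart, as in the no-restart ablation).
#' @param s_max maximum walk length (default 50).
#' @param kurt_drop plateau threshold on the kurtosis decrease (default 3).
#' @param kurt_low absolute kurtosis threshold (default 8).
#' @param kurt_type kurtosis convention, `"fisher"` (excess; default) or
#'   `"pearson"`; the thresholds apply to whichever is chosen.
#' @param keep_walk also materialize the full M x M walk state at the
#'   selected step (memory O(M^2)).
#' @param s_fixed force the walk length to this value, bypassing the
#'   kurtosis rule (used by the fixed-step ablation); `NULL` (default)
#'   selects automatically.
#' @param verbose log the selected step.
#' @return List with `nam` (a `reda_nam` carrying the full
#'   `kurtosis_trace`) and `state` (a `reda_walk`; its `r` is `NULL` unless
#'   `keep_walk = TRUE`).
#' @export
select_steps <- function(W, samples, barcodes = rownames(W), alpha = 0.3,
                         s_max = 50, kurt_drop = 3, kurt_low = 8,
                         kurt_type = c("fisher", "pearson"),
                         keep_walk = FALSE, s_fixed = NULL, verbose = FALSE) {
  kurt_type <- match.arg(kurt_type)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  if (s_max < 1) stop("s_max must be >= 1", call. = FALSE)
  s_max <- as.integer(s_max)
  if (is.null(barcodes)) barcodes <- as.character(seq_len(nrow(W)))
  s_ind <- sample_indicator(samples, barcodes)
  if (ncol(s_ind) < 4)
    stop("need at least 4 samples: kurtosis across fewer values is degenerate",
         call. = FALSE)
  cell_counts <- colSums(s_ind)
  St <- t(s_ind)                                  # R_0 = S^T (walk step 0)
  R <- St
  trace <- data.frame(s = integer(), median_kurtosis = numeric())
  prev_med <- NA_real_
  if (!is.null(s_fixed)) {
    stopifnot(s_fixed >= 1)
    s_max <- as.integer(s_fixed)
  }
  s_sel <- s_max
  for (s in seq_len(s_max)) {
    R <- (1 - alpha) * as.matrix(R %*% W) + alpha * St
    if (!all(abs(rowSums(R) - cell_counts) < 1e-8))
      stop("walk conservation violated at step ", s, call. = FALSE)
    med <- stats::median(col_kurtosis(R / rowSums(R), type = kurt_type),
                         na.rm = TRUE)
    # all columns zero-variance means perfectly balanced neighborhoods
    if (is.na(med)) med <- -Inf
    trace <- rbind(trace, data.frame(s = s, median_kurtosis = med))
    if (is.null(s_fixed) &&
        (med < kurt_low || (s >= 2 && (prev_med - med) < kurt_drop))) {
      s_sel <- as.integer(s)
      break
    }
    prev_med <- med
    if (is.null(s_fixed) && s == s_max)
      warning(sprintf("kurtosis rule did not fire by s_max = %d; using s_max",
                      s_max), call. = FALSE)
  }
  reda_log("nam", fmt_kv(s_selected = s_sel, alpha = alpha,
                         median_kurtosis = signif(trace$median_kurtosis[s_sel], 4)),
           verbose = verbose)
  nam <- new_nam(R, colnames(s_ind), barcodes, s_sel, alpha, trace)
  state <- if (keep_walk) rwr_walk(W, s_sel, alpha = alpha)
           else structure(list(r = NULL, s = s_sel, alpha = alpha),
                          class = "reda_walk")
  list(nam = nam, state = state)
}

#' @export
print.reda_nam <- function(x, ...) {
  cat(sprintf("reda_nam: %d samples x %d cells (s=%d, alpha=%.2f)\n",
              nrow(x$Q), ncol(x$Q), x$s_selected, x$alpha))
  invisible(x)
}

#' Export a NAM as TSV plus a JSON sidecar
#'
#' Writes `nam.tsv` (samples x cells, row names = sample ids) and
#' `nam.json` (alpha, selected step, kurtosis trace) into `dir`.
#'
#' @param nam a `reda_nam`.
#' @param dir output directory.
#' @return Invisibly, the two paths.
#' @export
write_nam <- function(nam, dir) {
  stopifnot(inherits(nam, "reda_nam"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_tsv <- file.path(dir, "nam.tsv")
  f_json <- file.path(dir, "nam.json")
  utils::write.table(format(as.data.frame(nam$Q), digits = 17, trim = TRUE),
                     f_tsv, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(alpha = nam$alpha, s_selected = nam$s_selected,
                            kurtosis_trace = nam$kurtosis_trace),
                       f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f_tsv, f_json))
}
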