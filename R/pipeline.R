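# End-to-end pipeline: preprocess -> graph -> NAM -> association test.

#' Run the full differential-abundance pipeline
#'
#' Chains [tfidf()] + [lsi()] (skipped when `embedding` is supplied),
#' [snn_graph()] (skipped when `graph` is supplied), [select_steps()] and
#' [association_test()]. One seed drives every stochastic stage through
#' stage-named substreams, so e.g. changing `n_perm` does not perturb the
#' embedding.
#'
#' @param counts a [count_matrix()]; may be `NULL` when `embedding` or
#'   `graph` is given.
#' @param samples a [sample_table()] covering the cells.
#' @param embedding optional precomputed `reda_embedding` (e.g. from
#'   [read_embedding()], typically batch-corrected externally); bypasses
#'   TF-IDF/LSI.
#' @param graph optional precomputed `reda_graph`; bypasses graph
#'   construction.
#' @param alpha restart probability (default 0.3).
#' @param k_neighbors kNN size for the SNN graph (default 20).
#' @param prune SNN Jaccard pruning threshold (default 1/15).
#' @param n_components LSI components (default 30; component 1 dropped when
#'   `drop_first`).
#' @param drop_first drop the depth-tracking first LSI component.
#' @param binarize binarize counts before TF-IDF.
#' @param s_max,s_fixed,kurt_type walk-length controls, see [select_steps()].
#' @param covariates,use_batch,k_max,n_perm,fdr association-test controls,
#'   see [association_test()].
#' @param seed integer run seed (required).
#' @param keep_nam attach the NAM to the result.
#' @param verbose log per-stage summaries to stderr.
#' @return A `reda_result` (see [association_test()]) whose `config` field
#'   records every tunable, plus `kurtosis_trace` and, if requested, `nam`.
#' @export
reda_run <- function(counts = NULL, samples, embedding = NULL, graph = NULL,
                     alpha = 0.3, k_neighbors = 20, prune = 1 / 15,
                     n_components = 30, drop_first = TRUE, binarize = TRUE,
                     s_max = 50, s_fixed = NULL,
                     kurt_type = c("fisher", "pearson"),
                     covariates = NULL, use_batch = TRUE, k_max = NULL,
                     n_perm = 1000, fdr = 0.05, seed, keep_nam = FALSE,
                     verbose = TRUE) {
  kurt_type <- match.arg(kurt_type)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(samples, "reda_samples"))
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage, ...) {
    reda_log(stage, ..., sprintf(" [%.1fs]", proc.time()[["elapsed"]] - t0),
             verbose = verbose)
  }

  if (is.null(graph)) {
    if (is.null(embedding)) {
      if (is.null(counts))
        stop("provide counts, an embedding, or a graph", call. = FALSE)
      x <- tfidf(counts, binarize = binarize)
      tick("preprocess", fmt_kv(peaks = nrow(x), cells = ncol(x)))
      embedding <- lsi(x, n_components = n_components,
                       drop_first = drop_first,
                       seed = stage_seed(seed, "lsi"))
      tick("lsi", fmt_kv(dims = ncol(embedding$coords)))
    } else {
      stopifnot(inherits(embedding, "reda_embedding"))
      tick("preprocess", "skipped (embedding supplied)")
    }
    graph <- snn_graph(embedding, k = k_neighbors, prune = prune)
    tick("graph", fmt_kv(cells = nrow(graph$adjacency),
                         edges = length(graph$adjacency@x) / 2))
  } else {
    stopifnot(inherits(graph, "reda_graph"))
    tick("graph", "skipped (graph supplied)")
  }

  barcodes <- rownames(graph$adjacency)
  if (is.null(barcodes) && !is.null(counts)) barcodes <- counts$barcodes
  W <- walk_matrix(graph)
  sel <- select_steps(W, samples, barcodes = barcodes, alpha = alpha,
                      s_max = s_max, kurt_type = kurt_type,
                      s_fixed = s_fixed)
  tick("nam", fmt_kv(s_selected = sel$nam$s_selected, alpha = alpha))

  result <- association_test(sel$nam, samples, covariates = covariates,
                             use_batch = use_batch, k_max = k_max,
                             n_perm = n_perm, fdr = fdr, seed = seed)
  tick("assoc", fmt_kv(global_p = signif(result$global_p, 4),
                       k = result$k_selected,
                       n_passing = length(result$passing_cells)))

  result$kurtosis_trace <- sel$nam$kurtosis_trace
  result$config <- list(alpha = alpha, k_neighbors = k_neighbors,
                        prune = prune, n_components = n_components,
                        drop_first = drop_first, binarize = binarize,
                        s_max = s_max, s_fixed = s_fixed,
                        kurt_type = kurt_type, k_max = k_max,
                        n_perm = n_perm, fdr = fdr, seed = seed)
  if (keep_nam) result$nam <- sel$nam
  result
}
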