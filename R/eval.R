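# Desk-scale benchmark harness: replicate simulations, pipeline runs per
# ablation arm with paired per-replicate seeds, and TPR/FPR aggregation.
# External methods are not bundled; plug them in through the adapter
# interface of `run_benchmark(arms = list(...))` — an arm may be a function
# (dataset in, barcode calls out) instead of a built-in label.

builtin_arms <- list(
  default      = list(alpha = 0.3, s_fixed = NULL),
  no_restart   = list(alpha = 0,   s_fixed = NULL),
  high_restart = list(alpha = 0.9, s_fixed = NULL),
  one_step     = list(alpha = 0.3, s_fixed = 1)
)

#' Paired simulation benchmark across ablation arms
#'
#' Simulates `n_replicates` datasets and runs every arm on each of them —
#' the dataset seed is shared across arms, so arm comparisons are paired
#' (identical data, differing only in the arm's walk settings). Built-in
#' arms: `"default"` (alpha 0.3, adaptive steps), `"no_restart"` (alpha 0),
#' `"high_restart"` (alpha 0.9), `"one_step"` (walk forced to one step). A
#' named list element may instead be a function `function(sim) barcodes`
#' adapting an external method.
#'
#' @param n_replicates number of simulated datasets.
#' @param config a [sim_config()] template; its seed is re-derived per
#'   replicate from `seed`.
#' @param arms character vector of built-in arm names, or a named list
#'   mixing built-in names and adapter functions.
#' @param n_perm permutations per run.
#' @param seed master seed; drives dataset and analysis substreams.
#' @param verbose log each run.
#' @return `reda_benchmark`: list with `per_replicate` (replicate, arm,
#'   tpr, fpr, global_p, s_selected, k_selected) and `aggregate` (median
#'   and IQR of TPR/FPR per arm).
#' @export
run_benchmark <- function(n_replicates = 5, config = sim_config(),
                          arms = c("default", "one_step"), n_perm = 500,
                          seed = 1, verbose = FALSE) {
  if (is.character(arms)) {
    bad <- setdiff(arms, names(builtin_arms))
    if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    arms <- stats::setNames(builtin_arms[arms], arms)
  }
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- stage_seed(seed, paste0("dataset", rep_i))
    sim <- simulate_dataset(cfg)
    for (arm_name in names(arms)) {
      arm <- arms[[arm_name]]
      if (is.function(arm)) {
        calls <- arm(sim)
        perf <- evaluate_calls(calls, sim$truth)
        row <- data.frame(replicate = rep_i, arm = arm_name,
                          tpr = perf$tpr, fpr = perf$fpr,
                          global_p = NA_real_, s_selected = NA_integer_,
                          k_selected = NA_integer_)
      } else {
        res <- suppressWarnings(
          reda_run(sim$counts, sim$samples, alpha = arm$alpha,
                   s_fixed = arm$s_fixed, n_perm = n_perm,
                   seed = stage_seed(seed, paste0("run", rep_i)),
                   verbose = FALSE))
        perf <- evaluate_calls(res$passing_cells, sim$truth)
        row <- data.frame(replicate = rep_i, arm = arm_name,
                          tpr = perf$tpr, fpr = perf$fpr,
                          global_p = res$global_p,
                          s_selected = res$s_selected,
                          k_selected = res$k_selected)
      }
      rows[[length(rows) + 1L]] <- row
      reda_log("bench", fmt_kv(replicate = rep_i, arm = arm_name,
                               tpr = signif(row$tpr, 3),
                               fpr = signif(row$fpr, 3)),
               verbose = verbose)
    }
  }
  per_replicate <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_replicate, per_replicate$arm),
    function(d) data.frame(arm = d$arm[1], n = nrow(d),
                           tpr_median = stats::median(d$tpr),
                           tpr_iqr = stats::IQR(d$tpr),
                           fpr_median = stats::median(d$fpr),
                           fpr_iqr = stats::IQR(d$fpr))))
  rownames(agg) <- NULL
  structure(list(per_replicate = per_replicate, aggregate = agg,
                 seed = seed),
            class = "reda_benchmark")
}

#' @export
print.reda_benchmark <- function(x, ...) {
  cat("reDA benchmark\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report as TSV + JSON
#'
#' @param report a `reda_benchmark`.
#' @param dir output directory.
#' @return Invisibly, the file paths.
#' @export
write_benchmark <- function(report, dir) {
  stopifnot(inherits(report, "reda_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_tsv <- file.path(dir, "benchmark.tsv")
  f_json <- file.path(dir, "benchmark.json")
  utils::write.table(report$per_replicate, f_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(aggregate = report$aggregate, seed = report$seed),
                       f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f_tsv, f_json))
}
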