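# Synthetic multi-sample scATAC-seq with planted differentially abundant
# subpopulations and ground-truth labels.
#
# Populations are Gaussian clusters in a latent space; each cell's latent
# position maps to per-peak accessibility probabilities through a logistic
# link whose intercept is calibrated so the mean per-cell detection fraction
# hits the target (scATAC-seq detects roughly 1-10% of peaks per cell).
# Counts are Bernoulli by default — near-binary, like the assay — with
# optional Poisson bursts. The planted signal is an abundance shift: the
# per-sample mixing weight of one population differs between the two
# conditions by `da_effect`; peak accessibility itself is condition-blind
# unless the optional accessibility-shift confounder is enabled.

#' Simulation configuration
#'
#' Defaults are the package's standard benchmark: 2 conditions x 5 samples x
#' 400 cells, 3000 peaks, 4 populations with the differentially abundant one
#' at 15% baseline and a 3-fold abundance effect — small enough to run in
#' seconds yet hard enough to be non-trivial.
#'
#' @param n_samples_per_condition samples per condition (2 conditions).
#' @param cells_per_sample cells drawn per sample.
#' @param n_peaks number of peaks.
#' @param n_populations number of cell populations.
#' @param da_population index (1-based) of the differentially abundant
#'   population.
#' @param da_effect abundance fold-change of that population between
#'   conditions; 1 plants no signal (null design).
#' @param da_baseline baseline mixing weight of the DA population; the
#'   remaining weight is split evenly over the other populations.
#' @param target_sparsity mean per-cell detection fraction to calibrate to,
#'   in (0, 1).
#' @param noise_sd within-population latent spread.
#' @param center_scale spread of the population centers (between-population
#'   separation).
#' @param mix_jitter_sd sd of per-sample log-normal jitter on the mixing
#'   weights (biological replicate variability).
#' @param latent_dim latent-space dimension.
#' @param burst_rate Poisson rate added on top of detected entries; 0 keeps
#'   counts binary.
#' @param accessibility_shift optional confounder: logit shift applied, in
#'   condition 1 cells, to a random 5% of peaks; 0 disables.
#' @param seed integer seed.
#' @return A `reda_sim_config` list.
#' @export
sim_config <- function(n_samples_per_condition = 5, cells_per_sample = 400,
                       n_peaks = 3000, n_populations = 4, da_population = 1,
                       da_effect = 3, da_baseline = 0.15,
                       target_sparsity = 0.05, noise_sd = 0.5,
                       center_scale = 2, mix_jitter_sd = 0.25,
                       latent_dim = 10, burst_rate = 0,
                       accessibility_shift = 0, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples_per_condition >= 1, cfg$cells_per_sample >= 10,
            cfg$n_populations >= 2,
            cfg$da_population >= 1, cfg$da_population <= cfg$n_populations,
            cfg$da_effect >= 1,
            cfg$target_sparsity > 0, cfg$target_sparsity < 1,
            cfg$da_baseline > 0, cfg$da_baseline < 1)
  if (cfg$target_sparsity * cfg$n_peaks < 1)
    stop("target_sparsity unattainable: fewer than one detected peak per cell",
         call. = FALSE)
  structure(cfg, class = "reda_sim_config")
}

#' Simulate a multi-sample scATAC-seq dataset with ground truth
#'
#' See [sim_config()] for the generative model. A fixed seed yields a
#' byte-identical dataset.
#'
#' @param config a [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `samples` (a
#'   [sample_table()]; phenotype 0/1 per condition), and `truth`
#'   (`data.frame` with `barcode`, `population`, `is_da_cell`, `sample`,
#'   `condition`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "reda_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_samples <- 2L * cfg$n_samples_per_condition
    m <- n_samples * cfg$cells_per_sample
    condition <- rep(0:1, each = cfg$n_samples_per_condition)
    sample_ids <- sprintf("s%02d", seq_len(n_samples))

    # mixing weights: DA population scaled by da_effect in condition 1,
    # then renormalized; per-sample log-normal jitter models replicate
    # variability
    w_base <- rep((1 - cfg$da_baseline) / (cfg$n_populations - 1),
                  cfg$n_populations)
    w_base[cfg$da_population] <- cfg$da_baseline
    weights <- matrix(NA_real_, n_samples, cfg$n_populations)
    for (ns in seq_len(n_samples)) {
      w <- w_base
      if (condition[ns] == 1)
        w[cfg$da_population] <- w[cfg$da_population] * cfg$da_effect
      w <- w * exp(rnorm(cfg$n_populations, 0, cfg$mix_jitter_sd))
      weights[ns, ] <- w / sum(w)
    }

    pop <- unlist(lapply(seq_len(n_samples), function(ns)
      sample.int(cfg$n_populations, cfg$cells_per_sample, replace = TRUE,
                 prob = weights[ns, ])))
    cell_sample <- rep(sample_ids, each = cfg$cells_per_sample)

    centers <- matrix(rnorm(cfg$n_populations * cfg$latent_dim,
                            sd = cfg$center_scale),
                      cfg$n_populations, cfg$latent_dim)
    latent <- centers[pop, , drop = FALSE] +
      matrix(rnorm(m * cfg$latent_dim, sd = cfg$noise_sd), m, cfg$latent_dim)

    # peak model: logit p = b0 + b_peak + L x, intercept b0 calibrated so
    # the mean detection probability equals target_sparsity
    loadings <- matrix(rnorm(cfg$n_peaks * cfg$latent_dim,
                             sd = 1 / sqrt(cfg$latent_dim)),
                       cfg$n_peaks, cfg$latent_dim)
    peak_base <- rnorm(cfg$n_peaks, sd = 1)
    eta <- tcrossprod(loadings, latent) + peak_base   # peaks x cells
    if (cfg$accessibility_shift != 0) {
      shifted <- sample.int(cfg$n_peaks, max(1, round(0.05 * cfg$n_peaks)))
      in_cond1 <- condition[match(cell_sample, sample_ids)] == 1
      eta[shifted, in_cond1] <- eta[shifted, in_cond1] + cfg$accessibility_shift
    }
    b0 <- uniroot(function(b) mean(stats::plogis(b + eta)) - cfg$target_sparsity,
                  interval = c(-30, 30), tol = 1e-8)$root
    p <- stats::plogis(b0 + eta)
    x <- matrix(as.numeric(runif(length(p)) < p), nrow(p), ncol(p))
    if (cfg$burst_rate > 0)
      x[x > 0] <- x[x > 0] + rpois(sum(x > 0), cfg$burst_rate)

    barcodes <- sprintf("cell%05d", seq_len(m))
    peaks <- data.frame(chrom = "chrSim",
                        start = (seq_len(cfg$n_peaks) - 1L) * 1000L,
                        end = (seq_len(cfg$n_peaks) - 1L) * 1000L + 500L)
    counts <- count_matrix(Matrix::Matrix(x, sparse = TRUE), peaks, barcodes)
    samples <- sample_table(
      cells = data.frame(barcode = barcodes, sample = cell_sample),
      samples = data.frame(sample = sample_ids, phenotype = condition))
    truth <- data.frame(barcode = barcodes, population = pop,
                        is_da_cell = pop == cfg$da_population,
                        sample = cell_sample,
                        condition = condition[match(cell_sample, sample_ids)])
    list(counts = counts, samples = samples, truth = truth, config = cfg)
  })
}

#' TPR/FPR of a predicted differentially abundant cell set
#'
#' `TPR = |pred ∩ DA| / |DA|`, `FPR = |pred ∩ notDA| / |notDA|` against the
#' planted population labels.
#'
#' @param predicted character vector of barcodes called differentially
#'   abundant (e.g. `passing_cells` of a `reda_result`).
#' @param truth the `truth` data.frame from [simulate_dataset()].
#' @return List with `tpr` and `fpr` (NaN with a warning if the truth has no
#'   DA cells).
#' @export
evaluate_calls <- function(predicted, truth) {
  stopifnot(all(c("barcode", "is_da_cell") %in% names(truth)))
  unknown <- setdiff(predicted, truth$barcode)
  if (length(unknown))
    stop("predicted barcodes absent from truth: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  pred <- truth$barcode %in% predicted
  da <- truth$is_da_cell
  tpr <- if (sum(da) == 0) {
    warning("truth contains no DA cells; TPR undefined", call. = FALSE)
    NaN
  } else sum(pred & da) / sum(da)
  fpr <- sum(pred & !da) / sum(!da)
  list(tpr = tpr, fpr = fpr)
}

#' Write a simulated dataset in the package's input formats
#'
#' Emits the Matrix Market triplet read by [read_count_matrix()], the two
#' design CSVs read by [read_sample_table()], and the truth labels as TSV.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, dir)
  utils::write.csv(sim$samples$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$samples$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
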