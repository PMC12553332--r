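# Association testing between the NAM and a sample-level phenotype:
# covariate control by residualization, PCA of the NAM across samples, a
# selection-aware permutation global test, per-cell neighborhood
# coefficients through the retained PC subspace, and an empirical FDR
# obtained by re-running the whole coefficient pipeline on phenotype
# permutations.

#' Residualize and standardize the NAM
#'
#' Each NAM column (one cell's neighborhood abundance across samples) is
#' centered; if covariates and/or a batch factor are supplied, the column is
#' replaced by its residual from an ordinary least-squares fit on them (with
#' intercept) across samples. Columns are then scaled to unit variance;
#' zero-variance columns are left at zero.
#'
#' @param Q a `reda_nam` or the samples x cells NAM matrix.
#' @param covariates optional numeric matrix/data.frame, one row per sample
#'   (same order as NAM rows).
#' @param batch optional batch factor, one value per sample; converted to
#'   indicator columns of the design.
#' @return The centered, residualized, unit-variance matrix `Q~` (samples x
#'   cells).
#' @export
residualize <- function(Q, covariates = NULL, batch = NULL) {
  if (inherits(Q, "reda_nam")) Q <- Q$Q
  Q <- as.matrix(Q)
  n <- nrow(Q)
  qt <- sweep(Q, 2L, colMeans(Q))
  design <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
    design <- covariates
  }
  if (!is.null(batch)) {
    batch <- factor(batch)
    if (nlevels(batch) > 1) {
      b <- stats::model.matrix(~ batch)[, -1, drop = FALSE]
      design <- cbind(design, b)
    }
  }
  if (!is.null(design)) {
    x <- cbind(`(intercept)` = 1, design)
    dec <- qr(x)
    if (dec$rank < ncol(x)) {
      bad <- colnames(x)[dec$pivot[seq(dec$rank + 1L, ncol(x))]]
      stop("covariate design is rank-deficient; offending column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    qt <- qr.resid(dec, qt)
  }
  s <- apply(qt, 2L, stats::sd)
  # columns annihilated by the residualization (or constant to begin with)
  # are left at zero rather than having round-off noise rescaled to unit
  # variance
  nz <- s > max(s, 0) * 1e-8
  qt[, nz] <- sweep(qt[, nz, drop = FALSE], 2L, s[nz], "/")
  qt[, !nz] <- 0
  qt
}

#' PCA of the residualized NAM
#'
#' Thin SVD `Q~ = U S V^T` with up to `min(N - 1, M)` components. Components
#' whose singular value is numerically zero are dropped. Signs are fixed by
#' making the largest-magnitude cell loading of each component positive, so
#' the decomposition is deterministic.
#'
#' @param qt residualized NAM from [residualize()].
#' @return `reda_nam_pca`: list with `scores` (`U S`, samples x K),
#'   `loadings` (`V`, cells x K), `d` (singular values).
#' @export
nam_pca <- function(qt) {
  n <- nrow(qt)
  k_top <- min(n - 1L, ncol(qt))
  sv <- svd(qt, nu = k_top, nv = k_top)
  d <- sv$d[seq_len(k_top)]
  keep <- d > max(d[1], 0) * 1e-12 & d > 0
  if (sum(keep) < 1)
    stop("no non-degenerate NAM principal component (is the NAM constant?)",
         call. = FALSE)
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  d <- d[keep]
  for (j in seq_along(d)) {
    top <- which.max(abs(v[, j]))
    if (v[top, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  rownames(u) <- rownames(qt)
  rownames(v) <- colnames(qt)
  structure(list(scores = u %*% diag(d, length(d)), loadings = v, d = d,
                 col_norm2 = colSums(qt^2)),
            class = "reda_nam_pca")
}

# Permutation indices of 1..n, shuffling within batch strata when a batch
# factor is given. Returns an n x n_perm integer matrix.
perm_indices <- function(n, n_perm, batch = NULL) {
  out <- matrix(0L, n, n_perm)
  if (is.null(batch)) {
    for (b in seq_len(n_perm)) out[, b] <- sample.int(n)
  } else {
    batch <- factor(batch)
    if (any(table(batch) == 1))
      warning("batch level(s) with a single sample: that sample is unpermutable",
              call. = FALSE)
    strata <- split(seq_len(n), batch)
    for (b in seq_len(n_perm)) {
      idx <- seq_len(n)
      for (g in strata) if (length(g) > 1) idx[g] <- g[sample.int(length(g))]
      out[, b] <- idx
    }
  }
  out
}

# Cumulative R^2 of centered y on the first k score columns, for all k.
# Score columns are centered and mutually orthogonal (they come from an SVD
# of a column-centered matrix), so R^2_k is the cumulative sum of squared
# correlations.
cumulative_r2 <- function(scores, y) {
  yc <- y - mean(y)
  ss_y <- sum(yc^2)
  proj <- as.vector(crossprod(scores, yc))^2 / colSums(scores^2)
  pmin(cumsum(proj) / ss_y, 1)
}

# Rank-selection statistic per k. Raw R^2 is monotone in k and saturates
# at k = N-1 (orthogonal predictors span the centered sample space), so
# maximizing it would always pick the largest, fully saturated rank. Each
# rank is instead scored by the overall F statistic of its k-PC regression,
# (R^2/k) / ((1-R^2)/(N-1-k)), mapped to -log of its parametric tail
# probability so that ranks with very different residual degrees of
# freedom are on a common scale (F with df2 = 1 is far heavier-tailed than
# F with df2 = 8, and a plain max-over-k of F would be dominated by the
# noisiest rank). The parametric tail is only a normalizing transform —
# significance always comes from the permutation distribution of the max.
# Ranks with no residual degrees of freedom (k > N-2) get -Inf; a
# numerically perfect fit gives +Inf, which orders correctly.
selection_stat <- function(r2, n) {
  k <- seq_along(r2)
  df2 <- n - 1 - k
  f <- (r2 / k) / pmax(1 - r2, 0) * df2
  stat <- ifelse(df2 >= 1,
                 -stats::pf(f, k, pmax(df2, 1), lower.tail = FALSE,
                            log.p = TRUE),
                 -Inf)
  stat[df2 >= 1 & r2 >= 1] <- Inf
  stat
}

#' Global association test between NAM variation and the phenotype
#'
#' For each candidate rank k, computes the squared multiple correlation
#' `R^2_k` of the centered phenotype with the first k NAM-PC score columns
#' and scores it by the upper tail of the overall F statistic of that
#' regression (a degrees-of-freedom-aware transform that puts all ranks on
#' a common scale; ranks with no residual degrees of freedom are excluded).
#' The observed statistic is the strongest rank (min-p over k); the same
#' selection is applied inside each permutation of the phenotype across
#' samples (within batch strata when given), so the reported p-value is
#' permutation-calibrated and accounts for the rank selection.
#'
#' @param scores NAM-PC sample scores from [nam_pca()].
#' @param y numeric phenotype, one value per sample.
#' @param batch optional batch factor; permutations are restricted to batch
#'   strata.
#' @param k_max largest rank considered; default `min(N - 1, 10)` capped at
#'   the number of available components.
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed for the permutation stream (required).
#' @return List with `global_p`, `k_selected` (argmax of `R^2_k`), `r2`
#'   (per-k values), `t_obs`, `n_perm`.
#' @export
global_test <- function(scores, y, batch = NULL, k_max = NULL,
                        n_perm = 1000, seed) {
  if (inherits(scores, "reda_nam_pca")) scores <- scores$scores
  n <- nrow(scores)
  if (n < 4) stop("need at least 4 samples for the permutation test",
                  call. = FALSE)
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2) stop("phenotype has no variation", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(k_max)) k_max <- min(n - 1L, 10L)
  k_max <- min(k_max, ncol(scores))
  r2 <- cumulative_r2(scores, y)[seq_len(k_max)]
  stat <- selection_stat(r2, n)
  t_obs <- max(stat)
  k_selected <- which.max(stat)
  t_null <- with_seed(seed, {
    perms <- perm_indices(n, n_perm, batch)
    vapply(seq_len(n_perm), function(b) {
      max(selection_stat(cumulative_r2(scores, y[perms[, b]])[seq_len(k_max)],
                         n))
    }, 0)
  })
  global_p <- (1 + sum(t_null >= t_obs)) / (1 + n_perm)
  list(global_p = global_p, k_selected = k_selected, r2 = r2, t_obs = t_obs,
       n_perm = n_perm)
}

# Per-cell coefficient: inner product of centered y with the rank-k
# projection of each NAM column, normalized by the full column and y norms
# — i.e. the correlation of y with column i after smoothing the column
# through the top-k PC subspace. Normalizing by the full column norm (the
# CNA convention) rather than the reconstruction norm keeps per-cell
# granularity: the reconstruction-normalized variant has constant magnitude
# across all cells whenever k = 1. Computed in O(M k) from the SVD factors.
coef_from_pca <- function(pca, y, k) {
  yc <- y - mean(y)
  u <- sweep(pca$scores[, seq_len(k), drop = FALSE], 2L,
             pca$d[seq_len(k)], "/")
  z <- as.vector(crossprod(u, yc)) * pca$d[seq_len(k)]
  num <- as.vector(pca$loadings[, seq_len(k), drop = FALSE] %*% z)
  cn2 <- pca$col_norm2
  denom <- sqrt(cn2 * sum(yc^2))
  coef <- ifelse(cn2 > max(cn2) * 1e-20, num / denom, 0)
  pmin(pmax(coef, -1), 1)
}

#' Per-cell neighborhood coefficients
#'
#' The coefficient of cell i is the correlation, across samples, between
#' the centered phenotype and NAM column i after smoothing the column
#' through the span of the first `k` NAM PCs: the inner product of the
#' centered phenotype with the rank-k projection of the column, normalized
#' by the full column norm. Values lie in `[-1, 1]` (Cauchy-Schwarz); cells
#' whose column has zero variance, or whose column is orthogonal to the
#' retained subspace, get 0.
#'
#' @param pca a `reda_nam_pca`.
#' @param y numeric phenotype per sample.
#' @param k retained rank, normally `k_selected` from [global_test()].
#' @return Numeric vector of length M (named by barcode when available).
#' @export
local_coefficients <- function(pca, y, k) {
  stopifnot(inherits(pca, "reda_nam_pca"))
  if (k > length(pca$d))
    stop(sprintf("k = %d exceeds the %d available components", k,
                 length(pca$d)), call. = FALSE)
  coef <- coef_from_pca(pca, y, k)
  names(coef) <- rownames(pca$loadings)
  coef
}

#' Empirical FDR for the neighborhood coefficients
#'
#' For each phenotype permutation (within batch strata when given) the
#' entire coefficient pipeline — rank selection by max `R^2_k`, then local
#' coefficients at the selected rank — is re-run, yielding null coefficient
#' vectors. On a grid of thresholds at equally spaced quantiles of the
#' observed `|coefficient|`, `FDR(t)` is the mean null exceedance count
#' divided by the observed exceedance count (at least 1, so the top of the
#' grid never divides by zero), clipped to `[0, 1]` and monotonized by
#' running minimum so stricter thresholds never report a larger FDR.
#'
#' @param pca a `reda_nam_pca`.
#' @param y numeric phenotype per sample.
#' @param coefficients observed coefficients from [local_coefficients()].
#' @param batch optional batch factor for stratified permutation.
#' @param k_max largest rank considered during null rank selection.
#' @param n_perm number of permutations.
#' @param fdr target FDR level (default 0.05).
#' @param seed integer seed (required).
#' @param n_thresholds grid size (default 50).
#' @return List with `fdr_table` (threshold, fdr), `t_star` (smallest
#'   threshold with FDR at or below `fdr`, `NA` if none — then no cell
#'   passes, which is reported, not an error), `passing` (logical per cell),
#'   `n_perm`.
#' @export
empirical_fdr <- function(pca, y, coefficients, batch = NULL, k_max = NULL,
                          n_perm = 1000, fdr = 0.05, seed,
                          n_thresholds = 50) {
  stopifnot(inherits(pca, "reda_nam_pca"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- nrow(pca$scores)
  if (is.null(k_max)) k_max <- min(n - 1L, 10L)
  k_max <- min(k_max, length(pca$d))
  obs <- abs(coefficients)
  thresholds <- unique(stats::quantile(obs, probs = seq(0, 1,
                                                        length.out = n_thresholds),
                                       names = FALSE))
  null_exceed <- matrix(0, n_perm, length(thresholds))
  with_seed(seed, {
    perms <- perm_indices(n, n_perm, batch)
    for (b in seq_len(n_perm)) {
      yp <- y[perms[, b]]
      kb <- which.max(selection_stat(
        cumulative_r2(pca$scores, yp)[seq_len(k_max)], n))
      nul <- abs(coef_from_pca(pca, yp, kb))
      null_exceed[b, ] <- vapply(thresholds, function(t) sum(nul >= t), 0)
    }
  })
  obs_exceed <- vapply(thresholds, function(t) sum(obs >= t), 0)
  fdr_raw <- pmin(pmax(colMeans(null_exceed) / pmax(1, obs_exceed), 0), 1)
  fdr_mono <- cummin(fdr_raw)
  ok <- which(fdr_mono <= fdr)
  t_star <- if (length(ok)) thresholds[min(ok)] else NA_real_
  passing <- if (is.na(t_star)) rep(FALSE, length(obs)) else obs >= t_star
  if (is.na(t_star))
    message(sprintf("no coefficient threshold achieves FDR <= %g; no cell passes",
                    fdr))
  list(fdr_table = data.frame(threshold = thresholds, fdr = fdr_mono,
                              fdr_raw = fdr_raw),
       t_star = t_star, passing = passing, n_perm = n_perm)
}

#' Full association test on a NAM
#'
#' Runs [residualize()], [nam_pca()], [global_test()],
#' [local_coefficients()] and [empirical_fdr()] in sequence. Requires at
#' least 4 samples. The seed drives the two permutation stages through
#' separate substreams (see [stage_seed()]).
#'
#' @param nam a `reda_nam` from [select_steps()] or [nam_from_walk()].
#' @param samples the [sample_table()] used to build the NAM.
#' @param covariates character vector of covariate columns of the sample
#'   table to adjust for; defaults to all of them.
#' @param use_batch adjust for and stratify permutations by the sample
#'   table's `batch` column when present (default TRUE).
#' @param k_max largest NAM-PC rank considered; default `min(N - 1, 10)`.
#' @param n_perm permutations for both the global test and the FDR.
#' @param fdr target FDR (default 0.05).
#' @param seed integer seed (required; recorded in the result).
#' @param verbose log stage summaries.
#' @return A `reda_result`: `global_p`, `k_selected`, `coefficients` (named
#'   per-cell vector in `[-1, 1]`), `fdr_table`, `t_star`, `passing_cells`,
#'   `r2_per_k`, `n_permutations`, `seed`, plus `s_selected`/`alpha` carried
#'   over from the NAM.
#' @export
association_test <- function(nam, samples, covariates = NULL,
                             use_batch = TRUE, k_max = NULL, n_perm = 1000,
                             fdr = 0.05, seed, verbose = FALSE) {
  stopifnot(inherits(nam, "reda_nam"), inherits(samples, "reda_samples"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  meta <- samples$samples[match(nam$sample_ids, samples$samples$sample), ]
  if (nrow(meta) < 4)
    stop("association testing needs at least 4 samples", call. = FALSE)
  y <- meta$phenotype
  if (length(unique(y)) < 2) stop("phenotype has no variation", call. = FALSE)
  if (is.null(covariates)) covariates <- samples$covariate_names
  covariate_mat <- if (length(covariates))
    as.matrix(meta[, covariates, drop = FALSE]) else NULL
  batch <- if (use_batch && !is.null(meta$batch)) factor(meta$batch) else NULL
  qt <- residualize(nam$Q, covariates = covariate_mat, batch = batch)
  pca <- nam_pca(qt)
  glb <- global_test(pca$scores, y, batch = batch, k_max = k_max,
                     n_perm = n_perm, seed = stage_seed(seed, "global"))
  coef <- local_coefficients(pca, y, glb$k_selected)
  efdr <- empirical_fdr(pca, y, coef, batch = batch, k_max = k_max,
                        n_perm = n_perm, fdr = fdr,
                        seed = stage_seed(seed, "fdr"))
  reda_log("assoc", fmt_kv(global_p = signif(glb$global_p, 4),
                           k = glb$k_selected,
                           n_passing = sum(efdr$passing)),
           verbose = verbose)
  structure(list(global_p = glb$global_p, k_selected = glb$k_selected,
                 coefficients = coef, fdr_table = efdr$fdr_table,
                 t_star = efdr$t_star,
                 passing_cells = names(coef)[efdr$passing],
                 r2_per_k = glb$r2, n_permutations = n_perm, fdr = fdr,
                 seed = seed, s_selected = nam$s_selected,
                 alpha = nam$alpha, config = NULL),
            class = "reda_result")
}

#' @export
print.reda_result <- function(x, ...) {
  cat("reDA association result\n")
  cat(sprintf("  global p = %.4g (k = %d, s = %s, alpha = %.2f)\n",
              x$global_p, x$k_selected, format(x$s_selected), x$alpha))
  cat(sprintf("  %d / %d cells pass FDR %.2g (|coef| >= %s)\n",
              length(x$passing_cells), length(x$coefficients), x$fdr,
              ifelse(is.na(x$t_star), "NA", format(signif(x$t_star, 4)))))
  invisible(x)
}
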