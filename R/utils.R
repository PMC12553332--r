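# Internal helpers shared across modules.

#' @importFrom stats cor median quantile rbinom rnorm rpois runif sd uniroot
#' @importFrom methods as is
NULL

#' Derive a stage-specific seed from a run seed
#'
#' A single user-facing seed drives every stochastic stage of a run through
#' stage-name-derived substreams, so adding permutations to one stage never
#' perturbs the draws of another (e.g. the simulated dataset stays identical
#' when `n_perm` changes).
#'
#' @param seed integer run seed.
#' @param stage character stage label, e.g. `"lsi"`, `"global"`, `"fdr"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small polynomial hash of the stage name; modulus keeps the result a
  # valid 32-bit R integer
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% .Machine$integer.max
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Column-wise kurtosis of a matrix
#'
#' Kurtosis of each column across rows, using population moments
#' (`m4 / m2^2`). `"fisher"` subtracts 3 (excess kurtosis), `"pearson"` does
#' not. Columns with zero variance are returned as `NA` so callers can skip
#' them when taking a median.
#'
#' @param x numeric matrix.
#' @param type `"fisher"` (excess, the default) or `"pearson"`.
#' @return Numeric vector of length `ncol(x)`.
#' @export
col_kurtosis <- function(x, type = c("fisher", "pearson")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- nrow(x)
  ctr <- sweep(x, 2L, colMeans(x))
  m2 <- colMeans(ctr^2)
  m4 <- colMeans(ctr^4)
  k <- ifelse(m2 > 0, m4 / m2^2, NA_real_)
  if (type == "fisher") k <- k - 3
  k
}

# Format "name=value" pairs for log lines.
fmt_kv <- function(...) {
  v <- list(...)
  paste(sprintf("%s=%s", names(v), vapply(v, format, "")), collapse = " ")
}

reda_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose))
    message(sprintf("[reDA:%s] %s", stage, paste0(..., collapse = "")))
}
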