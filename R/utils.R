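#' Derive a stage seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically
#' from a single master seed, so that one integer reproduces a whole run.
#' The derivation is a simple multiplicative hash kept inside the 32-bit
#' signed integer range R requires of `set.seed()`.
#'
#' @param master integer master seed.
#' @param offset integer offset identifying the stage or replicate (>= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.numeric(offset), length(offset) == 1L, offset >= 0)
  m <- 2147483647               # 2^31 - 1, Mersenne prime
  s <- (abs(master) %% m)
  # two rounds of a Lehmer-style mix keep nearby (master, offset) pairs apart
  s <- (s * 48271 + offset * 16807 + 12345) %% m
  s <- (s * 48271 + 7919) %% m
  as.integer(s)
}

#' Column z-scores with population standard deviation
#'
#' Standardizes each column to mean 0, SD 1 using the population SD
#' (denominator n). Columns with zero SD are returned as all zeros rather
#' than NaN. This is the single standardization convention used for the
#' cluster-by-marker heatmap and the per-subpopulation ROI count matrix.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  z <- sweep(x, 2L, mu)
  nz <- sdev > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sdev[nz], "/")
  z[, !nz] <- 0
  z
}

# internal: consistent stop() with a class so tests can assert error types
imc_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "imcscope_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
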