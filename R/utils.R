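#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic sub-stream seeds derived from a master seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1009 + 1) %% 2147483629L)
}

# Row-wise log-sum-exp for a matrix of log values. Entries here are log
# bivariate-normal kernels, bounded above by 0 and far from double underflow
# for the c grids in use, so no shift is required.
row_lse <- function(m) log(rowSums(exp(m)))

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
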