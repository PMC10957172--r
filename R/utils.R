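# Internal helpers shared across modules.

# Round half away from zero (Table-style integer percentages, planted counts).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

# Derive a child seed from a master seed and a stage offset, staying inside
# 32-bit integer range.  Exact in double arithmetic (< 2^53).
derive_seed <- function(master, stage) {
  as.integer((abs(as.numeric(master)) * 48271 + 7919 * as.numeric(stage)) %%
               2147483629)
}

# Paired differences that are constant up to floating-point noise make a
# t statistic meaningless; detect them with a relative tolerance.
near_constant <- function(x) {
  sd(x) <= 1e-8 * mean(abs(x)) + 1e-10
}

# Linear interpolation over NA runs; endpoints extended flat.
interp_na <- function(x) {
  miss <- !is.finite(x)
  if (!any(miss)) return(x)
  if (all(miss)) stop("cannot interpolate an all-missing vector")
  idx <- seq_along(x)
  approx(idx[!miss], x[!miss], xout = idx, rule = 2)$y
}

# Zero up to floating-point accumulation error.
near_zero <- function(x) {
  all(abs(x) <= 1e-10)
}
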