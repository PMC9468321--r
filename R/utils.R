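# Internal helpers: typed conditions, quadrature, canonical number formatting.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sutureskill_validation_error",
                                "sutureskill_error", "error")))
}

abort_missing_file <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sutureskill_missing_file_error",
                                "sutureskill_error", "error")))
}

#' @keywords internal
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Trapezoidal quadrature on a uniform grid with spacing dt.
trapz_uniform <- function(v, dt) {
  n <- length(v)
  if (n < 2L) abort_validation("trapezoidal quadrature needs at least 2 samples")
  dt * (sum(v) - 0.5 * (v[1L] + v[n]))
}

# Canonical float formatting: 15 significant digits, deterministic bytes,
# round-trips doubles well below 1e-12 relative.
fmt_num <- function(x) sprintf("%.15g", x)

# Derive a per-unit 31-bit seed from a global seed; pure integer arithmetic in
# doubles, always < 2^31.
derive_seed <- function(seed, index) {
  ((seed %% 2147483629) * 1009 + index * 9973 + 11) %% 2147483629
}
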