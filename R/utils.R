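# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# C-locale lexicographic sort so node order never depends on the session
# locale (state vectors must be reproducible across machines).
sort_c <- function(x) sort(x, method = "radix")

# Deterministic 32-bit sub-seed from (master seed, stream index).
# 2147483647 = 2^31 - 1 (prime); 69621 is invertible mod it, so distinct
# indices under one master seed always yield distinct sub-seeds.
derive_seed <- function(seed, index) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + as.double(index) * 69621) %% 2147483647)
}

# Column-wise max(abs(.)) without apply() overhead; m is a matrix.
col_max_abs <- function(m) {
  out <- abs(m[1L, ])
  nr <- nrow(m)
  if (nr > 1L) for (r in 2:nr) out <- pmax(out, abs(m[r, ]))
  out
}

abort_format <- function(msg) abort(msg, class = "netdasc_format_error")

abort_validation <- function(msg) abort(msg, class = "netdasc_validation_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    abort_validation(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s (got %s)",
      name, if (open_lower) "(" else "[", format(lower), format(upper),
      if (open_upper) ")" else "]", deparse(x)
    ))
  }
  invisible(x)
}
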