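#' @keywords internal
"_PACKAGE"

# Deterministic derivation of sub-stream seeds from one global seed.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...), use.names = FALSE)
  h <- (as.double(seed) %% 2147483647) + 1
  for (p in parts) {
    v <- if (is.character(p)) {
      u <- utf8ToInt(p)
      sum(u * seq_along(u))
    } else {
      as.double(p)
    }
    h <- (h * 48271 + (v %% 2147483647)) %% 2147483647
    h <- (h * 48271 + 1) %% 2147483647
  }
  as.integer(h)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# quartiles by linear interpolation (type 7), the package-wide IQR convention
quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
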