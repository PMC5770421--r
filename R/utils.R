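# internal helpers: argument checking and deterministic seed derivation

assert_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number (got %g).", name, x))
  }
  invisible(x)
}

# 32-bit FNV-1a over a string, in double arithmetic that never exceeds 2^53.
# Used to derive independent RNG streams from (seed, labels...): adding a new
# sample never perturbs the stream of an existing one.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) + (h %/% 2^31) * 2^31
    # 32-bit modular multiply by the FNV prime, split to keep precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) %% 2^32 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  h
}

derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "\x1f")
  as.integer(fnv1a32(key) %% 2147483646) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
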