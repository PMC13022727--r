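# Internal utilities: deterministic ordering and integer hashing.

# Locale-independent string sort (C byte order) so serialized artifacts are
# byte-identical across machines.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# Deterministic 31-bit rolling hash of an integer vector.
hash_ints <- function(x, h0 = 17) {
  h <- h0
  for (v in x) h <- (h * 131 + (v %% 2147483629)) %% 2147483629
  h
}

# Hash a character scalar deterministically.
hash_string <- function(s) hash_ints(utf8ToInt(s))

`%||%` <- function(a, b) if (is.null(a)) b else a
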