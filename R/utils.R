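`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number", name))
  }
}

# Lightweight, dependency-free fingerprint of an R object (a polynomial
# rolling hash over the deparsed form).  Used to stamp output files so a run
# can be matched to its configuration; not cryptographic.
config_fingerprint <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Proportion-style permutation p-value with the plus-one correction.
perm_pvalue <- function(n_ge, n_perm) (1 + n_ge) / (n_perm + 1)
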