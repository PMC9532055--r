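## Internal helpers shared across modules.

#' @noRd
stopf <- function(fmt, ..., class) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "eegpathError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
assertPositiveScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("'%s' must be a positive finite scalar", name,
          class = "invalidConfigError")
  }
  invisible(x)
}

## FNV-1a 32-bit hash of a character scalar; used for feature-layout
## fingerprints so a model refuses rows with a different column layout.
#' @noRd
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    ## xor with a byte only touches the low 8 bits (h kept as a double,
    ## which exceeds R's 32-bit bitwXor range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    ## 32-bit modular multiply in 16-bit halves to stay within the
    ## 53-bit double mantissa
    hi <- floor(h / 65536); lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Deterministic per-recording seed stream, kept below 2^31.
#' @noRd
deriveSeed <- function(baseSeed, index) {
  as.integer((as.double(baseSeed) * 7919 + as.double(index) * 104729 + 11) %%
               2147483647)
}

## Population standard deviation along columns of a matrix.
#' @noRd
colPopSd <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(m * m) - mu * mu)
}
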