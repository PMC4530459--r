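#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages draw their own seeds with a named stream so partial re-runs are
#' reproducible.  The result is a positive integer below 2^31.
#'
#' @param seed master integer seed.
#' @param stream integer or string naming the sub-stream.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stream) {
  s <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(paste0("s", stream)))
    s <- (s * 31 + ch) %% 2147483647
  as.integer(s %% 2147483646) + 1L
}
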