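`%||%` <- function(x, y) if (is.null(x)) y else x

# centred running mean with window k (odd); edges use shrunken windows
.smooth_boxcar <- function(x, k) {
  if (k <= 1) return(x)
  h <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
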