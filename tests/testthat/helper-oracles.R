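# Independent direct-convolution bicubic reference (Keys a = -0.5,
# antialiased, reflect boundary), coded separately from the package path.
ref_bicubic_1d <- function(n_in, f) {
  kern <- function(t, a = -0.5) {
    at <- abs(t)
    ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
           ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
  }
  refl <- function(i, n) {
    while (any(i < 0 | i >= n)) {
      i[i < 0] <- -1 - i[i < 0]
      i[i >= n] <- 2 * n - 1 - i[i >= n]
    }
    i
  }
  D <- matrix(0, n_in / f, n_in)
  for (j in seq_len(n_in / f)) {
    src <- (j - 0.5) * f - 0.5
    is <- seq(floor(src) - 2 * f + 1, floor(src) + 2 * f)
    wv <- kern((is - src) / f)
    ii <- refl(as.integer(is), n_in) + 1
    for (k in seq_along(ii)) D[j, ii[k]] <- D[j, ii[k]] + wv[k]
  }
  D / rowSums(D)
}
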