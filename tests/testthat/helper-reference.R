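# Independent plain-R EMD used as the oracle for the compiled path.
# Deliberately built from stats::spline and R loops only.

ref_local_mean <- function(x) {
  n <- length(x)
  d <- diff(x)
  idx <- which(d[-1] * d[-(n - 1)] < 0) + 1L    # strict interior extrema
  if (length(idx) < 2L) return(NULL)
  maxi <- idx[x[idx] > x[idx - 1L]]
  mini <- idx[x[idx] < x[idx - 1L]]
  if (length(maxi) < 1L || length(mini) < 1L) return(NULL)
  ext <- function(t, v) {
    nl <- min(2L, length(t))
    t0 <- t - 1L                                 # 0-based abscissa
    list(t = c(-rev(t0[seq_len(nl)]), t0, 2 * (n - 1) - rev(t0)[seq_len(nl)]),
         v = c(rev(v[seq_len(nl)]), v, rev(v)[seq_len(nl)]))
  }
  a <- ext(maxi, x[maxi]); b <- ext(mini, x[mini])
  up <- stats::spline(a$t, a$v, xout = 0:(n - 1), method = "natural")$y
  lo <- stats::spline(b$t, b$v, xout = 0:(n - 1), method = "natural")$y
  (up + lo) / 2
}

ref_sift <- function(x, s_number = 2L, max_siftings = 100L) {
  h <- x
  stable <- 0L; prev <- c(-1L, -1L)
  for (s in seq_len(max_siftings)) {
    m <- ref_local_mean(h)
    if (is.null(m)) break
    h <- h - m
    d <- diff(h)
    ne <- sum(d[-1] * d[-(length(h) - 1)] < 0)
    zc <- zero_crossings(h)
    if (abs(ne - zc) <= 1 && ne == prev[1] && zc == prev[2])
      stable <- stable + 1L
    else stable <- 0L
    prev <- c(ne, zc)
    if (stable >= s_number) break
  }
  h
}

ref_emd <- function(x, s_number = 2L) {
  r <- x
  imfs <- list()
  e0 <- sum(x^2)
  repeat {
    m <- ref_local_mean(r)
    if (is.null(m)) break
    imf <- ref_sift(r, s_number)
    if (sum(imf^2) <= 1e-24 * e0) break
    imfs[[length(imfs) + 1L]] <- imf
    r <- r - imf
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs) else
         matrix(numeric(0), length(x), 0),
       residue = r)
}
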