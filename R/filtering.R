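# Zero-phase IIR application and polyphase resampling primitives.
#
# Filter design comes from the `signal` package (Butterworth, FIR
# windows); application is done here because zero-phase filtering needs
# odd-extension padding plus steady-state initial conditions to keep
# edge transients out of the 0.5 Hz high-pass band, and polyphase
# resampling needs unit passband gain.

# Steady-state initial filter state (direct form II transposed) for a
# unit-step input, so that filtering a constant yields its steady-state
# response from the first sample.
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  if (n < 2) return(numeric(0))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  comp <- matrix(0, n - 1, n - 1)
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  comp[1, ] <- -a[2:n]
  solve(diag(n - 1) - t(comp), b[2:n] - a[2:n] * b[1])
}

# Zero-phase (forward-backward) IIR filtering with symmetric (even)
# extension of `padlen` samples at each end and steady-state
# initialization. Even extension keeps the pad free of the DC pedestal
# an odd extension adds, which band-stop filters would pass and ring
# back into the signal.
filtfilt_zp <- function(filt, x, padlen = NULL) {
  b <- filt$b; a <- filt$a
  nfilt <- max(length(a), length(b))
  n <- length(x)
  # default pad: ~18 time constants of a 0.5 Hz edge at 256 Hz
  padlen <- min(n - 1L, padlen %||% max(3L * (nfilt - 1L), 3000L))
  ext <- c(x[(padlen + 1L):2],
           x,
           x[(n - 1L):(n - padlen)])
  zi <- filter_zi(b, a)
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

# Polyphase rational resampling by p/q with a Hamming-windowed FIR
# anti-aliasing/interpolation filter of unit passband gain.
resample_poly <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (p == q) return(x)
  n_taps <- 2L * 10L * max(p, q) + 1L
  h <- signal::fir1(n_taps - 1L, 1 / max(p, q)) * p
  xu <- numeric(length(x) * p)
  xu[seq(1L, length(xu), by = p)] <- x
  delay <- (n_taps - 1L) %/% 2L
  xf <- signal::fftfilt(h, c(xu, numeric(delay)))
  xf <- xf[(delay + 1L):(delay + length(xu))]
  out_len <- ceiling(length(x) * p / q)
  xf[seq(1L, by = q, length.out = out_len)]
}
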