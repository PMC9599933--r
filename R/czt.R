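# Band-restricted zero-padded DFT via the Bluestein chirp-z transform.
#
# The spectral estimator needs the periodogram of short segments on a fixed
# very fine grid (fs / NFFT with NFFT ~ 7e5), but only inside a narrow
# physiological band. Computing the full zero-padded FFT per sliding window
# would dominate the runtime; the chirp-z transform evaluates exactly the
# DFT bins k0..k1 of the zero-padded transform (identical to machine
# precision) in O((n + m) log(n + m)).
#
# X_k = sum_n x_n W^{kn}, W = exp(-2*pi*i/NFFT). With kn =
# (n^2 + k^2 - (k-n)^2)/2 the sum becomes a convolution of chirp-premultiplied
# sequences, evaluated with FFTs of length >= n + m - 1. Squared indices are
# reduced mod 2*NFFT before forming phases so the doubles stay exact.

czt_plan <- function(n, nfft, k0, k1) {
  stopifnot(n >= 1, k1 >= k0, nfft >= n)
  m <- k1 - k0 + 1L
  L <- stats::nextn(n + m - 1L, c(2, 3, 5))
  nn <- 0:(n - 1)
  kk <- 0:(m - 1)
  an <- exp(-2i * pi * ((k0 * nn) %% nfft) / nfft) *
    exp(-1i * pi * ((nn * nn) %% (2 * nfft)) / nfft)
  jj <- (-(n - 1)):(m - 1)
  bj <- exp(1i * pi * ((jj * jj) %% (2 * nfft)) / nfft)
  bpad <- complex(length.out = L)
  bpad[1:m] <- bj[n:(n + m - 1L)]                    # lags 0 .. m-1
  if (n > 1) bpad[(L - n + 2L):L] <- bj[1:(n - 1L)]  # lags -(n-1) .. -1
  ck <- exp(-1i * pi * ((kk * kk) %% (2 * nfft)) / nfft)
  list(n = n, m = m, L = L, k0 = k0, nfft = nfft,
       an = an, B = stats::fft(bpad), ck = ck)
}

czt_exec <- function(x, plan) {
  stopifnot(length(x) == plan$n)
  a <- complex(length.out = plan$L)
  a[seq_len(plan$n)] <- x * plan$an
  y <- stats::fft(stats::fft(a) * plan$B, inverse = TRUE) / plan$L
  y[seq_len(plan$m)] * plan$ck
}
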