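# Minimal DSP layer: digital Butterworth band-pass design (bilinear
# transform), zero-phase forward-backward filtering, and a Welch power
# spectral density. No external signal-processing dependency is available,
# so these are implemented here and validated in the test suite against
# frozen reference outputs from an independent implementation.

# Butterworth band-pass of prototype order n (2n poles after the band
# transform), critical frequencies in Hz. Returns list(b, a) polynomial
# coefficients of the digital filter.
butter_bandpass <- function(n, low_hz, high_hz, fs) {
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  # analog low-pass prototype: poles on the unit circle, no zeros, gain 1
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)     # prewarped edges
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass in the analog domain
  pl <- p * bw / 2
  pb <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
  zb <- rep(0 + 0i, n)
  kb <- bw^n
  # bilinear transform
  pz <- (fs2 + pb) / (fs2 - pb)
  zz <- (fs2 + zb) / (fs2 - zb)
  zz <- c(zz, rep(-1 + 0i, length(pb) - length(zb)))
  kz <- kb * Re(prod(fs2 - zb) / prod(fs2 - pb))
  b <- Re(kz * poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Direct-form IIR filter via two stats::filter passes (MA part as a
# convolution, AR part as a recursion). Zero initial conditions.
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    as.numeric(y)
  } else v
}

# Zero-phase filtering: odd-reflection padding, forward pass, backward pass.
# The pad length is chosen from the slowest filter pole so that the start-up
# transient of the zero-initial-condition recursion has decayed below ~1e-8
# before the retained samples begin.
filtfilt_bf <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) {
    rho <- max(Mod(polyroot(rev(a))))
    pad <- if (rho < 1) ceiling(-18.4 / log(rho)) else 10L * length(a)
    pad <- max(pad, 3L * (max(length(a), length(b)) - 1L))
    pad <- min(pad, n - 1L)
  }
  if (n <= 3L * (max(length(a), length(b)) - 1L))
    stop("signal too short for zero-phase filtering", call. = FALSE)
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a signal (zero-phase Butterworth)
#'
#' 4th-order Butterworth band-pass applied forward and backward (zero phase,
#' so waveform alignment is preserved for correlation metrics).
#'
#' @param x numeric vector.
#' @param fps sampling rate, Hz.
#' @param band `c(low, high)` pass band in Hz; the default 0.65--4.0 Hz
#'   covers 39--240 beats per minute.
#' @param order Butterworth prototype order.
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fps, band = c(0.65, 4.0), order = 4L) {
  ba <- butter_bandpass(order, band[1], band[2], fps)
  filtfilt_bf(ba$b, ba$a, x)
}

# Remove a least-squares straight line.
detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' Shared preprocessing stage for RGB traces
#'
#' Per channel: linear detrend, then zero-phase 4th-order Butterworth
#' band-pass. The output trace is zero-mean per channel and is the common
#' input representation for spectral heart-rate estimation.
#'
#' @param trace an [rgb_trace].
#' @param band pass band in Hz.
#' @return an [rgb_trace] with filtered `values`.
#' @export
preprocess <- function(trace, band = c(0.65, 4.0)) {
  stopifnot(inherits(trace, "rgb_trace"))
  if (nrow(trace$values) < 2 * trace$fps)
    stop("trace shorter than 2 s; not enough data to filter", call. = FALSE)
  v <- apply(trace$values, 2, function(ch)
    bandpass(detrend_linear(ch), trace$fps, band))
  out <- trace
  out$values <- v
  out
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed overlapping segments,
#' zero-padded FFT.
#'
#' @param x numeric vector.
#' @param fps sampling rate, Hz.
#' @param seg_len segment length in samples (clipped to `length(x)`).
#' @param overlap fractional segment overlap.
#' @param nfft FFT length (zero-padded; rounded up to a power of two).
#' @return list with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fps, seg_len = 256L, overlap = 0.5,
                      nfft = 4096L) {
  n <- length(x)
  seg_len <- min(as.integer(seg_len), n)
  hop <- max(1L, as.integer(seg_len * (1 - overlap)))
  nfft <- 2^ceiling(log2(max(nfft, seg_len)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- stats::fft(c(seg, rep(0, nfft - seg_len)))
    acc <- acc + Mod(sp[seq_len(nfft %/% 2 + 1)])^2
  }
  list(freq = (0:(nfft %/% 2)) * fps / nfft,
       power = acc / (length(starts) * sum(win^2) * fps))
}
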