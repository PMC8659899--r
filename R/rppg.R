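# The seven pulse-extraction algorithms. Each takes a RAW per-region RGB
# trace (mean color per frame, 0-255 scale) and returns a bvp_signal; the
# stage each formulation requires (running-mean normalization, detrending,
# band-pass) is applied internally, because chrominance methods need the raw
# channel means that a band-passed trace no longer carries. The final pulse
# of every method is band-passed to the heart-rate band and zero-meaned.

#' Construct a BVP signal object
#'
#' @param samples numeric pulse estimate (arbitrary scale).
#' @param fps sampling rate, Hz.
#' @param method method label.
#' @return an object of class `bvp_signal`.
#' @export
bvp_signal <- function(samples, fps, method = "unknown") {
  samples <- as.numeric(samples)
  samples <- samples - mean(samples)
  structure(list(samples = samples, fps = fps, method = method),
            class = "bvp_signal")
}

#' @export
print.bvp_signal <- function(x, ...) {
  cat(sprintf("<bvp_signal> %s: %d samples @ %g fps\n",
              x$method, length(x$samples), x$fps))
  invisible(x)
}

check_trace <- function(trace, min_seconds = 2) {
  stopifnot(inherits(trace, "rgb_trace"))
  if (nrow(trace$values) < min_seconds * trace$fps)
    stop("trace shorter than ", min_seconds, " s", call. = FALSE)
}

#' GREEN pulse extraction
#'
#' The band-passed green channel, the channel with the strongest hemoglobin
#' absorption signature, is used directly as the pulse estimate.
#'
#' @param trace an [rgb_trace] (raw mean colors).
#' @param band heart-rate pass band, Hz.
#' @return a [bvp_signal].
#' @export
rppg_green <- function(trace, band = c(0.65, 4.0)) {
  check_trace(trace)
  g <- trace$values[, 2]
  if (stats::sd(g) == 0)
    return(bvp_signal(rep(0, length(g)), trace$fps, "GREEN"))
  bvp_signal(bandpass(detrend_linear(g), trace$fps, band),
             trace$fps, "GREEN")
}

#' ICA (JADE) pulse extraction
#'
#' Detrends and band-passes the three channels, separates them with JADE,
#' and returns one component. Component selection: `"spectral"` (default)
#' picks the component with the largest in-band spectral peak
#' (deterministic and robust); `"second"` reproduces the classical
#' empirical rule of taking the second component.
#'
#' @param trace an [rgb_trace].
#' @param select `"spectral"` or `"second"`.
#' @param band heart-rate pass band, Hz.
#' @return a [bvp_signal].
#' @export
rppg_ica <- function(trace, select = c("spectral", "second"),
                     band = c(0.65, 4.0)) {
  select <- match.arg(select)
  check_trace(trace, min_seconds = 10)
  raw_sds <- apply(trace$values, 2, stats::sd)
  if (any(raw_sds == 0))
    stop("rank-deficient input: constant channel(s) ",
         paste(which(raw_sds == 0), collapse = ","), call. = FALSE)
  X <- apply(trace$values, 2, detrend_linear)
  for (i in 1:2) for (j in (i + 1):3)
    if (identical(trace$values[, i], trace$values[, j]))
      stop("rank-deficient input: channels ", i, " and ", j,
           " are identical", call. = FALSE)
  Xf <- apply(X, 2, bandpass, fps = trace$fps, band = band)
  dec <- jade(t(Xf))
  comp <- if (select == "second") {
    dec$S[2, ]
  } else {
    peaks <- apply(dec$S, 1, function(s) {
      psd <- welch_psd(s, trace$fps)
      inb <- psd$freq >= band[1] & psd$freq <= band[2]
      max(psd$power[inb])
    })
    dec$S[which.max(peaks), ]
  }
  bvp_signal(comp, trace$fps, "ICA")
}

# Centered running mean with edge shrinkage (partial windows at the ends).
running_mean <- function(x, L) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- L %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

hann_window <- function(L) 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))

#' CHROM pulse extraction
#'
#' Chrominance-based method: channels are normalized by a running mean,
#' projected onto the chrominance pair X = 3R - 2G, Y = 1.5R + G - 1.5B
#' (which cancels achromatic intensity variation), band-passed, and
#' combined as X - (sd(X)/sd(Y)) * Y in Hann-weighted overlapping windows
#' with overlap-add.
#'
#' @param trace an [rgb_trace]; channel means must be strictly positive.
#' @param window_s analysis window, seconds.
#' @param band heart-rate pass band, Hz.
#' @return a [bvp_signal].
#' @export
rppg_chrom <- function(trace, window_s = 1.6, band = c(0.65, 4.0)) {
  check_trace(trace)
  V <- trace$values
  if (any(colMeans(V) <= 0))
    stop("CHROM needs strictly positive channel means", call. = FALSE)
  fps <- trace$fps
  T_ <- nrow(V)
  L <- min(2L * max(1L, round(window_s * fps / 2)), T_)  # even window
  Cn <- sapply(1:3, function(c) V[, c] / running_mean(V[, c], L) - 1)
  Xs <- 3 * Cn[, 1] - 2 * Cn[, 2]
  Ys <- 1.5 * Cn[, 1] + Cn[, 2] - 1.5 * Cn[, 3]
  Xf <- bandpass(Xs, fps, band)
  Yf <- bandpass(Ys, fps, band)
  hop <- L %/% 2
  win <- hann_window(L)
  out <- numeric(T_)
  wsum <- numeric(T_)
  starts <- unique(c(seq(1L, T_ - L + 1L, by = hop), T_ - L + 1L))
  for (s in starts) {
    i <- s:(s + L - 1L)
    sy <- stats::sd(Yf[i])
    alpha <- if (sy > 0) stats::sd(Xf[i]) / sy else 0
    seg <- Xf[i] - alpha * Yf[i]
    out[i] <- out[i] + win * (seg - mean(seg))
    wsum[i] <- wsum[i] + win
  }
  out[wsum > 0] <- out[wsum > 0] / wsum[wsum > 0]
  bvp_signal(out, fps, "CHROM")
}

#' POS pulse extraction
#'
#' Plane-orthogonal-to-skin method: within each sliding window (default
#' 1.6 s, hop one frame) channels are temporally normalized by their window
#' mean, projected with the matrix `[[0, 1, -1], [-2, 1, 1]]` (both rows sum
#' to zero, cancelling achromatic variation), combined as
#' `S1 + (sd(S1)/sd(S2)) * S2`, and overlap-added.
#'
#' Implemented with rolling-sum algebra (exactly equivalent to the
#' per-window loop, since the per-window means of the projected signals are
#' identically zero) so that long recordings stay fast in R.
#'
#' @param trace an [rgb_trace]; channel means must be strictly positive.
#' @param window_s sliding window, seconds.
#' @param band final pass band, Hz.
#' @return a [bvp_signal].
#' @export
rppg_pos <- function(trace, window_s = 1.6, band = c(0.65, 4.0)) {
  check_trace(trace)
  V <- trace$values
  if (any(colMeans(V) <= 0))
    stop("POS needs strictly positive channel means", call. = FALSE)
  fps <- trace$fps
  T_ <- nrow(V)
  L <- min(max(3L, round(window_s * fps)), T_)
  R <- V[, 1]; G <- V[, 2]; B <- V[, 3]
  roll <- function(x) {             # sum over each window of length L
    cs <- c(0, cumsum(x))
    cs[(L + 1):(T_ + 1)] - cs[1:(T_ - L + 1)]
  }
  muR <- roll(R) / L; muG <- roll(G) / L; muB <- roll(B) / L
  if (any(muR <= 0 | muG <= 0 | muB <= 0))
    stop("POS needs strictly positive window means", call. = FALSE)
  sGG <- roll(G * G); sBB <- roll(B * B); sRR <- roll(R * R)
  sGB <- roll(G * B); sRG <- roll(R * G); sRB <- roll(R * B)
  # window variances of S1 = Gn - Bn and S2 = -2Rn + Gn + Bn (means are 1-1=0
  # and -2+1+1=0 exactly)
  v1 <- sGG / (L * muG^2) - 2 * sGB / (L * muG * muB) + sBB / (L * muB^2) - 0
  v2 <- 4 * sRR / (L * muR^2) + sGG / (L * muG^2) + sBB / (L * muB^2) -
    4 * sRG / (L * muR * muG) - 4 * sRB / (L * muR * muB) +
    2 * sGB / (L * muG * muB)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  r <- ifelse(v2 > 0, sqrt(v1) / sqrt(v2), 0)
  # per-window channel coefficients, accumulated over the windows covering t
  aR <- -2 * r / muR
  aG <- (1 + r) / muG
  aB <- (r - 1) / muB
  nw <- T_ - L + 1L
  cover_sum <- function(a) {        # sum a[w] over windows w containing t
    cs <- c(0, cumsum(a))
    w_lo <- pmax(seq_len(T_) - L + 1L, 1L)
    w_hi <- pmin(seq_len(T_), nw)
    out <- cs[w_hi + 1] - cs[w_lo]
    out[w_hi < w_lo] <- 0
    out
  }
  H <- R * cover_sum(aR) + G * cover_sum(aG) + B * cover_sum(aB)
  bvp_signal(bandpass(H - mean(H), fps, band), fps, "POS")
}

#' SSR pulse extraction (spatial subspace rotation)
#'
#' Works on retained per-frame pixel colors rather than the mean trace: per
#' frame, the 3 x 3 pixel-color correlation matrix is eigendecomposed; the
#' rotation of the principal (skin-tone) axis against the subspace of a
#' reference frame one temporal stride back yields the pulse, assembled by
#' overlap-add.
#'
#' @param trace an [rgb_trace] carrying `pixel_samples` (from
#'   `extract_rgb_trace(..., keep_pixels = TRUE)`), or a list of per-frame
#'   pixel matrices.
#' @param fps sampling rate (taken from the trace when one is given).
#' @param stride_s temporal stride, seconds.
#' @param band final pass band, Hz.
#' @return a [bvp_signal].
#' @export
rppg_ssr <- function(trace, fps = NULL, stride_s = 1.0, band = c(0.65, 4.0)) {
  if (inherits(trace, "rgb_trace")) {
    pixels <- trace$pixel_samples
    fps <- trace$fps
    if (is.null(pixels))
      stop("SSR needs pixel samples; extract the trace with keep_pixels=TRUE",
           call. = FALSE)
  } else pixels <- trace
  K <- length(pixels)
  if (K < 2 * fps) stop("need at least 2 s of frames", call. = FALSE)
  if (any(vapply(pixels, nrow, 1L) < 3L))
    stop("fewer pixels than channels in some frame", call. = FALSE)
  l <- max(2L, round(stride_s * fps))
  U <- vector("list", K); lam <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    Vk <- pixels[[k]]
    C <- crossprod(Vk) / nrow(Vk)
    e <- eigen(C, symmetric = TRUE)
    V_ <- e$vectors
    if (k > 1L) for (j in 1:3)       # eigenvectors have arbitrary sign;
      if (sum(V_[, j] * U[[k - 1L]][, j]) < 0) V_[, j] <- -V_[, j]
    U[[k]] <- V_                      # enforce temporal continuity
    lam[k, ] <- pmax(e$values, 0)
  }
  # degenerate only if the pixel cloud is rank-1 in (nearly) every frame,
  # i.e. no spatial color diversity at all; isolated rank drops (e.g. at
  # pulse zero-crossings) are handled per window below
  if (mean(lam[, 2] / lam[, 1] < 1e-12) > 0.9)
    stop("degenerate pixel-color correlation (rank < 2): SSR needs ",
         "spatial color diversity", call. = FALSE)
  P <- numeric(K)
  for (k in seq(l, K)) {
    tau <- k - l + 1L
    u2 <- U[[tau]][, 2]; u3 <- U[[tau]][, 3]
    idx <- tau:k
    s1 <- s2 <- numeric(length(idx))
    lam2_ok <- lam[tau, 2] / lam[tau, 1] > 1e-12
    lam3_ok <- lam[tau, 3] / lam[tau, 1] > 1e-12
    for (j in seq_along(idx)) {
      t <- idx[j]
      u1t <- U[[t]][, 1]
      s1[j] <- if (lam2_ok)
        sqrt(lam[t, 1] / lam[tau, 2]) * sum(u1t * u2) else 0
      s2[j] <- if (lam3_ok)
        sqrt(lam[t, 1] / lam[tau, 3]) * sum(u1t * u3) else 0
    }
    sd2 <- stats::sd(s2)
    p <- if (sd2 > 0) s1 - stats::sd(s1) / sd2 * s2 else s1
    P[idx] <- P[idx] + (p - mean(p))
  }
  bvp_signal(bandpass(P, fps, band), fps, "SSR")
}

default_pbv_signature <- function() {
  s <- c(0.33, 0.78, 0.53)     # published blood-volume pulse signature
  s / sqrt(sum(s^2))
}

#' PBV pulse extraction
#'
#' Blood-volume-pulse signature method: the weights `w` solving
#' `(C C^T) w = signature` over the normalized band-passed channels give the
#' linear combination whose color direction matches the known pulse
#' signature, suppressing motion components along other directions.
#'
#' @param trace an [rgb_trace].
#' @param signature 3-vector pulse color signature (unit-normalized
#'   internally); default is the published skin-reflection value.
#' @param band pass band, Hz.
#' @return a [bvp_signal].
#' @export
rppg_pbv <- function(trace, signature = default_pbv_signature(),
                     band = c(0.65, 4.0)) {
  check_trace(trace)
  signature <- signature / sqrt(sum(signature^2))
  mu <- colMeans(trace$values)
  if (any(mu <= 0)) stop("PBV needs positive channel means", call. = FALSE)
  Cn <- sweep(trace$values, 2, mu, "/") - 1
  Cf <- t(apply(Cn, 2, bandpass, fps = trace$fps, band = band))  # 3 x T
  Q <- tcrossprod(Cf)
  if (rcond(Q) < 1e-12) {
    warning("near-singular channel covariance; using regularized solve")
    Q <- Q + diag(3) * max(diag(Q), .Machine$double.eps) * 1e-9
  }
  w <- solve(Q, signature)
  bvp_signal(drop(w %*% Cf), trace$fps, "PBV")
}

#' LGI pulse extraction
#'
#' Local group invariance: the dominant left-singular direction `u1` of the
#' channel matrix (the global intensity/illumination axis) is projected out
#' with `P = I - u1 u1^T`. The default output is the projection of the
#' channels onto the second singular direction, which is invariant (up to
#' sign) under orthogonal channel rotations; `channel = "green"` instead
#' returns the green row of the projected matrix, matching common reference
#' implementations.
#'
#' @param trace an [rgb_trace].
#' @param channel `"svd"` (default) or `"green"`.
#' @param band pass band, Hz.
#' @return a [bvp_signal].
#' @export
rppg_lgi <- function(trace, channel = c("svd", "green"),
                     band = c(0.65, 4.0)) {
  channel <- match.arg(channel)
  check_trace(trace)
  # NOT demeaned: the dominant singular direction of the raw channel matrix
  # is the DC / global-illumination axis, which is what gets projected out
  C <- t(trace$values)               # 3 x T
  sv <- svd(C)
  if (sv$d[1] <= 0 || !any(sv$d > 1e-12 * sv$d[1]))
    stop("zero-energy trace: nothing to decompose", call. = FALSE)
  if (channel == "svd") {
    u2 <- sv$u[, 2]
    if (u2[which.max(abs(u2))] < 0) u2 <- -u2  # deterministic sign
    p <- drop(u2 %*% C)
  } else {
    u1 <- sv$u[, 1]
    F_ <- (diag(3) - tcrossprod(u1)) %*% C
    p <- F_[2, ]
  }
  bvp_signal(bandpass(p, trace$fps, band), trace$fps, "LGI")
}

#' Registry of pulse-extraction methods
#'
#' @param methods character vector of method names to select (any of
#'   GREEN, ICA, CHROM, POS, SSR, PBV, LGI); default all seven.
#' @return named list of functions, each mapping an [rgb_trace] to a
#'   [bvp_signal].
#' @export
rppg_method_registry <- function(methods = NULL) {
  reg <- list(GREEN = rppg_green, ICA = rppg_ica, CHROM = rppg_chrom,
              POS = rppg_pos, SSR = rppg_ssr, PBV = rppg_pbv,
              LGI = rppg_lgi)
  if (is.null(methods)) return(reg)
  methods <- toupper(methods)
  bad <- setdiff(methods, names(reg))
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  reg[methods]
}

#' Windowed heart-rate estimation from a pulse signal
#'
#' Per overlapping window, the Welch power spectral density is computed and
#' the heart rate taken as 60 times the in-band peak frequency.
#'
#' @param bvp a [bvp_signal] (or numeric vector with `fps` supplied).
#' @param window_s analysis window, seconds.
#' @param hop_s hop between windows, seconds.
#' @param band admissible pulse band, Hz (default 0.65--4.0 Hz, i.e.
#'   39--240 beats per minute).
#' @param fps sampling rate when `bvp` is a plain vector.
#' @param nfft FFT length for the spectral grid.
#' @return a `bpm_series`: list with `window_centers` (s), `bpm`, `band`.
#' @export
estimate_bpm <- function(bvp, window_s = 10, hop_s = 1,
                         band = c(0.65, 4.0), fps = NULL, nfft = 8192L) {
  if (inherits(bvp, "bvp_signal")) {
    x <- bvp$samples; fps <- bvp$fps
  } else x <- as.numeric(bvp)
  n <- length(x)
  win <- round(window_s * fps)
  hop <- max(1L, round(hop_s * fps))
  if (win > n)
    stop("window longer than the signal", call. = FALSE)
  starts <- seq(1L, n - win + 1L, by = hop)
  bpm <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win - 1L)]
    psd <- welch_psd(seg, fps, seg_len = min(256L, win), nfft = nfft)
    inb <- which(psd$freq >= band[1] & psd$freq <= band[2])
    bpm[i] <- 60 * psd$freq[inb[which.max(psd$power[inb])]]
  }
  structure(list(window_centers = (starts - 1L + win / 2) / fps,
                 bpm = bpm, band = band),
            class = "bpm_series")
}
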