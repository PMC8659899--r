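# JADE: blind source separation by joint approximate diagonalization of
# fourth-order cumulant matrices (Cardoso & Souloumiac). Deterministic:
# whitening by eigendecomposition, Jacobi rotations with a fixed sweep
# order, and a sign convention on the unmixing rows.

#' JADE independent component analysis
#'
#' Separates an `n x T` channel matrix into `n` independent components by
#' joint diagonalization of the whitened fourth-order cumulant matrices.
#'
#' @param X numeric `n x T` matrix (channels in rows), `T >> n`.
#' @param eps Jacobi rotation threshold.
#' @param rank_tol relative covariance-eigenvalue cutoff below which a
#'   direction is treated as carrying no signal (PCA dimension reduction;
#'   degenerate inputs yield fewer sources instead of failing).
#' @return list with `S` (`n x T` estimated sources, unit variance), `B`
#'   (unmixing matrix, `S = B %*% X` after demeaning), `W` (whitener).
#' @export
jade <- function(X, eps = NULL, rank_tol = 1e-9) {
  X <- as.matrix(X)
  nch <- nrow(X); T_ <- ncol(X)
  if (T_ < 10L * nch)
    stop("JADE needs substantially more samples than channels", call. = FALSE)
  X <- X - rowMeans(X)
  R <- tcrossprod(X) / T_
  ev <- eigen(R, symmetric = TRUE)
  if (ev$values[1] <= 0)
    stop("rank-deficient input: channel covariance is singular ",
         "(a constant channel?)", call. = FALSE)
  # keep only directions carrying variance (PCA step of JADE); degenerate
  # inputs reduce to fewer effective sources rather than exploding
  n <- sum(ev$values / ev$values[1] > rank_tol)
  W <- diag(1 / sqrt(ev$values[seq_len(n)]), n) %*%
    t(ev$vectors[, seq_len(n), drop = FALSE])
  Z <- W %*% X                       # whitened: cov = I
  if (n == 1L) {
    B <- W
    if (B[1, which.max(abs(B[1, ]))] < 0) B <- -B
    return(list(S = B %*% X, B = B, W = W))
  }

  # cumulant matrix set (n(n+1)/2 symmetric n x n matrices)
  nbcm <- n * (n + 1L) / 2L
  CM <- array(0, c(n, n, nbcm))
  k <- 1L
  for (im in seq_len(n)) {
    Zim <- Z[im, ]
    Qii <- (Z * rep(Zim * Zim, each = n)) %*% t(Z) / T_ -
      diag(n) - 2 * tcrossprod(diag(n)[, im])
    CM[, , k] <- Qii; k <- k + 1L
    if (im > 1L) for (jm in seq_len(im - 1L)) {
      Zjm <- Z[jm, ]
      Qij <- (Z * rep(Zim * Zjm, each = n)) %*% t(Z) / T_ -
        tcrossprod(diag(n)[, im], diag(n)[, jm]) -
        tcrossprod(diag(n)[, jm], diag(n)[, im])
      CM[, , k] <- sqrt(2) * Qij; k <- k + 1L
    }
  }

  if (is.null(eps)) eps <- 1 / sqrt(T_) / 100
  V <- diag(n)
  sweeps <- 0L
  max_sweeps <- 100L   # Jacobi sweeps can cycle on exactly symmetric inputs
  repeat {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) break
    rotated <- FALSE
    for (p in seq_len(n - 1L)) for (q in seq((p + 1L), n)) {
      g1 <- CM[p, p, ] - CM[q, q, ]
      g2 <- CM[p, q, ] + CM[q, p, ]
      ton <- sum(g1 * g1) - sum(g2 * g2)
      toff <- 2 * sum(g1 * g2)
      theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
      if (abs(theta) > eps) {
        rotated <- TRUE
        cth <- cos(theta); sth <- sin(theta)
        G <- matrix(c(cth, sth, -sth, cth), 2, 2)  # [c -s; s c]
        pq <- c(p, q)
        V[, pq] <- V[, pq] %*% G
        CM[pq, , ] <- array(apply(CM[pq, , , drop = FALSE], 3,
                                  function(M) t(G) %*% M), c(2, n, nbcm))
        CM[, pq, ] <- array(apply(CM[, pq, , drop = FALSE], 3,
                                  function(M) M %*% G), c(n, 2, nbcm))
      }
    }
    if (!rotated) break
  }

  B <- t(V) %*% W
  # deterministic output order (descending energy through B) and sign
  ord <- order(rowSums(B^2), decreasing = TRUE)
  B <- B[ord, , drop = FALSE]
  for (i in seq_len(n)) {
    j <- which.max(abs(B[i, ]))
    if (B[i, j] < 0) B[i, ] <- -B[i, ]
  }
  list(S = B %*% X, B = B, W = W)
}
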