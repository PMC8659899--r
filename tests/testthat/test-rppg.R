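# Method-level tests. Traces are constructed analytically (multiplicative
# pulse/illumination on a skin-tone mean, as in the generator's world) so
# each algorithm's defining property can be asserted directly.

fps <- 30
tt <- (0:1799) / fps
bvp_ref <- sin(2 * pi * 1.2 * tt) + 0.3 * sin(2 * pi * 2.4 * tt)

test_that("GREEN returns the (filtered) green channel", {
  v <- cbind(rep(100, 1800), 110 + 5 * bvp_ref, rep(90, 1800))
  out <- rppg_green(make_plain_trace(v, fps))
  expect_gte(cor(out$samples, bvp_ref), 0.99)
  v0 <- v; v0[, 2] <- 0
  expect_equal(rppg_green(make_plain_trace(v0, fps))$samples,
               rep(0, 1800))
})

test_that("JADE separates mixed sources and flags rank deficiency", {
  set.seed(21)
  S <- rbind(sin(2 * pi * 0.8 * tt), sin(2 * pi * 1.3 * tt + 1),
             sin(2 * pi * 2.2 * tt + 2))
  A <- matrix(c(1, .5, .3, .4, 1.2, .7, .2, .6, .9), 3, 3)
  dec <- jade(A %*% S)
  for (i in 1:3)
    expect_gte(max(abs(cor(t(dec$S), S[i, ]))), 0.95)
  # pulse mixed with broadband noise sources: the spectral-peak rule picks
  # the component whose power is concentrated at one in-band frequency
  mix <- t(A %*% rbind(bvp_ref, rnorm(1800), rnorm(1800))) +
    rep(c(150, 100, 70), each = 1800)
  out <- rppg_ica(make_plain_trace(mix, fps))
  expect_gte(abs(cor(out$samples, bvp_ref)), 0.9)
  # duplicated channels are a decomposition error
  dup <- cbind(mix[, 1], mix[, 1], mix[, 3])
  expect_error(rppg_ica(make_plain_trace(dup, fps)), "rank-deficient")
  expect_error(rppg_ica(make_plain_trace(cbind(mix[, 1:2], 50), fps)),
               "constant channel")
})

test_that("CHROM cancels achromatic variation and is gain-invariant", {
  # generator fixture: identical fluctuation on R = G = B
  trf <- get_flicker_trace()
  flick_sd <- sd(trf$values[, 2])
  out_g <- rppg_green(trf)
  out_c <- rppg_chrom(trf)
  expect_gte(sd(out_g$samples), 0.5 * flick_sd)  # GREEN passes the flicker
  expect_lte(sd(out_c$samples), 0.01 * flick_sd) # CHROM cancels it
  # planted pulse + achromatic illumination: CHROM beats GREEN
  mu <- c(150, 100, 70)
  illum <- 0.04 * sin(2 * pi * 0.9 * tt)
  k <- c(0.33, 0.78, 0.53) / sqrt(sum(c(0.33, 0.78, 0.53)^2))
  v <- sapply(1:3, function(c) mu[c] * (1 + 0.02 * k[c] * bvp_ref + illum))
  tr <- make_plain_trace(v, fps)
  expect_gt(abs(cor(rppg_chrom(tr)$samples, bvp_ref)),
            abs(cor(rppg_green(tr)$samples, bvp_ref)))
  # global gain x2: identical output
  tr2 <- make_plain_trace(2 * v, fps)
  expect_equal(rppg_chrom(tr2)$samples, rppg_chrom(tr)$samples,
               tolerance = 1e-8)
  expect_error(rppg_chrom(make_plain_trace(v - 200, fps)), "positive")
})

test_that("POS cancels achromatic variation, recovers BPM, gain-invariant", {
  trf <- get_flicker_trace()
  expect_lte(sd(rppg_pos(trf)$samples), 0.01 * sd(trf$values[, 2]))
  # noiseless scene: BPM within +/- 1 of the planted ramp
  sc <- get_noiseless_scene()
  tr <- get_noiseless_trace()
  est <- estimate_bpm(rppg_pos(tr))
  expect_lte(max(abs(est$bpm - scene_truth_bpm(sc, est$window_centers))), 1)
  mu <- c(150, 100, 70)
  k <- c(0.3, 0.8, 0.5)
  v <- sapply(1:3, function(c) mu[c] * (1 + 0.02 * k[c] * bvp_ref))
  p1 <- rppg_pos(make_plain_trace(v, fps))
  p2 <- rppg_pos(make_plain_trace(2 * v, fps))
  expect_equal(p2$samples, p1$samples, tolerance = 1e-8)
})

test_that("SSR: recovery, permutation invariance, degeneracy error", {
  tr <- get_noiseless_trace()
  sc <- get_noiseless_scene()
  est <- estimate_bpm(rppg_ssr(tr))
  expect_lte(max(abs(est$bpm - scene_truth_bpm(sc, est$window_centers))), 2)
  # permuting pixels within frames leaves the output unchanged
  set.seed(9)
  perm <- sample(nrow(tr$pixel_samples[[1]]))
  tr_p <- tr
  tr_p$pixel_samples <- lapply(tr$pixel_samples,
                               function(m) m[perm, , drop = FALSE])
  # correlation matrices are permutation-invariant; floating-point
  # summation order leaves ~1e-5 relative differences
  expect_gt(cor(rppg_ssr(tr_p)$samples, rppg_ssr(tr)$samples), 0.99999)
  # rank-1 pixel clouds in every frame -> degenerate-correlation error
  tr_d <- tr
  tr_d$pixel_samples <- lapply(seq_along(tr$pixel_samples), function(t)
    matrix(rep(c(150, 100, 70), each = 50), 50, 3) * (1 + 0.01 * sin(t)))
  expect_error(rppg_ssr(tr_d), "degenerate")
})

test_that("PBV: signature alignment, orthogonality, exact solve", {
  mu <- c(150, 100, 70)
  s <- rppgroi:::default_pbv_signature()
  o <- c(s[2], -s[1], 0); o <- o / sqrt(sum(o^2))  # orthogonal direction
  w_noise <- sin(2 * pi * 1.8 * tt + 0.5)
  v <- sapply(1:3, function(c)
    mu[c] * (1 + 0.02 * s[c] * bvp_ref + 0.02 * o[c] * w_noise))
  out <- suppressWarnings(rppg_pbv(make_plain_trace(v, fps)))
  expect_gte(abs(cor(out$samples, bvp_ref)), 0.95)
  # signature orthogonal to the planted direction: output vanishes
  v1 <- sapply(1:3, function(c) mu[c] * (1 + 0.02 * s[c] * bvp_ref))
  out_o <- suppressWarnings(rppg_pbv(make_plain_trace(v1, fps),
                                     signature = o))
  p <- if (sd(out_o$samples) < 1e-9) 0 else abs(cor(out_o$samples, bvp_ref))
  expect_lte(p, 0.2)
  # zero-noise single-direction trace: output proportional to the pulse
  out_1 <- suppressWarnings(rppg_pbv(make_plain_trace(v1, fps)))
  expect_gte(abs(cor(out_1$samples, bvp_ref)), 0.999)
})

test_that("LGI: projection removes illumination, rotation-invariant", {
  mu <- c(150, 100, 70)
  q <- c(mu[2], -mu[1], 0); q <- q / sqrt(sum(q^2))  # off the mean axis
  illum <- 0.05 * sin(2 * pi * 0.9 * tt)             # along the mean axis
  v <- sapply(1:3, function(c) mu[c] * (1 + illum)) + 2 * outer(bvp_ref, q)
  tr <- make_plain_trace(v, fps)
  expect_gte(abs(cor(rppg_lgi(tr)$samples, bvp_ref)), 0.8)
  # trace entirely in the dominant direction: near-zero output
  v0 <- sapply(1:3, function(c) mu[c] * (1 + illum))
  out0 <- rppg_lgi(make_plain_trace(v0, fps))
  expect_lte(sd(out0$samples), 1e-6 * sd(illum * mu[1]))
  # orthogonal channel rotation: output invariant up to sign
  set.seed(4)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  out_r <- rppg_lgi(make_plain_trace(t(R %*% t(v)), fps))
  expect_gte(abs(cor(out_r$samples, rppg_lgi(tr)$samples)), 0.9999)
})

test_that("estimate_bpm: tones, band restriction, chirp tracking", {
  x <- sin(2 * pi * 1.2 * tt)
  est <- estimate_bpm(x, fps = fps)
  expect_true(all(abs(est$bpm - 72) <= 0.25))
  # out-of-band drift is ignored even when stronger
  x2 <- 0.5 * sin(2 * pi * 1.0 * tt) + 2 * sin(2 * pi * 0.2 * tt)
  est2 <- estimate_bpm(x2, fps = fps)
  expect_true(all(abs(est2$bpm - 60) <= 0.25))
  # chirp 1.0 -> 1.5 Hz over 60 s: tracks instantaneous frequency
  phase <- 2 * pi * (tt + 0.25 * tt^2 / 60)
  est3 <- estimate_bpm(sin(phase), fps = fps)
  f_inst <- 60 * (1 + 0.5 * est3$window_centers / 60)
  expect_true(all(abs(est3$bpm - f_inst) <= 3))
  expect_true(all(diff(est3$bpm) >= -0.5))
  expect_true(all(est3$bpm >= 39 & est3$bpm <= 240))
  expect_error(estimate_bpm(x[1:100], fps = fps), "window longer")
})

test_that("shared invariants: constant input, scale invariance", {
  v_const <- matrix(rep(c(150, 100, 70), each = 1800), 1800, 3)
  tr_const <- make_plain_trace(v_const, fps)
  for (f in list(rppg_green, rppg_chrom, rppg_pos, rppg_lgi))
    expect_lte(sd(suppressWarnings(f(tr_const))$samples), 1e-9)
  expect_lte(sd(suppressWarnings(rppg_pbv(tr_const))$samples), 1e-9)
  # positive rescaling changes no BPM estimate
  tr <- get_noiseless_trace()
  tr_s <- tr
  tr_s$values <- tr$values * 3.7
  tr_s$pixel_samples <- lapply(tr$pixel_samples, function(m) m * 3.7)
  for (m in c("GREEN", "ICA", "CHROM", "POS", "SSR", "PBV", "LGI")) {
    f <- rppg_method_registry(m)[[1]]
    b1 <- suppressWarnings(f(tr)); b2 <- suppressWarnings(f(tr_s))
    expect_equal(estimate_bpm(b2)$bpm, estimate_bpm(b1)$bpm,
                 tolerance = 1e-9, label = m)
  }
  expect_error(rppg_method_registry("NOPE"), "unknown method")
})
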