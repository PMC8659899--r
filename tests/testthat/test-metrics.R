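test_that("MAE, RMSE, PCC: examples and brute-force agreement", {
  expect_equal(mae(c(70, 70), c(70, 70)), 0)
  expect_equal(mae(c(70, 70), c(72, 75)), 3.5)
  expect_equal(rmse(c(70, 70), c(72, 75)), sqrt(14.5))
  expect_equal(pcc(1:10, 2 * (1:10) + 5), 1.0)
  expect_equal(pcc(1:10, -(1:10)), -1.0)
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(50, 80, 10); b <- rnorm(50, 80, 10)
    expect_equal(mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
    expect_equal(rmse(a, b), oracle_rmse(a, b), tolerance = 1e-12)
    expect_equal(pcc(a, b), oracle_pcc(a, b), tolerance = 1e-12)
    expect_gte(rmse(a, b), mae(a, b))   # power-mean inequality
  }
  expect_error(mae(1:3, 1:4), "equal length")
  expect_error(pcc(rep(1, 5), 1:5), "zero variance")
})

test_that("rBS: spec examples and exclusion of missing PCC", {
  g <- data.frame(region_id = c("a", "b", "c"),
                  mae = c(2, 5, 10), rmse = c(3, 6, 12),
                  pcc = c(0.9, 0.5, 0.2))
  out <- rbs(g)
  expect_equal(out$rbs[1], (log(8 + exp(1)) + log(9 + exp(1))) * 0.9,
               tolerance = 1e-12)
  expect_equal(round(out$rbs[1], 4), 4.3498)
  # region attaining both maxima: rbs = 2 |pcc|
  expect_equal(out$rbs[3], 2 * 0.2, tolerance = 1e-12)
  # pcc = 0 -> rbs = 0
  g0 <- g; g0$pcc[2] <- 0
  expect_equal(rbs(g0)$rbs[2], 0)
  # missing pcc excluded with flag
  gna <- g; gna$pcc[2] <- NA
  outna <- rbs(gna)
  expect_true(is.na(outna$rbs[2]) && outna$excluded[2])
  expect_error(rbs(g[0, ]), "empty")
})

test_that("rBS invariants: monotonicity, shift invariance, bounds", {
  set.seed(41)
  for (i in 1:50) {
    maes <- runif(6, 0, 20); rmses <- runif(6, 0, 25)
    pccs <- runif(6, -1, 1)
    v <- oracle_rbs(maes, rmses, pccs)
    expect_true(all(v >= 0))
    # shifting all MAEs by a constant leaves rBS unchanged
    expect_equal(oracle_rbs(maes + 3.3, rmses, pccs), v, tolerance = 1e-12)
    # lower MAE (holding the max) -> no smaller rBS
    j <- which.min(maes)
    m2 <- maes; m2[j] <- m2[j] / 2
    expect_gte(oracle_rbs(m2, rmses, pccs)[j], v[j] - 1e-12)
    # larger |pcc| -> no smaller rBS
    p2 <- pccs; p2[j] <- sign(pccs[j] + 1e-9) * min(1, abs(pccs[j]) * 1.5)
    expect_gte(oracle_rbs(maes, rmses, p2)[j], v[j] - 1e-12)
  }
})

test_that("median_rank agrees with brute force and honors min-rank ties", {
  set.seed(51)
  for (i in 1:50) {
    tab <- random_metric_table(n_regions = sample(3:12, 1),
                               n_groups = sample(1:7, 1))
    rt <- rbs_table(tab)
    mr <- median_rank(rt)
    want <- oracle_median_rank(rt$region_id[!is.na(rt$rbs)],
                               rt$rbs[!is.na(rt$rbs)])
    expect_equal(mr$median_rbs, unname(want$median[mr$region_id]),
                 tolerance = 1e-12)
    expect_equal(mr$rank, unname(want$rank[mr$region_id]))
  }
  # total tie -> all rank 1
  tied <- data.frame(region_id = c("a", "b", "c"), rbs = c(2, 2, 2))
  expect_equal(median_rank(tied)$rank, c(1L, 1L, 1L))
})

test_that("top_bottom selections", {
  rk <- data.frame(region_id = letters[1:6],
                   median_rbs = c(5, 3, 6, 1, 2, 4))
  rk$rank <- rppgroi:::rank_descending_min_ties(rk$median_rbs)
  tb <- top_bottom(rk, 2)
  expect_equal(tb$top, c("c", "a"))
  expect_equal(tb$bottom, c("d", "e"))
  all6 <- top_bottom(rk, 6)
  expect_setequal(all6$top, letters[1:6])
  expect_setequal(all6$bottom, letters[1:6])
  expect_equal(top_bottom(rk, 1)$top, "c")
  expect_error(top_bottom(rk, 0), "positive")
  expect_error(top_bottom(rk, 7), "exceeds")
})

test_that("thickness/pixel correlation: perfect order and brute force", {
  # rank exactly the thickness order -> correlation 1
  th <- c(1000, 1200, 1400, 1600, 1800)
  expect_equal(thickness_pixel_correlation(1:5, th, 5:1)[["r_thickness_rank"]],
               1.00)
  set.seed(61)
  rk <- sample(1:10); th <- runif(10, 900, 2100); px <- rpois(10, 400)
  got <- thickness_pixel_correlation(rk, th, px, digits = NA)
  bf <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(got[["r_thickness_rank"]], bf(th, rk), tolerance = 1e-12)
  expect_equal(got[["r_pixels_rank"]], bf(px, rk), tolerance = 1e-12)
  expect_error(thickness_pixel_correlation(1:2, c(1, 2), c(3, 4)),
               "at least 3")
})
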