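test_that("rasterize_polygon: basic shapes and clipping", {
  sq <- rasterize_polygon(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                          c(20, 20))
  expect_equal(sq$pixel_count, 100L)
  # triangle fully outside the frame
  tri <- rasterize_polygon(rbind(c(30, 30), c(40, 30), c(35, 40)), c(20, 20))
  expect_true(tri$empty)
  expect_equal(tri$pixel_count, 0L)
  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1)), c(10, 10)),
               "at least 3 vertices")
})

test_that("rasterization equals the brute-force even-odd oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    w <- sample(8:64, 1); h <- sample(8:64, 1)
    verts <- cbind(runif(n, -5, w + 5), runif(n, -5, h + 5))
    got <- rasterize_polygon(verts, c(w, h))$pixels
    want <- oracle_rasterize(verts, c(w, h))
    ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(unname(ord(got)), unname(ord(want)), ignore_attr = TRUE)
  }
})

test_that("build_region_masks: canonical fixture is complete and disjoint", {
  lm <- canonical_landmarks(128, 128)
  masks <- build_region_masks(lm)
  expect_length(masks, 31L)
  expect_true(all(!vapply(masks, `[[`, TRUE, "empty")))
  allpix <- do.call(rbind, lapply(masks, `[[`, "pixels"))
  expect_equal(nrow(allpix), nrow(unique(allpix)))  # pairwise disjoint
  # scaling the fixture x2 scales pixel counts ~4x (base frame large
  # enough that rasterization discretization stays below the tolerance)
  masksA <- build_region_masks(canonical_landmarks(512, 512))
  masksB <- build_region_masks(canonical_landmarks(1024, 1024))
  ratio <- vapply(seq_along(masksA), function(i)
    masksB[[i]]$pixel_count / masksA[[i]]$pixel_count, 0)
  expect_true(all(abs(ratio - 4) / 4 <= 0.10))
  # degenerate: every landmark at one point -> 31 empty masks
  pts <- matrix(5, 468, 2)
  masks0 <- build_region_masks(landmark_set(pts, c(64, 64)))
  expect_true(all(vapply(masks0, `[[`, TRUE, "empty")))
  expect_error(landmark_set(matrix(0, 100, 2), c(64, 64)), "468")
})

test_that("extract_rgb_trace: means, holds, pixel retention", {
  # constant-color frames -> constant trace
  fr <- array(0, c(8, 8, 3, 4))
  fr[, , 1, ] <- 10; fr[, , 2, ] <- 20; fr[, , 3, ] <- 30
  mask <- rasterize_polygon(rbind(c(1, 1), c(6, 1), c(6, 6), c(1, 6)),
                            c(8, 8))
  tr <- extract_rgb_trace(fr, mask, fps = 10)
  expect_true(all(tr$values[, 1] == 10 & tr$values[, 2] == 20 &
                    tr$values[, 3] == 30))
  # two-pixel mask arithmetic mean
  fr2 <- array(0, c(4, 4, 3, 1))
  fr2[1, 1, , 1] <- c(0, 0, 0); fr2[2, 1, , 1] <- c(2, 4, 6)
  m2 <- rppgroi:::new_region_mask(rbind(c(0, 0), c(1, 0)), c(4, 4))
  tr2 <- extract_rgb_trace(list(fr2[, , , 1]), m2, fps = 1)
  expect_equal(tr2$values[1, ], c(1, 2, 3))
  # checkerboard vs brute-force mean; permutation invariance of pixel order
  set.seed(3)
  frc <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3, 2))
  mc <- rasterize_polygon(rbind(c(2, 1), c(13, 3), c(10, 14), c(1, 9)),
                          c(16, 16))
  trc <- extract_rgb_trace(frc, mc, fps = 2)
  for (t in 1:2) for (c in 1:3) {
    s <- 0
    for (i in seq_len(mc$pixel_count))
      s <- s + frc[mc$pixels[i, 1] + 1, mc$pixels[i, 2] + 1, c, t]
    expect_equal(trc$values[t, c], s / mc$pixel_count)
  }
  perm <- rppgroi:::new_region_mask(mc$pixels[sample(mc$pixel_count), ],
                                    c(16, 16))
  expect_equal(extract_rgb_trace(frc, perm, fps = 2)$values, trc$values)
  # empty-mask frames: previous-value hold, flagged
  masks <- list(mc, rppgroi:::new_region_mask(matrix(integer(), 0, 2),
                                              c(16, 16)))
  trh <- extract_rgb_trace(list(frc[, , , 1], frc[, , , 2]), masks, fps = 2)
  expect_equal(trh$values[2, ], trh$values[1, ])
  expect_equal(trh$held, c(FALSE, TRUE))
  expect_error(extract_rgb_trace(list(frc[, , , 1]),
                                 list(masks[[2]]), fps = 1), "empty")
  # retained pixel samples are bounded and drawn from the mask
  trp <- extract_rgb_trace(frc, mc, fps = 2, keep_pixels = TRUE,
                           max_pixels = 10)
  expect_length(trp$pixel_samples, 2L)
  expect_equal(nrow(trp$pixel_samples[[1]]), 10L)
})

test_that("combine_regions: unions and inclusion-exclusion", {
  lm <- canonical_landmarks(128, 128)
  masks <- build_region_masks(lm)
  top <- combine_regions(masks, c(27, 10, 3, 0, 28), label = "TOP5")
  expect_equal(top$pixel_count,
               sum(vapply(masks[c("27", "10", "3", "0", "28")],
                          `[[`, 0L, "pixel_count")))
  # idempotence
  self <- combine_regions(list(masks[["10"]], masks[["10"]]))
  expect_equal(sort(paste(self$pixels[, 1], self$pixels[, 2])),
               sort(paste(masks[["10"]]$pixels[, 1],
                          masks[["10"]]$pixels[, 2])))
  # overlap: 50 + 50 sharing 10 -> 90
  a <- rppgroi:::new_region_mask(cbind(0, 0:49), c(100, 100))
  b <- rppgroi:::new_region_mask(cbind(0, 40:89), c(100, 100))
  expect_equal(combine_regions(list(a, b))$pixel_count, 90L)
  expect_error(combine_regions(masks, region_ids = 99), "no masks")
})

test_that("skin_mask: bounds reject non-skin and recover the face", {
  blue <- array(0, c(8, 8, 3)); blue[, , 3] <- 255
  expect_true(skin_mask(blue)$empty)
  skin <- array(0, c(8, 8, 3))
  skin[, , 1] <- 153; skin[, , 2] <- 102; skin[, , 3] <- 68
  expect_equal(skin_mask(skin)$pixel_count, 64L)
  # generator fixture: mask within the face, >= 90% of face pixels
  sc <- render_scene(scene_config(frame_size = c(48L, 36L), duration = 4,
                                  seed = 3L))
  face <- do.call(rbind, lapply(sc$masks, `[[`, "pixels"))
  sm <- skin_mask(sc$frames[, , , 1])
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(sm$pixels) %in% key(face)))
  expect_gte(sm$pixel_count / nrow(face), 0.90)
})

test_that("landmark CSV provider and PGM export round-trip", {
  lm <- canonical_landmarks(64, 64)
  df <- data.frame(frame_index = 0L, point_index = 0:467,
                   x = lm$points[, 1], y = lm$points[, 2])
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  got <- read_landmarks_csv(path, c(64, 64))
  expect_length(got, 1L)
  expect_equal(got[[1]]$points, lm$points)
  pgm <- withr::local_tempfile(fileext = ".pgm")
  write_mask_pgm(build_region_masks(lm)[["24"]], pgm)
  expect_equal(readLines(pgm, n = 1), "P2")
})
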