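# Shared fixtures (built once per test run, cached) and independent
# brute-force oracles. Oracles deliberately use naive loops, not the
# package's vectorized code paths.

fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# ---- stated-world fixtures ----------------------------------------------

acceptance_scene_seeds <- function() 100L + 1:10

# the 10 mild-noise scenes of the end-to-end acceptance run, evaluated with
# POS and CHROM plus the combined masks (shared by several criteria)
get_acceptance_run <- function() with_cache("acc_run", {
  scenes <- lapply(acceptance_scene_seeds(), function(s)
    scene_config(seed = s))
  run_pipeline(run_manifest(scenes = scenes, methods = c("POS", "CHROM"),
                            combos = TRUE, seed = 1L))
})

# one noiseless 60 s / 30 fps scene; region 27 carries the strongest pulse
get_noiseless_scene <- function() with_cache("scene_none",
  render_scene(scene_config(noise = noise_preset("none"), seed = 7L)))

get_noiseless_trace <- function() with_cache("trace_none", {
  sc <- get_noiseless_scene()
  extract_rgb_trace(sc$frames, sc$masks[["27"]], sc$config$fps,
                    keep_pixels = TRUE)
})

# ramp ground truth of the default scene configuration, at window centers
scene_truth_bpm <- function(scene, window_centers) {
  70 + 25 * window_centers / scene$config$duration
}

# achromatic-flicker-only scene trace: identical channels, no pulse
get_flicker_trace <- function() with_cache("trace_flicker", {
  cfg <- scene_config(frame_size = c(32L, 32L), fps = 30, duration = 30,
                      regions = data.frame(region_id = 0L, x0 = 4, x1 = 28,
                                           y0 = 4, y1 = 28,
                                           thickness_um = 1200),
                      base_color = c(128, 128, 128),
                      amplitude_law = function(th) 0 * th,
                      noise = list(sensor_sd = 0, flicker_amp = 3,
                                   flicker_freq = 1.2, specular_amp = 0,
                                   jitter_px = 0L, quantization_step = 0),
                      pixel_amp_jitter = 0, seed = 5L)
  sc <- render_scene(cfg)
  extract_rgb_trace(sc$frames, sc$masks[[1]], cfg$fps)
})

make_plain_trace <- function(values, fps = 30) rgb_trace(values, fps)

# ---- brute-force oracles -------------------------------------------------

oracle_point_in_polygon <- function(px, py, xs, ys) {
  inside <- FALSE
  n <- length(xs)
  j <- n
  for (i in seq_len(n)) {
    if ((ys[j] > py) != (ys[i] > py)) {
      xint <- xs[j] + (py - ys[j]) * (xs[i] - xs[j]) / (ys[i] - ys[j])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(vertices, frame_size) {
  hits <- matrix(NA_integer_, frame_size[1] * frame_size[2], 2)
  k <- 0L
  for (row in 0:(frame_size[2] - 1)) for (col in 0:(frame_size[1] - 1)) {
    if (oracle_point_in_polygon(col + 0.5, row + 0.5,
                                vertices[, 1], vertices[, 2])) {
      k <- k + 1L
      hits[k, ] <- c(row, col)
    }
  }
  hits[seq_len(k), , drop = FALSE]
}

oracle_mae <- function(ref, est) {
  s <- 0
  for (i in seq_along(ref)) s <- s + abs(est[i] - ref[i])
  s / length(ref)
}

oracle_rmse <- function(ref, est) {
  s <- 0
  for (i in seq_along(ref)) s <- s + (est[i] - ref[i])^2
  sqrt(s / length(ref))
}

oracle_pcc <- function(ref, est) {
  mu <- mean(ref); mh <- mean(est)
  num <- sum((est - mh) * (ref - mu))
  num / sqrt(sum((est - mh)^2) * sum((ref - mu)^2))
}

oracle_rbs <- function(maes, rmses, pccs) {
  mm <- max(maes); mr <- max(rmses)
  (log(mm - maes + exp(1)) + log(mr - rmses + exp(1))) * abs(pccs)
}

oracle_median_rank <- function(region_ids, values) {
  meds <- sapply(split(values, region_ids), function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  })
  ord <- names(sort(meds, decreasing = TRUE))
  rk <- integer(length(meds)); names(rk) <- names(meds)
  for (nm in names(meds)) rk[nm] <- sum(meds > meds[nm]) + 1L
  list(median = meds, rank = rk)
}

random_metric_table <- function(n_regions, n_groups) {
  do.call(rbind, lapply(seq_len(n_groups), function(g)
    data.frame(dataset = "d", method = "m", video = paste0("v", g),
               region_id = as.character(seq_len(n_regions)),
               mae = runif(n_regions, 0, 20),
               rmse = runif(n_regions, 0, 25),
               pcc = runif(n_regions, -1, 1))))
}
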