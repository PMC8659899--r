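# Synthetic facial scenes with a planted blood-volume pulse.
#
# The generator states a simplified physical world: K disjoint skin regions
# whose pixel colors share one pulsatile diffuse component, with a
# region-specific amplitude that decreases with the region's combined skin
# thickness (thicker skin -> weaker diffuse pulse at the surface). On top of
# the pulse it adds the three confound classes that degrade real rPPG video:
# achromatic illumination flicker and specular fluctuation (identical in all
# channels, what CHROM/POS are built to cancel), per-pixel sensor noise, and
# codec-like quantization; optional whole-face mask jitter emulates small
# head motion. Eye regions carry no pulse (they are not skin).

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(code)
}

#' Inverse-thickness amplitude law
#'
#' The default mapping from combined skin thickness to relative pulsatile
#' amplitude: `a(thickness) = a_ref * t_ref / thickness`, i.e. amplitude
#' inversely proportional to relative total thickness. `a_ref` is the
#' fractional color modulation of the thinnest region.
#'
#' @param a_ref modulation fraction at the reference (thinnest) thickness.
#' @param t_ref reference thickness, micrometres.
#' @return function mapping thickness (µm) to amplitude.
#' @export
amplitude_law_inverse <- function(a_ref = 0.015, t_ref = 1030.28) {
  function(thickness) a_ref * t_ref / thickness
}

#' Exponential-decay amplitude law
#'
#' Alternative law `a(thickness) = a_ref * exp(-(thickness - t_ref)/scale)`.
#'
#' @inheritParams amplitude_law_inverse
#' @param scale decay scale, micrometres.
#' @return function mapping thickness (µm) to amplitude.
#' @export
amplitude_law_exp <- function(a_ref = 0.015, t_ref = 1030.28, scale = 700) {
  function(thickness) a_ref * exp(-(thickness - t_ref) / scale)
}

#' Noise presets
#'
#' `"none"`: all noise off (analytic checks). `"mild"`: the default stated
#' test condition -- sensor noise 1 intensity level per pixel, achromatic
#' flicker of 1.5 levels at 0.25 Hz plus a slow specular random walk of 1
#' level, integer quantization, no mask jitter.
#'
#' @param preset `"none"` or `"mild"`.
#' @return named list of noise parameters.
#' @export
noise_preset <- function(preset = c("mild", "none")) {
  preset <- match.arg(preset)
  switch(preset,
    none = list(sensor_sd = 0, flicker_amp = 0, flicker_freq = 0.25,
                specular_amp = 0, jitter_px = 0L, quantization_step = 0),
    mild = list(sensor_sd = 1.0, flicker_amp = 1.5, flicker_freq = 0.25,
                specular_amp = 1.0, jitter_px = 0L, quantization_step = 1))
}

default_scene_regions <- function(frame_size) {
  reg <- load_proposed_regions()
  lay <- as.data.frame(.region_layout)
  lay <- lay[order(lay$region_id), ]
  data.frame(region_id = lay$region_id,
             x0 = lay$x0 * frame_size[1], x1 = lay$x1 * frame_size[1],
             y0 = lay$y0 * frame_size[2], y1 = lay$y1 * frame_size[2],
             thickness_um = reg$thickness_um[match(lay$region_id,
                                                   reg$region_id)])
}

#' Synthetic scene configuration
#'
#' @param frame_size `c(width, height)` pixels.
#' @param fps frames per second.
#' @param duration seconds.
#' @param regions data.frame with `region_id`, rectangle bounds
#'   `x0, x1, y0, y1` (pixels) and `thickness_um` (`NA` = no pulse);
#'   default: the 31 proposed regions in the package's schematic layout
#'   with their published thicknesses.
#' @param base_color baseline skin color, `c(R, G, B)` 0--255.
#' @param coupling unit 3-vector of pulsatile channel weights
#'   (green-dominant default, the hemoglobin absorption signature).
#' @param amplitude_law function thickness (µm) -> relative amplitude.
#' @param hr_profile heart rate: a constant (BPM), or a function of time
#'   (s) returning BPM. Default (`NULL`): a slow ramp from 70 BPM at t = 0
#'   to 95 BPM at t = duration, so that correlation metrics are
#'   well-defined on the windowed heart-rate series.
#' @param noise list as from [noise_preset()].
#' @param pixel_amp_jitter per-pixel multiplicative spread of the planted
#'   amplitude (uniform, +/- this fraction; gives SSR spatial diversity).
#' @param seed integer; fixes the scene byte-for-byte.
#' @return a `scene_config` object.
#' @export
scene_config <- function(frame_size = c(64L, 48L), fps = 30, duration = 60,
                         regions = default_scene_regions(frame_size),
                         base_color = c(153, 102, 68),
                         coupling = c(0.33, 0.78, 0.53),
                         amplitude_law = amplitude_law_inverse(),
                         hr_profile = NULL,
                         noise = noise_preset("mild"),
                         pixel_amp_jitter = 0.15,
                         seed = 1L) {
  coupling <- coupling / sqrt(sum(coupling^2))
  if (is.null(hr_profile)) {
    dur <- duration
    hr_profile <- function(t) 70 + 25 * t / dur   # slow ramp 70 -> 95 BPM
  }
  hr_fun <- if (is.function(hr_profile)) hr_profile
            else function(t) rep(hr_profile[1], length(t))
  hr_chk <- hr_fun(seq(0, duration, length.out = 101))
  if (any(hr_chk < 40 | hr_chk > 180))
    stop("hr_profile must stay within [40, 180] BPM", call. = FALSE)
  if (fps < 2 * max(hr_chk) / 60)
    stop("fps below twice the maximum heart-rate frequency", call. = FALSE)
  # disjointness of region rectangles
  n <- nrow(regions)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (regions$x0[i] < regions$x1[j] && regions$x0[j] < regions$x1[i] &&
        regions$y0[i] < regions$y1[j] && regions$y0[j] < regions$y1[i])
      stop("overlapping region rectangles: ", regions$region_id[i], " and ",
           regions$region_id[j], call. = FALSE)
  }
  structure(list(frame_size = as.integer(frame_size), fps = fps,
                 duration = duration, regions = regions,
                 base_color = base_color, coupling = coupling,
                 amplitude_law = amplitude_law, hr_fun = hr_fun,
                 noise = noise, pixel_amp_jitter = pixel_amp_jitter,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a ground-truth blood-volume pulse
#'
#' Phase-continuous waveform: a fundamental at `hr(t)/60` Hz plus a second
#' harmonic at 30% amplitude.
#'
#' @param hr_profile constant BPM or function of time (s) returning BPM,
#'   within \[40, 180\].
#' @param fps sampling rate, Hz.
#' @param duration seconds.
#' @return list with `bvp` (length `fps * duration`), `hr` (instantaneous
#'   BPM per sample), `hr_per_s` (BPM at integer seconds), `t` (sample
#'   times, s), `fps`.
#' @export
make_bvp <- function(hr_profile, fps, duration) {
  hr_fun <- if (is.function(hr_profile)) hr_profile
            else function(t) rep(hr_profile[1], length(t))
  T_ <- round(fps * duration)
  t <- (seq_len(T_) - 1) / fps
  hr <- hr_fun(t)
  if (any(hr < 40 | hr > 180))
    stop("hr_profile must stay within [40, 180] BPM", call. = FALSE)
  phase <- 2 * pi * cumsum(hr / 60) / fps
  bvp <- sin(phase) + 0.3 * sin(2 * phase)
  list(bvp = bvp, hr = hr,
       hr_per_s = hr_fun(seq(0, floor(duration) - 1)),
       t = t, fps = fps)
}

#' Render a synthetic facial scene
#'
#' Per pixel in region r at frame t:
#' `color_c = base_c * (1 + m_p * a_r * bvp(t) * coupling_c)
#'  + flicker(t) + specular(t) + sensor noise`, then quantization and
#' clipping to 0--255. `a_r = amplitude_law(thickness_r)`; `m_p` is the
#' per-pixel amplitude jitter; flicker and specular terms are achromatic
#' (identical in R, G, B). Background pixels carry no pulse. The same seed
#' always reproduces the scene byte-for-byte; independent substreams drive
#' waveform-independent noise sources so toggling one does not shift the
#' others.
#'
#' @param config a [scene_config].
#' @return list with `frames` (`height x width x 3 x T` integer-valued
#'   array), `masks` (list of `region_mask`, one per region; per-frame list
#'   when jitter is active), `truth` (from [make_bvp()] plus
#'   `region_amplitudes`), `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  w <- config$frame_size[1]; h <- config$frame_size[2]
  fps <- config$fps
  T_ <- round(fps * config$duration)
  truth <- make_bvp(config$hr_fun, fps, config$duration)
  nz <- config$noise
  HW <- h * w

  # background: dim, bluish-gray (rejected by the skin mask)
  bg <- c(45, 45, 50)
  frames <- array(rep(rep(bg, each = HW), T_), c(h, w, 3, T_))

  # achromatic global terms
  flick <- if (nz$flicker_amp > 0)
    nz$flicker_amp * sin(2 * pi * nz$flicker_freq * truth$t) else numeric(T_)
  spec <- if (nz$specular_amp > 0) local_seed(
    substream_seed(config$seed, 2L), {
      s <- cumsum(rnorm(T_))
      s <- s - running_mean(s, max(3L, round(2 * fps)))  # slow wander, zero-mean
      nz$specular_amp * s / max(stats::sd(s), 1e-12)
    }) else numeric(T_)
  achrom <- flick + spec

  # whole-face mask jitter: bounded integer random walk
  jit <- matrix(0L, T_, 2)
  if (nz$jitter_px > 0) jit <- local_seed(
    substream_seed(config$seed, 3L), {
      steps <- matrix(sample(c(-1L, 0L, 1L), 2L * T_, replace = TRUE), T_, 2)
      j <- apply(steps, 2, cumsum)
      matrix(as.integer(pmax(pmin(j, nz$jitter_px), -nz$jitter_px)), T_, 2)
    })
  jittered <- any(jit != 0L)

  regs <- config$regions
  amps <- ifelse(is.na(regs$thickness_um), 0,
                 config$amplitude_law(regs$thickness_um))
  names(amps) <- as.character(regs$region_id)

  base_masks <- lapply(seq_len(nrow(regs)), function(i) {
    rasterize_polygon(rbind(c(regs$x0[i], regs$y0[i]),
                            c(regs$x1[i], regs$y0[i]),
                            c(regs$x1[i], regs$y1[i]),
                            c(regs$x0[i], regs$y1[i])),
                      c(w, h), region_id = as.integer(regs$region_id[i]))
  })
  names(base_masks) <- as.character(regs$region_id)

  for (i in seq_len(nrow(regs))) {
    m <- base_masks[[i]]
    if (m$empty) next
    npix <- m$pixel_count
    mp <- if (config$pixel_amp_jitter > 0) local_seed(
      substream_seed(config$seed, 100L + i),
      1 + stats::runif(npix, -config$pixel_amp_jitter,
                       config$pixel_amp_jitter)) else rep(1, npix)
    mod <- outer(mp * amps[i], truth$bvp)           # npix x T
    lin0 <- m$pixels[, 1] + 1L + h * m$pixels[, 2]  # channel-1 linear index
    for (c in 1:3) {
      idx <- as.vector(outer(lin0 + (c - 1L) * HW,
                             (seq_len(T_) - 1L) * 3L * HW, "+"))
      frames[idx] <- config$base_color[c] * (1 + config$coupling[c] * mod)
    }
  }

  if (any(achrom != 0))
    frames <- frames + rep(achrom, each = 3L * HW)
  if (nz$sensor_sd > 0)
    frames <- frames + local_seed(substream_seed(config$seed, 1L),
                                  rnorm(length(frames), 0, nz$sensor_sd))
  if (nz$quantization_step > 0)
    frames <- round(frames / nz$quantization_step) * nz$quantization_step
  frames[frames < 0] <- 0
  frames[frames > 255] <- 255

  masks <- if (jittered) {
    lapply(seq_len(T_), function(t) lapply(base_masks, function(m) {
      px <- m$pixels
      px[, 1] <- px[, 1] + jit[t, 1]; px[, 2] <- px[, 2] + jit[t, 2]
      keep <- px[, 1] >= 0 & px[, 1] < h & px[, 2] >= 0 & px[, 2] < w
      new_region_mask(px[keep, , drop = FALSE], c(w, h), m$region_id)
    }))
  } else base_masks

  truth$region_amplitudes <- amps
  list(frames = frames, masks = masks, truth = truth, config = config)
}

# ---- plain-text frame and ground-truth I/O (UBFC-style layout) ----------

write_ppm_frame <- function(frame, path) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  v <- as.integer(round(aperm(frame, c(3, 2, 1))))  # RGB interleaved, row-major
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(v, collapse = " "), con)
  invisible(path)
}

read_ppm_frame <- function(path) {
  txt <- scan(path, what = "", quiet = TRUE, comment.char = "#")
  if (txt[1] != "P3") stop("not an ASCII PPM file: ", path, call. = FALSE)
  w <- as.integer(txt[2]); h <- as.integer(txt[3])
  v <- as.numeric(txt[-(1:4)])
  aperm(array(v, c(3, w, h)), c(3, 2, 1))
}

#' Write a rendered scene in the UBFC-style on-disk layout
#'
#' One directory per synthetic subject: a lossless ASCII-PPM frame sequence
#' under `vid/`, a three-line ground-truth text file (pulse waveform, BPM
#' per second, timestamps), and a richer per-sample CSV
#' (`time, bvp, hr`). A `scene.json` records frame size, fps and the
#' planted region amplitudes.
#'
#' @param scene output of [render_scene()].
#' @param out_dir subject directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_ubfc_layout <- function(scene, out_dir) {
  dir.create(file.path(out_dir, "vid"), recursive = TRUE,
             showWarnings = FALSE)
  T_ <- dim(scene$frames)[4]
  for (t in seq_len(T_))
    write_ppm_frame(scene$frames[, , , t],
                    file.path(out_dir, "vid", sprintf("frame_%05d.ppm", t)))
  tr <- scene$truth
  gt <- c(paste(format(tr$bvp, digits = 8, trim = TRUE), collapse = " "),
          paste(format(tr$hr_per_s, digits = 8, trim = TRUE), collapse = " "),
          paste(format(tr$t, digits = 8, trim = TRUE), collapse = " "))
  writeLines(gt, file.path(out_dir, "ground_truth.txt"))
  utils::write.csv(data.frame(time = tr$t, bvp = tr$bvp, hr = tr$hr),
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(frame_size = scene$config$frame_size, fps = scene$config$fps,
         duration = scene$config$duration, seed = scene$config$seed,
         region_amplitudes = as.list(tr$region_amplitudes)),
    file.path(out_dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read one UBFC-style subject directory
#'
#' @param dir subject directory (as written by [write_ubfc_layout()], or
#'   any directory with a `vid/` PPM sequence and `ground_truth.txt`).
#' @param read_frames also load the frame sequence.
#' @return list with `truth` (`bvp`, `hr_per_s`, `t`) and, when requested,
#'   `frames` and `fps`.
#' @export
read_ubfc_subject <- function(dir, read_frames = TRUE) {
  gt_path <- file.path(dir, "ground_truth.txt")
  if (!file.exists(gt_path))
    stop("missing ground truth: ", gt_path, call. = FALSE)
  lines <- readLines(gt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L)
    stop("malformed ground-truth file (expected 3 lines): ", gt_path,
         call. = FALSE)
  parse_line <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  truth <- list(bvp = parse_line(lines[1]), hr_per_s = parse_line(lines[2]),
                t = parse_line(lines[3]))
  if (any(vapply(truth, function(v) any(is.na(v)), TRUE)))
    stop("non-numeric values in ground-truth file: ", gt_path, call. = FALSE)
  out <- list(truth = truth)
  if (read_frames) {
    files <- sort(list.files(file.path(dir, "vid"), pattern = "\\.ppm$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("no frames under ", file.path(dir, "vid"), call. = FALSE)
    fr1 <- read_ppm_frame(files[1])
    frames <- array(0, c(dim(fr1), length(files)))
    frames[, , , 1] <- fr1
    for (i in seq_along(files)[-1]) frames[, , , i] <- read_ppm_frame(files[i])
    out$frames <- frames
    out$fps <- if (length(truth$t) > 1)
      1 / stats::median(diff(truth$t)) else NA_real_
  }
  out
}

#' List subject directories of a UBFC-style dataset
#'
#' @param dataset_dir directory containing one subdirectory per subject.
#' @return character vector of subject directories.
#' @export
list_ubfc_subjects <- function(dataset_dir) {
  dirs <- list.dirs(dataset_dir, recursive = FALSE)
  dirs[file.exists(file.path(dirs, "ground_truth.txt"))]
}
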