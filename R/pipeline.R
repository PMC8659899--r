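# End-to-end orchestration: scenes/videos -> region masks -> RGB traces ->
# pulse extraction -> windowed BPM -> MAE/RMSE/PCC -> rBS -> ranking ->
# report tables. Deterministic for a fixed manifest.

#' Build a run manifest
#'
#' @param scenes list of [scene_config] objects (synthetic dataset), or
#'   `NULL` when `dataset_dir` is given.
#' @param dataset_dir UBFC-style dataset directory (one subject per
#'   subdirectory); requires `landmarks.csv` per subject unless masks can
#'   be derived from a packaged `scene.json` (synthetic subjects).
#' @param methods method names, see [rppg_method_registry()].
#' @param window_s,hop_s BPM estimation window and hop, seconds.
#' @param combos also evaluate the TOP-5 / BOT-5 combined masks and the
#'   whole-face skin-mask baseline (labels `"TOP5"`, `"BOT5"`,
#'   `"FACE_SKIN"`).
#' @param top_ids,bot_ids region ids of the combined masks; defaults are
#'   the published TOP-5 and BOT-5 sets.
#' @param dataset_label label stamped on the metric records.
#' @param seed integer master seed.
#' @return a `run_manifest` object.
#' @export
run_manifest <- function(scenes = NULL, dataset_dir = NULL,
                         methods = c("POS"), window_s = 10, hop_s = 1,
                         combos = FALSE,
                         top_ids = c(27, 10, 3, 0, 28),
                         bot_ids = c(15, 13, 12, 20, 19),
                         dataset_label = if (is.null(dataset_dir))
                           "synthetic" else basename(dataset_dir),
                         seed = 1L) {
  if (is.null(scenes) && is.null(dataset_dir))
    stop("provide scenes or dataset_dir", call. = FALSE)
  structure(list(scenes = scenes, dataset_dir = dataset_dir,
                 methods = toupper(methods), window_s = window_s,
                 hop_s = hop_s, combos = combos,
                 top_ids = top_ids, bot_ids = bot_ids,
                 dataset_label = dataset_label, seed = as.integer(seed),
                 version = as.character(utils::packageVersion("rppgroi"))),
            class = "run_manifest")
}

# Windowed ground-truth heart rate aligned with estimate_bpm's windows.
reference_bpm <- function(hr_samples, fps, n_samples, window_s, hop_s) {
  win <- round(window_s * fps)
  hop <- max(1L, round(hop_s * fps))
  starts <- seq(1L, n_samples - win + 1L, by = hop)
  vapply(starts, function(s) mean(hr_samples[s:(s + win - 1L)]), 0)
}

run_one_video <- function(frames, masks, truth, fps, manifest, video_label) {
  reg <- rppg_method_registry(manifest$methods)
  need_pixels <- "SSR" %in% manifest$methods
  T_ <- if (is.list(frames)) length(frames) else dim(frames)[4]
  records <- list()
  skips <- character()
  per_frame <- !inherits(masks[[1]], "region_mask")
  region_masks <- if (per_frame) masks[[1]] else masks
  pixel_counts <- vapply(region_masks, `[[`, 0L, "pixel_count")

  for (ri in seq_along(region_masks)) {
    rid <- as.character(region_masks[[ri]]$region_id)
    mk <- if (per_frame) lapply(masks, `[[`, ri) else region_masks[[ri]]
    trace <- tryCatch(
      extract_rgb_trace(frames, mk, fps, keep_pixels = need_pixels,
                        seed = manifest$seed),
      error = function(e) NULL)
    if (is.null(trace)) {
      skips <- c(skips, paste0(video_label, "/", rid, ": empty"))
      next
    }
    for (m in names(reg)) {
      rec <- tryCatch({
        bvp <- reg[[m]](trace)
        est <- estimate_bpm(bvp, manifest$window_s, manifest$hop_s)
        ref <- reference_bpm(truth$hr, fps, length(bvp$samples),
                             manifest$window_s, manifest$hop_s)
        metric_record(manifest$dataset_label, m, video_label, rid,
                      ref, est$bpm)
      }, error = function(e) {
        skips <<- c(skips, paste0(video_label, "/", rid, "/", m, ": ",
                                  conditionMessage(e)))
        NULL
      })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }

  combo_records <- list()
  if (isTRUE(manifest$combos)) {
    fr1 <- if (is.list(frames)) frames[[1]] else frames[, , , 1]
    combo_masks <- list(
      TOP5 = combine_regions(region_masks, manifest$top_ids, label = NA),
      BOT5 = combine_regions(region_masks, manifest$bot_ids, label = NA),
      FACE_SKIN = skin_mask(fr1))
    for (lab in names(combo_masks)) {
      cm <- combo_masks[[lab]]
      if (cm$empty) {
        skips <- c(skips, paste0(video_label, "/", lab, ": empty"))
        next
      }
      trace <- extract_rgb_trace(frames, cm, fps, keep_pixels = need_pixels,
                                 seed = manifest$seed)
      for (m in names(reg)) {
        rec <- tryCatch({
          bvp <- reg[[m]](trace)
          est <- estimate_bpm(bvp, manifest$window_s, manifest$hop_s)
          ref <- reference_bpm(truth$hr, fps, length(bvp$samples),
                               manifest$window_s, manifest$hop_s)
          metric_record(manifest$dataset_label, m, video_label, lab,
                        ref, est$bpm)
        }, error = function(e) NULL)
        if (!is.null(rec)) combo_records[[length(combo_records) + 1L]] <- rec
      }
    }
  }
  list(records = records, combo_records = combo_records, skips = skips,
       pixel_counts = pixel_counts)
}

#' Run the full ROI-assessment pipeline
#'
#' Executes every requested pulse-extraction method on every region of
#' every video, scores the regions, and ranks them by median rBS.
#'
#' @param manifest a [run_manifest].
#' @param out_dir optional output directory for tidy CSV tables, report
#'   renderings and the manifest snapshot.
#' @return list with `records` (per-region metric records), `rbs`
#'   (records with rBS), `ranking` (median rBS + rank per region),
#'   `combo_records`, `pixel_counts` (first video), `skips`,
#'   `manifest`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  all_rec <- list(); all_combo <- list(); all_skips <- character()
  pixel_counts <- NULL

  videos <- if (!is.null(manifest$scenes)) {
    lapply(seq_along(manifest$scenes), function(i)
      list(kind = "scene", i = i,
           label = sprintf("scene%02d", i)))
  } else {
    dirs <- list_ubfc_subjects(manifest$dataset_dir)
    if (length(dirs) == 0L)
      stop("no subjects found under ", manifest$dataset_dir, call. = FALSE)
    lapply(dirs, function(d) list(kind = "ubfc", dir = d,
                                  label = basename(d)))
  }

  for (v in videos) {
    res <- tryCatch({
      if (v$kind == "scene") {
        sc <- render_scene(manifest$scenes[[v$i]])
        run_one_video(sc$frames, sc$masks, sc$truth, sc$config$fps,
                      manifest, v$label)
      } else {
        sub <- read_ubfc_subject(v$dir, read_frames = TRUE)
        masks <- ubfc_subject_masks(v$dir, dim(sub$frames)[2],
                                    dim(sub$frames)[1])
        hr <- stats::approx(seq_along(sub$truth$hr_per_s) - 1,
                            sub$truth$hr_per_s, xout = sub$truth$t,
                            rule = 2)$y
        run_one_video(sub$frames, masks, list(hr = hr), sub$fps,
                      manifest, v$label)
      }
    }, error = function(e) {
      all_skips <<- c(all_skips, paste0(v$label, ": ", conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    all_rec <- c(all_rec, res$records)
    all_combo <- c(all_combo, res$combo_records)
    all_skips <- c(all_skips, res$skips)
    if (is.null(pixel_counts)) pixel_counts <- res$pixel_counts
  }
  if (length(all_rec) == 0L)
    stop("all videos were skipped; nothing to report", call. = FALSE)

  records <- do.call(rbind, all_rec)
  rbs_tab <- rbs_table(records)
  ranking <- median_rank(rbs_tab)
  out <- list(records = records, rbs = rbs_tab, ranking = ranking,
              combo_records = if (length(all_combo))
                do.call(rbind, all_combo) else NULL,
              pixel_counts = pixel_counts, skips = all_skips,
              manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

# Masks for a UBFC-style subject: landmarks.csv if present, otherwise the
# synthetic scene.json region rectangles.
ubfc_subject_masks <- function(dir, width, height) {
  lm_path <- file.path(dir, "landmarks.csv")
  sc_path <- file.path(dir, "scene.json")
  if (file.exists(lm_path)) {
    lms <- read_landmarks_csv(lm_path, c(width, height))
    if (length(lms) == 1L) build_region_masks(lms[[1]])
    else lapply(lms, build_region_masks)
  } else if (file.exists(sc_path)) {
    build_region_masks(canonical_landmarks(width, height))
  } else stop("no landmarks.csv or scene.json in ", dir, call. = FALSE)
}

write_run_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$records,
                   file.path(out_dir, "metric_records.csv"),
                   row.names = FALSE)
  utils::write.csv(results$rbs, file.path(out_dir, "rbs_records.csv"),
                   row.names = FALSE)
  utils::write.csv(results$ranking, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)
  if (!is.null(results$combo_records))
    utils::write.csv(results$combo_records,
                     file.path(out_dir, "combo_records.csv"),
                     row.names = FALSE)
  m <- results$manifest
  snap <- list(methods = m$methods, window_s = m$window_s, hop_s = m$hop_s,
               combos = m$combos, dataset_label = m$dataset_label,
               seed = m$seed, version = m$version,
               n_videos = if (!is.null(m$scenes)) length(m$scenes)
                          else length(list_ubfc_subjects(m$dataset_dir)),
               timestamp = format(Sys.time(), tz = "UTC"))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(snap, mpath, auto_unbox = TRUE)
  hash <- unname(tools::md5sum(mpath))
  for (f in c("metric_records.csv", "rbs_records.csv", "ranking.csv"))
    cat(sprintf("# manifest_md5,%s\n", hash),
        file = file.path(out_dir, paste0(f, ".meta")), append = FALSE)
  report_tables(results, out_dir)
  invisible(out_dir)
}

#' Render summary report tables
#'
#' Writes three summaries: the median-rBS ranking of the regions, the
#' thickness/pixel-count/rank table with its correlation footer, and (when
#' combined-mask records exist) the TOP-5 / Face+Skin / BOT-5 MAE and PCC
#' comparison per method. Each is written as CSV and as aligned text.
#'
#' @param results output of [run_pipeline()].
#' @param out_dir output directory.
#' @return invisible list of the three data.frames.
#' @export
report_tables <- function(results, out_dir) {
  if (is.null(results$ranking) || nrow(results$ranking) == 0L)
    stop("empty results; nothing to report", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t6 <- results$ranking
  t6$median_rbs <- round_half_up(t6$median_rbs, 2)
  utils::write.csv(t6, file.path(out_dir, "table_rank.csv"),
                   row.names = FALSE)

  reg <- load_proposed_regions()
  ids <- suppressWarnings(as.integer(t6$region_id))
  t7 <- data.frame(region_id = t6$region_id,
                   name = reg$name[match(ids, reg$region_id)],
                   thickness_um = reg$thickness_um[match(ids, reg$region_id)],
                   pixel_count = if (!is.null(results$pixel_counts))
                     unname(results$pixel_counts[t6$region_id])
                     else NA_integer_,
                   rank = t6$rank)
  corr <- tryCatch(
    thickness_pixel_correlation(t7$rank, t7$thickness_um, t7$pixel_count),
    error = function(e) c(r_thickness_rank = NA, r_pixels_rank = NA))
  t7_path <- file.path(out_dir, "table_thickness_pixels.csv")
  utils::write.csv(t7, t7_path, row.names = FALSE)
  cat(sprintf("# correlation(thickness, rank),%s\n",
              format(corr[["r_thickness_rank"]])),
      sprintf("# correlation(pixels, rank),%s\n",
              format(corr[["r_pixels_rank"]])),
      file = t7_path, append = TRUE, sep = "")

  t8 <- NULL
  if (!is.null(results$combo_records)) {
    cr <- results$combo_records
    agg <- stats::aggregate(cbind(mae, pcc) ~ method + region_id, data = cr,
                            FUN = stats::median)
    names(agg)[names(agg) == "region_id"] <- "roi"
    t8 <- agg[order(agg$method, agg$roi), ]
    utils::write.csv(t8, file.path(out_dir, "table_combos.csv"),
                     row.names = FALSE)
  }

  txt <- c("Region ranking by median rBS",
           utils::capture.output(print(t6, row.names = FALSE)),
           "", "Thickness / pixel count / rank",
           utils::capture.output(print(t7, row.names = FALSE)),
           sprintf("correlation(thickness, rank) = %s  (thickness-bearing regions)",
                   format(corr[["r_thickness_rank"]])),
           sprintf("correlation(pixels, rank)    = %s", format(corr[["r_pixels_rank"]])))
  if (!is.null(t8))
    txt <- c(txt, "", "Combined-mask comparison (median over videos)",
             utils::capture.output(print(t8, row.names = FALSE)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(list(rank = t6, thickness = t7, combos = t8))
}

#' Plot estimated pulse against ground truth
#'
#' Overlay of (scaled) extracted pulse waveforms on the planted
#' blood-volume pulse, for visual comparison of ROI quality.
#'
#' @param truth_bvp ground-truth pulse samples.
#' @param estimates named list of [bvp_signal] objects.
#' @param fps sampling rate of `truth_bvp`.
#' @param seconds time span to draw.
#' @param path optional output file (PNG via `grDevices::png`).
#' @return invisible NULL.
#' @export
plot_bvp_overlay <- function(truth_bvp, estimates, fps, seconds = 10,
                             path = NULL) {
  n <- min(length(truth_bvp), round(seconds * fps))
  t <- (seq_len(n) - 1) / fps
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 300 * length(estimates))
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(length(estimates), 1), mar = c(3, 4, 2, 1))
  for (nm in names(estimates)) {
    e <- estimates[[nm]]$samples[seq_len(n)]
    e <- e / max(stats::sd(e), 1e-12) * stats::sd(truth_bvp[seq_len(n)])
    graphics::plot(t, truth_bvp[seq_len(n)], type = "l", col = "darkgreen",
                   xlab = "time (s)", ylab = "pulse", main = nm)
    graphics::lines(t, e, col = "orange")
  }
  invisible(NULL)
}
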