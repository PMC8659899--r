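# ROI geometry: face-mesh landmarks -> 31 region masks -> per-region RGB
# traces. All image coordinates are 0-based with the origin at the top-left
# pixel corner; a pixel (row, col) has its center at (x, y) =
# (col + 0.5, row + 0.5). Polygons are filled by the even-odd rule over pixel
# centers, half-open at the image edges.
#
# The region -> landmark-polygon map is plain data
# (inst/extdata/region_polygons.json) over the package's SYNTHETIC canonical
# 468-point layout (see canonical_landmarks); real face-mesh deployments
# supply their own map and a landmark CSV.

# Normalized rectangle layout of the 31 regions on the schematic frontal
# face: region_id, x0, x1, y0, y1 (fractions of frame width/height).
# "Right" regions are the subject's right, i.e. the viewer's left.
.region_layout <- matrix(c(
   0, .38, .62, .05, .13,
   1, .13, .37, .05, .13,
   2, .63, .87, .05, .13,
   3, .38, .62, .14, .21,
   4, .16, .40, .24, .33,
   5, .60, .84, .24, .33,
   6, .02, .12, .22, .40,
   7, .88, .98, .22, .40,
   8, .13, .37, .14, .21,
   9, .63, .87, .14, .21,
  10, .42, .58, .22, .29,
  11, .44, .56, .30, .38,
  12, .36, .43, .34, .42,
  13, .57, .64, .34, .42,
  14, .36, .43, .43, .50,
  15, .57, .64, .43, .50,
  16, .44, .56, .39, .46,
  17, .44, .56, .47, .53,
  18, .46, .54, .59, .65,
  19, .33, .45, .66, .71,
  20, .55, .67, .66, .71,
  21, .44, .56, .54, .58,
  22, .33, .42, .52, .62,
  23, .58, .67, .52, .62,
  24, .42, .58, .76, .90,
  25, .30, .40, .73, .85,
  26, .60, .70, .73, .85,
  27, .13, .35, .35, .50,
  28, .65, .87, .35, .50,
  29, .12, .32, .52, .68,
  30, .68, .88, .52, .68), ncol = 5, byrow = TRUE,
  dimnames = list(NULL, c("region_id", "x0", "x1", "y0", "y1")))

#' Landmark set for one frame
#'
#' @param points numeric 468 x 2 matrix of (x, y) pixel coordinates.
#' @param frame_size integer `c(width, height)` in pixels.
#' @param frame_index frame number (0-based).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, frame_size, frame_index = 0L) {
  points <- as.matrix(points)
  if (nrow(points) != 468L || ncol(points) != 2L)
    stop("a landmark set must contain exactly 468 (x, y) points",
         call. = FALSE)
  if (any(!is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  structure(list(points = unname(points),
                 frame_size = as.integer(frame_size),
                 frame_index = as.integer(frame_index)),
            class = "landmark_set")
}

#' Synthetic canonical frontal-face landmarks
#'
#' Deterministically places 468 landmarks in a schematic frontal-face layout:
#' the first 124 indices are the corners of the 31 region rectangles (4 per
#' region, the topology referenced by the packaged polygon map); the
#' remaining indices lie on concentric face-oval ellipses. This is a
#' synthetic stand-in for a real face-mesh topology, sufficient to exercise
#' mask rasterization and the full pipeline.
#'
#' @param width,height frame size in pixels.
#' @return a [landmark_set].
#' @export
canonical_landmarks <- function(width = 128L, height = 128L) {
  pts <- matrix(0, 468L, 2L)
  for (i in seq_len(nrow(.region_layout))) {
    r <- .region_layout[i, ]
    x0 <- r[["x0"]] * width;  x1 <- r[["x1"]] * width
    y0 <- r[["y0"]] * height; y1 <- r[["y1"]] * height
    base <- 4L * r[["region_id"]]
    pts[base + 1:4, ] <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  }
  rest <- 125:468
  k <- seq_along(rest)
  ring <- 0.30 + 0.16 * ((k - 1) %% 4)           # 4 concentric ellipses
  th <- 2 * pi * (k - 1) / length(rest) * 4
  pts[rest, 1] <- width * (0.5 + ring * 0.48 * cos(th))
  pts[rest, 2] <- height * (0.5 + ring * 0.46 * sin(th))
  landmark_set(pts, c(width, height))
}

#' Rasterize a polygon into a pixel mask
#'
#' Fills the polygon interior by the even-odd rule evaluated at pixel
#' centers, clipped to the frame. Vertices are (x, y) in 0-based image
#' coordinates.
#'
#' @param vertices numeric n x 2 matrix (n >= 3) of polygon vertices.
#' @param frame_size integer `c(width, height)`.
#' @param region_id optional region label carried on the mask.
#' @return an object of class `region_mask`: list with `pixels` (m x 2
#'   integer matrix, columns `row`, `col`, 0-based), `pixel_count`,
#'   `frame_size`, `region_id`, `empty`.
#' @export
rasterize_polygon <- function(vertices, frame_size, region_id = NA_integer_) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  w <- as.integer(frame_size[1]); h <- as.integer(frame_size[2])
  xs <- vertices[, 1]; ys <- vertices[, 2]
  c0 <- max(0L, floor(min(xs) - 0.5)); c1 <- min(w - 1L, ceiling(max(xs)))
  r0 <- max(0L, floor(min(ys) - 0.5)); r1 <- min(h - 1L, ceiling(max(ys)))
  if (c1 < c0 || r1 < r0 || any(!is.finite(vertices)))
    return(new_region_mask(matrix(integer(), 0, 2), c(w, h), region_id))
  cols <- c0:c1; rows <- r0:r1
  px <- cols + 0.5; py <- rows + 0.5
  inside <- matrix(FALSE, length(rows), length(cols))
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    if (y1 != y2) {
      hit_rows <- which((y1 > py) != (y2 > py))
      if (length(hit_rows)) {
        xint <- x1 + (py[hit_rows] - y1) * (x2 - x1) / (y2 - y1)
        cross <- outer(xint, px, FUN = ">")   # center strictly left of edge
        inside[hit_rows, ] <- xor(inside[hit_rows, , drop = FALSE], cross)
      }
    }
    j <- i
  }
  idx <- which(inside, arr.ind = TRUE)
  pixels <- cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
  new_region_mask(pixels, c(w, h), region_id)
}

new_region_mask <- function(pixels, frame_size, region_id = NA_integer_) {
  pixels <- matrix(as.integer(pixels), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  structure(list(region_id = region_id,
                 pixels = pixels,
                 pixel_count = nrow(pixels),
                 frame_size = as.integer(frame_size),
                 empty = nrow(pixels) == 0L),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> region %s: %d px in %dx%d frame%s\n",
              as.character(x$region_id), x$pixel_count,
              x$frame_size[1], x$frame_size[2],
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

#' Convert a region mask to a logical matrix
#'
#' @param mask a `region_mask`.
#' @return logical `height x width` matrix (R's 1-based indexing).
#' @export
mask_matrix <- function(mask) {
  m <- matrix(FALSE, mask$frame_size[2], mask$frame_size[1])
  if (!mask$empty) m[mask$pixels + 1L] <- TRUE
  m
}

#' Load the packaged region -> landmark-polygon map
#'
#' @param path optional path to an alternative JSON map
#'   (`region_id -> ordered landmark indices`, 0-based).
#' @return named list of integer vectors.
#' @export
load_region_polygon_map <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("region_polygons.json")
  map <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(map, as.integer)
}

#' Build the 31 region masks for one frame
#'
#' Rasterizes every proposed region's landmark polygon for one landmark set.
#' Regions whose polygon degenerates or falls outside the frame yield empty
#' masks (flagged, not errors).
#'
#' @param landmarks a [landmark_set].
#' @param polygon_map map from `load_region_polygon_map()`.
#' @return named list of 31 `region_mask` objects, names `"0"`..`"30"`.
#' @export
build_region_masks <- function(landmarks,
                               polygon_map = load_region_polygon_map()) {
  if (!inherits(landmarks, "landmark_set"))
    stop("landmarks must be a landmark_set", call. = FALSE)
  out <- lapply(names(polygon_map), function(id) {
    verts <- landmarks$points[polygon_map[[id]] + 1L, , drop = FALSE]
    rasterize_polygon(verts, landmarks$frame_size,
                      region_id = as.integer(id))
  })
  names(out) <- names(polygon_map)
  out
}

#' Union of region masks
#'
#' @param masks list of `region_mask` objects from the same frame.
#' @param region_ids optional subset of region ids to combine (matched
#'   against each mask's `region_id`); default combines all given masks.
#' @param label region label for the combined mask.
#' @return a `region_mask` containing the set union of member pixels.
#' @export
combine_regions <- function(masks, region_ids = NULL, label = NA_integer_) {
  if (!is.null(region_ids)) {
    ids <- vapply(masks, function(m) as.integer(m$region_id), 1L)
    masks <- masks[ids %in% as.integer(region_ids)]
  }
  if (length(masks) == 0L)
    stop("no masks selected to combine", call. = FALSE)
  fs <- masks[[1]]$frame_size
  px <- unique(do.call(rbind, lapply(masks, `[[`, "pixels")))
  new_region_mask(px, fs, label)
}

default_skin_bounds <- function() {
  # chromaticity bounds (r = R/(R+G+B), g = G/(R+G+B)) plus brightness floor;
  # tuned to admit the synthetic generator's skin tones and reject saturated
  # non-skin colors.
  list(r = c(0.33, 0.60), g = c(0.22, 0.40), min_value = 60)
}

#' Chrominance-threshold skin mask
#'
#' Marks pixels whose normalized chromaticity falls inside configurable
#' skin-tone bounds. Used only for the whole-face "Face + Skin" baseline.
#'
#' @param frame numeric `height x width x 3` array (R, G, B, 0--255).
#' @param bounds list with elements `r`, `g` (each `c(lo, hi)` chromaticity
#'   bounds) and `min_value` (minimum R channel intensity).
#' @return a `region_mask` (possibly empty).
#' @export
skin_mask <- function(frame, bounds = default_skin_bounds()) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frame must be a height x width x 3 array", call. = FALSE)
  R <- frame[, , 1]; G <- frame[, , 2]; B <- frame[, , 3]
  s <- R + G + B
  s[s <= 0] <- NA
  r <- R / s; g <- G / s
  keep <- !is.na(s) &
    r >= bounds$r[1] & r <= bounds$r[2] &
    g >= bounds$g[1] & g <= bounds$g[2] &
    R >= bounds$min_value & R > B
  idx <- which(keep, arr.ind = TRUE)
  new_region_mask(cbind(idx[, 1] - 1L, idx[, 2] - 1L),
                  c(ncol(R), nrow(R)), region_id = NA_integer_)
}

#' Extract a per-region mean RGB trace from a frame sequence
#'
#' Per frame, the spatial mean of each color channel over the mask. Frames
#' with an empty mask are filled by previous-value hold and flagged in the
#' `held` attribute. With `keep_pixels = TRUE` a uniformly subsampled matrix
#' of per-pixel colors is retained per frame (needed by the SSR method),
#' bounded at `max_pixels` pixels.
#'
#' @param frames `height x width x 3 x T` numeric array, or a list of
#'   `height x width x 3` arrays.
#' @param masks one `region_mask` (applied to every frame) or a list of
#'   per-frame masks.
#' @param fps frames per second.
#' @param keep_pixels retain per-frame pixel samples for SSR.
#' @param max_pixels subsampling bound for retained pixels.
#' @param seed seed for the pixel subsample.
#' @return an `rgb_trace`: list with `values` (T x 3 matrix, R/G/B), `fps`,
#'   `region_id`, `pixel_samples` (list or NULL), `held` (logical T).
#' @export
extract_rgb_trace <- function(frames, masks, fps, keep_pixels = FALSE,
                              max_pixels = 2000L, seed = 1L) {
  if (is.list(frames)) {
    T_ <- length(frames)
    get_frame <- function(t) frames[[t]]
  } else {
    stopifnot(length(dim(frames)) == 4L)
    T_ <- dim(frames)[4]
    get_frame <- function(t) frames[, , , t, drop = TRUE]
  }
  static <- inherits(masks, "region_mask")
  get_mask <- if (static) function(t) masks else function(t) masks[[t]]
  if (!static && length(masks) != T_)
    stop("need one mask per frame", call. = FALSE)
  if (all(vapply(seq_len(T_), function(t) get_mask(t)$empty, TRUE)))
    stop("all masks are empty; cannot extract a trace", call. = FALSE)

  # fast path: static mask over a contiguous array (the common case in the
  # pipeline) -- one gather per channel instead of a per-frame loop
  if (static && !is.list(frames) && !masks$empty) {
    h <- dim(frames)[1]; HW <- h * dim(frames)[2]
    lin0 <- masks$pixels[, 1] + 1L + h * masks$pixels[, 2]
    n <- length(lin0)
    frame_off <- (seq_len(T_) - 1L) * 3L * HW
    values <- matrix(NA_real_, T_, 3)
    pix_chan <- vector("list", 3)
    for (c in 1:3) {
      # flatten: a matrix index into a 4-D array would be misread as
      # coordinate rows when its column count matches the array rank
      M <- frames[as.vector(outer(lin0 + (c - 1L) * HW, frame_off, "+"))]
      dim(M) <- c(n, T_)
      values[, c] <- colMeans(M)
      if (keep_pixels) pix_chan[[c]] <- M
    }
    samples <- NULL
    if (keep_pixels) {
      sub_idx <- if (n > max_pixels) local_seed(seed, sort(sample.int(n, max_pixels)))
                 else seq_len(n)
      samples <- lapply(seq_len(T_), function(t)
        cbind(pix_chan[[1]][sub_idx, t], pix_chan[[2]][sub_idx, t],
              pix_chan[[3]][sub_idx, t]))
    }
    return(rgb_trace(values, fps, region_id = masks$region_id,
                     pixel_samples = samples, held = logical(T_)))
  }

  values <- matrix(NA_real_, T_, 3)
  held <- logical(T_)
  samples <- if (keep_pixels) vector("list", T_) else NULL
  sub_idx <- NULL
  for (t in seq_len(T_)) {
    m <- get_mask(t)
    if (m$empty) {
      held[t] <- TRUE
      next
    }
    fr <- get_frame(t)
    h <- dim(fr)[1]
    lin <- m$pixels[, 1] + 1L + h * m$pixels[, 2]  # 1-based linear index
    n <- length(lin)
    pix <- cbind(fr[, , 1][lin], fr[, , 2][lin], fr[, , 3][lin])
    values[t, ] <- colMeans(pix)
    if (keep_pixels) {
      if (is.null(sub_idx)) {
        if (n > max_pixels) {
          old <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
          set.seed(seed)
          sub_idx <- sort(sample.int(n, max_pixels))
          if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
        } else sub_idx <- seq_len(n)
      }
      keep <- sub_idx[sub_idx <= n]
      samples[[t]] <- pix[keep, , drop = FALSE]
    }
  }
  # previous-value hold (and first-valid backfill for a leading gap)
  first_ok <- which(!held)[1]
  if (first_ok > 1L) values[seq_len(first_ok - 1L), ] <-
      matrix(values[first_ok, ], first_ok - 1L, 3, byrow = TRUE)
  for (t in seq_len(T_)[-1]) if (held[t] && t > first_ok) {
    values[t, ] <- values[t - 1L, ]
    if (keep_pixels) samples[[t]] <- samples[[t - 1L]]
  }
  if (keep_pixels && first_ok > 1L)
    for (t in seq_len(first_ok - 1L)) samples[[t]] <- samples[[first_ok]]
  rgb_trace(values, fps, region_id = get_mask(first_ok)$region_id,
            pixel_samples = samples, held = held)
}

#' Construct an RGB trace object
#'
#' @param values T x 3 numeric matrix of mean R, G, B per frame (0--255).
#' @param fps frames per second (> 0).
#' @param region_id optional region label.
#' @param pixel_samples optional list of per-frame pixel-color matrices.
#' @param held optional logical vector flagging previous-value-hold frames.
#' @return an object of class `rgb_trace`.
#' @export
rgb_trace <- function(values, fps, region_id = NA_integer_,
                      pixel_samples = NULL, held = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 3L || nrow(values) < 1L || any(!is.finite(values)))
    stop("trace values must be a finite T x 3 matrix", call. = FALSE)
  stopifnot_scalar_number(fps, "fps")
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  structure(list(values = unname(values), fps = fps,
                 region_id = region_id,
                 pixel_samples = pixel_samples,
                 held = held %||% logical(nrow(values))),
            class = "rgb_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-frame landmarks from CSV
#'
#' File-based landmark provider: a CSV with columns `frame_index`,
#' `point_index`, `x`, `y` (0-based indices) yields one [landmark_set] per
#' frame, so the pipeline never needs a face-tracking dependency.
#'
#' @param path CSV file path.
#' @param frame_size integer `c(width, height)`.
#' @return list of `landmark_set`, ordered by frame index.
#' @export
read_landmarks_csv <- function(path, frame_size) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "point_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(sort(unique(df$frame_index)), function(fi) {
    sub <- df[df$frame_index == fi, ]
    sub <- sub[order(sub$point_index), ]
    landmark_set(cbind(sub$x, sub$y), frame_size, fi)
  })
}

#' Export a mask as an ASCII PGM image
#'
#' Plain-text portable graymap (P2) rendering of one region mask for visual
#' inspection without binary image dependencies.
#'
#' @param mask a `region_mask`.
#' @param path output file path (.pgm).
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  m <- mask_matrix(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  apply(m, 1, function(row)
    writeLines(paste(ifelse(row, 255L, 0L), collapse = " "), con))
  invisible(path)
}
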