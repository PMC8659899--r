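# Region-quality metrics. A per-(dataset, method, video, region) record
# carries MAE, RMSE and PCC between the windowed heart-rate estimate and the
# ground truth; the composite relative BVP-similarity score
#
#   rBS = (ln(max(MAE) - MAE + e) + ln(max(RMSE) - RMSE + e)) * |PCC|
#
# compares regions within one (dataset, method, video) group (the maxima are
# taken over that group). Logs are natural, so the region attaining both
# maxima scores exactly 2|PCC|. Regions are ranked by the median rBS over
# all groups, descending, ties sharing the minimum rank.

check_pair <- function(reference, estimate) {
  if (length(reference) != length(estimate))
    stop("reference and estimate must have equal length", call. = FALSE)
  if (length(reference) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(reference)) || any(!is.finite(estimate)))
    stop("signals must be finite", call. = FALSE)
}

#' Mean absolute error
#' @param reference ground-truth series.
#' @param estimate estimated series, same length.
#' @return mean of `|estimate - reference|`.
#' @export
mae <- function(reference, estimate) {
  check_pair(reference, estimate)
  mean(abs(estimate - reference))
}

#' Root mean square error
#' @inheritParams mae
#' @return square root of the mean squared difference.
#' @export
rmse <- function(reference, estimate) {
  check_pair(reference, estimate)
  sqrt(mean((estimate - reference)^2))
}

#' Pearson correlation coefficient
#' @inheritParams mae
#' @return correlation in `[-1, 1]`.
#' @export
pcc <- function(reference, estimate) {
  check_pair(reference, estimate)
  if (stats::sd(reference) == 0 || stats::sd(estimate) == 0)
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  stats::cor(reference, estimate)
}

#' Build one metric record
#'
#' @param dataset,method,video labels.
#' @param region_id region identifier (integer or character label such as
#'   `"TOP5"`).
#' @param reference,estimate aligned series (windowed heart rate, or pulse
#'   waveforms for waveform-level comparison).
#' @return one-row data.frame with `mae`, `rmse`, `pcc` (`pcc` is `NA` when
#'   undefined; the record is then excluded from rBS with a flag).
#' @export
metric_record <- function(dataset, method, video, region_id,
                          reference, estimate) {
  p <- tryCatch(pcc(reference, estimate), error = function(e) NA_real_)
  data.frame(dataset = dataset, method = method, video = video,
             region_id = as.character(region_id),
             mae = mae(reference, estimate),
             rmse = rmse(reference, estimate),
             pcc = p,
             stringsAsFactors = FALSE)
}

#' rBS scores for one group of regions
#'
#' Computes the composite score for every region in one
#' (dataset, method, video) group. Records with missing PCC are excluded
#' (returned with `rbs = NA` and `excluded = TRUE`).
#'
#' @param group data.frame of metric records sharing one group, with columns
#'   `region_id`, `mae`, `rmse`, `pcc`.
#' @return `group` with columns `rbs` and `excluded` appended.
#' @export
rbs <- function(group) {
  if (nrow(group) == 0L) stop("empty metric group", call. = FALSE)
  ok <- !is.na(group$pcc)
  if (!any(ok)) stop("no usable PCC in group", call. = FALSE)
  max_mae <- max(group$mae[ok])
  max_rmse <- max(group$rmse[ok])
  out <- rep(NA_real_, nrow(group))
  out[ok] <- (log(max_mae - group$mae[ok] + exp(1)) +
                log(max_rmse - group$rmse[ok] + exp(1))) * abs(group$pcc[ok])
  group$rbs <- out
  group$excluded <- !ok
  group
}

#' rBS table over many groups
#'
#' Applies [rbs()] within every (dataset, method, video) group of a tidy
#' metric-record table.
#'
#' @param records data.frame of metric records.
#' @return the records with `rbs`/`excluded` columns, class `rbs_table`.
#' @export
rbs_table <- function(records) {
  key <- interaction(records$dataset, records$method, records$video,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), rbs))
  rownames(out) <- NULL
  class(out) <- c("rbs_table", class(out))
  out
}

#' Median rBS and rank per region
#'
#' Medians are taken per region over all (dataset, method, video) groups;
#' regions are ranked by median, descending, ties sharing the minimum
#' (best) rank. Regions with no usable rBS values are dropped with a
#' warning.
#'
#' @param table an `rbs_table` (or any data.frame with `region_id`, `rbs`).
#' @return data.frame with `region_id`, `median_rbs`, `rank`, sorted by
#'   rank.
#' @export
median_rank <- function(table) {
  vals <- split(table$rbs[!is.na(table$rbs)],
                table$region_id[!is.na(table$rbs)])
  if (length(vals) == 0L) stop("no usable rBS values", call. = FALSE)
  dropped <- setdiff(unique(table$region_id), names(vals))
  if (length(dropped))
    warning("regions with no usable rBS excluded from ranking: ",
            paste(dropped, collapse = ", "))
  med <- vapply(vals, stats::median, 0)
  out <- data.frame(region_id = names(med), median_rbs = unname(med),
                    stringsAsFactors = FALSE)
  out$rank <- rank_descending_min_ties(out$median_rbs)
  out[order(out$rank, out$region_id), , drop = FALSE]
}

# Descending ranks with ties sharing the minimum rank (1 = largest value).
rank_descending_min_ties <- function(x) {
  as.integer(rank(-x, ties.method = "min"))
}

#' TOP-k and BOT-k regions of a ranking
#'
#' The table is put in one deterministic order -- median rBS descending,
#' ties broken by ascending region id -- and the first and last `k` rows
#' are taken. With tied medians the k-th-from-worst region is otherwise
#' ambiguous; this single-ordering rule reproduces the published TOP-5 /
#' BOT-5 selection.
#'
#' @param ranking data.frame from [median_rank()] (columns `region_id`,
#'   `median_rbs`, `rank`).
#' @param k number of regions on each end.
#' @return list with `top` and `bottom` region-id vectors, each ordered
#'   best-first / worst-first.
#' @export
top_bottom <- function(ranking, k = 5L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(ranking))
    stop("k exceeds the number of ranked regions", call. = FALSE)
  ids <- ranking$region_id
  num <- suppressWarnings(as.numeric(ids))
  id_ord <- if (!any(is.na(num))) num else ids
  ord <- order(-ranking$median_rbs, id_ord)
  bottom_rows <- utils::tail(ord, k)
  # worst-first presentation keeps the same tie convention (ascending id)
  bottom_rows <- bottom_rows[order(ranking$median_rbs[bottom_rows],
                                   id_ord[bottom_rows])]
  list(top = ids[ord[seq_len(k)]],
       bottom = ids[bottom_rows])
}

#' Correlation of rBS rank with skin thickness and region size
#'
#' Pearson correlation of the per-region rank with (a) combined skin
#' thickness, over the regions that have a thickness (the eye regions do
#' not), and (b) pixel count, over all regions.
#'
#' @param ranks integer ranks aligned by region.
#' @param thickness thickness in micrometres (`NA` allowed).
#' @param pixel_counts region pixel counts.
#' @param digits decimal places of the reported coefficients (`NA` for full
#'   precision).
#' @return named numeric `c(r_thickness_rank, r_pixels_rank)`.
#' @export
thickness_pixel_correlation <- function(ranks, thickness, pixel_counts,
                                        digits = 2) {
  stopifnot(length(ranks) == length(thickness),
            length(ranks) == length(pixel_counts))
  ok <- !is.na(thickness)
  if (sum(ok) < 3L || length(ranks) < 3L)
    stop("need at least 3 usable regions", call. = FALSE)
  out <- c(r_thickness_rank = stats::cor(thickness[ok], ranks[ok]),
           r_pixels_rank = stats::cor(pixel_counts, ranks))
  if (!is.na(digits)) out <- round_half_up(out, digits)
  out
}
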