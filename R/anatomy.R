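# Facial skin-thickness tables and the 31-region anatomical ROI set.
#
# The package carries two static tables measured on cadaveric facial skin:
# 39 anatomical sites with mean epidermal and dermal thickness (micrometres),
# and the 31 evaluation regions derived from them (scalp/ear/neck sites
# dropped, periocular sites merged into one eye region per side, symmetric
# folds split into left/right). Relative-thickness ratios normalize each
# thickness by the thinnest site in its category.

#' Relative skin-thickness ratios
#'
#' Computes the relative epidermal (eRT), dermal (dRT) and total (RT)
#' thickness ratios for one site: each thickness divided by the corresponding
#' minimum over the full 39-site table.
#'
#' @param epi epidermal thickness, micrometres (> 0).
#' @param derm dermal thickness, micrometres (> 0).
#' @param min_epi minimum epidermal thickness over all sites.
#' @param min_derm minimum dermal thickness over all sites.
#' @param min_total minimum combined (epidermal + dermal) thickness.
#' @param digits decimal places for the returned display ratios; use
#'   `digits = NA` for full precision.
#' @return named numeric vector `c(eRT, dRT, RT)`.
#' @examples
#' relative_thickness(44.70, 1200.93, 29.57, 758.85, 799.16)
#' @export
relative_thickness <- function(epi, derm, min_epi, min_derm, min_total,
                               digits = 2) {
  vals <- c(epi = epi, derm = derm, min_epi = min_epi,
            min_derm = min_derm, min_total = min_total)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thickness inputs must be finite and > 0", call. = FALSE)
  out <- c(eRT = epi / min_epi,
           dRT = derm / min_derm,
           RT  = (epi + derm) / min_total)
  if (!is.na(digits)) out <- round_half_up(out, digits)
  out
}

#' Load the 39-site facial skin-thickness table
#'
#' Returns the packaged cadaveric thickness table with relative-thickness
#' ratios recomputed from the raw values at full precision. The ratio columns
#' as printed in the source report (which contain a handful of typographic
#' errors) are retained as `printed_eRT`/`printed_dRT`/`printed_RT`.
#'
#' @return a data.frame with one row per anatomical site: `site_id`, `name`,
#'   `epi_um`, `derm_um`, `total_um`, `eRT`, `dRT`, `RT` and the `printed_*`
#'   reference columns.
#' @export
load_anatomy_table <- function() {
  tab <- utils::read.csv(pkg_extdata("anatomy_sites.csv"),
                         stringsAsFactors = FALSE)
  need <- c("site_id", "name", "epi_um", "derm_um")
  if (!all(need %in% names(tab)) || nrow(tab) != 39L ||
      any(!is.finite(tab$epi_um)) || any(!is.finite(tab$derm_um)) ||
      any(tab$epi_um <= 0) || any(tab$derm_um <= 0))
    stop("packaged anatomy table failed integrity checks", call. = FALSE)
  tab$total_um <- tab$epi_um + tab$derm_um
  tab$eRT <- tab$epi_um / min(tab$epi_um)
  tab$dRT <- tab$derm_um / min(tab$derm_um)
  tab$RT  <- tab$total_um / min(tab$total_um)
  tab
}

#' Load the 31 proposed evaluation regions
#'
#' Returns the 31-region ROI table: the combined skin thickness as printed in
#' the source table, the mapped 39-site source site(s), laterality, and a
#' recomputed thickness (epidermal + dermal sum of the named source site).
#' For three nasal/philtrum regions (16--18) the printed thickness does not
#' match the named site's sum; these rows carry `thickness_mismatch = TRUE`
#' and both values are exposed. The two eye regions (4, 5) have no thickness
#' (`NA`).
#'
#' @return a data.frame with one row per region: `region_id`, `name`,
#'   `thickness_um` (printed), `recomputed_thickness_um`, `source_sites`
#'   (semicolon-separated site ids), `laterality`, `thickness_mismatch`.
#' @export
load_proposed_regions <- function() {
  reg <- utils::read.csv(pkg_extdata("proposed_regions.csv"),
                         stringsAsFactors = FALSE)
  if (nrow(reg) != 31L)
    stop("packaged region table failed integrity checks", call. = FALSE)
  sites <- load_anatomy_table()
  first_site <- as.integer(vapply(strsplit(reg$source_sites, ";"),
                                  `[[`, "", 1L))
  reg$recomputed_thickness_um <- ifelse(
    is.na(reg$thickness_um), NA_real_,
    sites$total_um[match(first_site, sites$site_id)])
  reg$thickness_mismatch <- !is.na(reg$thickness_um) &
    abs(reg$thickness_um - reg$recomputed_thickness_um) > 0.02
  reg
}

#' Combined skin thickness of a proposed region
#'
#' @param region_id integer in 0..30.
#' @param recomputed if `TRUE`, return the thickness recomputed from the
#'   mapped 39-site table instead of the printed value.
#' @return thickness in micrometres, or `NA` for the eye regions (4, 5).
#' @examples
#' proposed_region_thickness(10) # Glabella
#' @export
proposed_region_thickness <- function(region_id, recomputed = FALSE) {
  reg <- load_proposed_regions()
  i <- match(as.integer(region_id), reg$region_id)
  if (any(is.na(i)))
    stop("unknown region_id: ",
         paste(region_id[is.na(i)], collapse = ", "), call. = FALSE)
  if (recomputed) reg$recomputed_thickness_um[i] else reg$thickness_um[i]
}

#' Published per-region rBS medians, ranks and pixel counts
#'
#' The published evaluation of the 31 regions on the two real datasets:
#' per-region median rBS, its rank (1 = best, ties share the minimum rank)
#' and the region's pixel count on the reference face. These are inputs for
#' the in-paper consistency checks and for `thickness_pixel_correlation()`;
#' the package does not claim to re-derive them without the real datasets.
#'
#' @return data.frame with `region_id`, `median_rbs`, `rank`, `pixel_count`.
#' @export
load_published_region_stats <- function() {
  tab <- utils::read.csv(pkg_extdata("published_region_stats.csv"),
                         stringsAsFactors = FALSE)
  if (nrow(tab) != 31L)
    stop("packaged region statistics failed integrity checks", call. = FALSE)
  tab
}
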