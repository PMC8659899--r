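#' @keywords internal
"_PACKAGE"

# Shared small helpers. Nothing here is exported.

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rppgroi")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' Round half away from zero (report-table convention)
#'
#' Base R `round()` rounds half to even; printed report tables use the
#' conventional half-up rule, so 1.565 displays as 1.57.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite number", call. = FALSE)
}

# Derive independent substream seeds from one user seed so that toggling one
# randomized component does not shift the draws of another. Kept below 2^31.
substream_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + stream * 7919L
}
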