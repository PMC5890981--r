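#' Fragment-size to CAG-repeat sizing calibration
#'
#' The CAG tract is PCR-amplified with constant 5' and 3' flanking sequence, so
#' the repeat number is an affine function of the sized PCR product:
#' \deqn{(CAG)_n = \frac{\mathrm{size}_{bp} - \mathrm{offset}}{\mathrm{bp\ per\ repeat}}
#'   \times \mathrm{slope} + \mathrm{intercept}}
#' The defaults encode the calibration used for R6/2 transgene sizing on
#' capillary gels: a 122 bp non-repeat flank, 3 bp per CAG unit, and an
#' empirical mobility correction (slope 1.0425, intercept 1.2088) for
#' CAG-repeat DNA running anomalously in the sizing matrix.
#'
#' @param offset_bp Length of the non-repeat flank in bp (default 122).
#' @param bp_per_repeat Base pairs per repeat unit (default 3); must be > 0.
#' @param slope Mobility-correction slope (default 1.0425); must be > 0.
#' @param intercept Mobility-correction intercept (default 1.2088).
#'
#' @return A `cag_calibration` object (a named list).
#' @examples
#' calib <- cag_calibration()
#' bp_to_cag(122, calib)  # 1.2088: pure-flank fragment
#' @export
cag_calibration <- function(offset_bp = 122, bp_per_repeat = 3,
                            slope = 1.0425, intercept = 1.2088) {
  stopifnot(is.numeric(offset_bp), is.numeric(bp_per_repeat),
            is.numeric(slope), is.numeric(intercept))
  if (bp_per_repeat <= 0) stop("`bp_per_repeat` must be > 0", call. = FALSE)
  if (slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  structure(
    list(offset_bp = offset_bp, bp_per_repeat = bp_per_repeat,
         slope = slope, intercept = intercept),
    class = "cag_calibration"
  )
}

#' @export
print.cag_calibration <- function(x, ...) {
  cat(sprintf(
    "<cag_calibration> (CAG)n = (size_bp - %g)/%g * %g + %g\n",
    x$offset_bp, x$bp_per_repeat, x$slope, x$intercept))
  invisible(x)
}

#' Convert PCR fragment size (bp) to CAG repeat number
#'
#' Strictly increasing affine map; `cag_to_bp()` is its exact inverse.
#' Fragments shorter than the flank are physically impossible for a genuine
#' repeat amplicon; with `strict = TRUE` they raise a warning but the value is
#' still returned (the map is defined on all positive sizes).
#'
#' @param size_bp Numeric vector of fragment sizes in bp; must be > 0.
#' @param calib A [cag_calibration()].
#' @param strict Warn on sizes at or below the flank offset.
#' @return Numeric vector of (possibly non-integral) CAG repeat numbers.
#' @examples
#' bp_to_cag(c(122, 125))       # 1.2088, 2.2513
#' cag_to_bp(bp_to_cag(852.33)) # 852.33
#' @export
bp_to_cag <- function(size_bp, calib = cag_calibration(), strict = FALSE) {
  stopifnot(is.numeric(size_bp))
  if (any(size_bp <= 0)) stop("`size_bp` must be positive", call. = FALSE)
  if (strict && any(size_bp <= calib$offset_bp)) {
    warning("fragment size at or below the non-repeat flank (",
            calib$offset_bp, " bp); sub-flank repeat numbers returned",
            call. = FALSE)
  }
  (size_bp - calib$offset_bp) / calib$bp_per_repeat * calib$slope + calib$intercept
}

#' @rdname bp_to_cag
#' @param cag Numeric vector of CAG repeat numbers.
#' @export
cag_to_bp <- function(cag, calib = cag_calibration()) {
  stopifnot(is.numeric(cag))
  (cag - calib$intercept) / calib$slope * calib$bp_per_repeat + calib$offset_bp
}
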