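# Peak calling and repeat-length distributions.

#' Call repeat-unit peaks from an electropherogram trace
#'
#' A peak is a local maximum of intensity versus fragment size (plateaus of
#' equal intensity count once, at their leftmost point; the two trace ends
#' count as peaks when the signal falls away from them). Peaks below
#' `min_rel_height` times the global maximum are discarded as stutter/noise
#' floor, and surviving peak sizes are mapped to CAG repeat numbers through
#' the sizing calibration. The modal repeat is the retained peak of maximal
#' intensity; ties resolve to the shortest allele.
#'
#' @param trace A tibble with columns `size_bp` (strictly increasing) and
#'   `intensity` for one sample.
#' @param min_rel_height Retention threshold as a fraction of the maximum
#'   intensity, in (0, 1]; default 0.10, a common stutter floor.
#' @param calib A [cag_calibration()].
#' @return A tibble of peaks (`cag`, `intensity`), strictly increasing in
#'   `cag`, with attribute `modal_cag`.
#' @examples
#' tr <- tibble::tibble(size_bp = c(849, 852.33, 855), intensity = c(1, 100, 2))
#' call_peaks(tr)
#' @export
call_peaks <- function(trace, min_rel_height = 0.10, calib = cag_calibration()) {
  stopifnot(is.data.frame(trace),
            all(c("size_bp", "intensity") %in% names(trace)))
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  if (!(min_rel_height > 0 && min_rel_height <= 1)) {
    stop("`min_rel_height` must be in (0, 1]", call. = FALSE)
  }
  o <- order(trace$size_bp)
  x <- trace$size_bp[o]
  y <- trace$intensity[o]
  if (any(diff(x) <= 0)) stop("trace sizes must be strictly increasing", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("trace intensities must be finite and non-negative", call. = FALSE)
  }
  if (all(y == 0)) stop("all-zero intensities: no peaks can be called", call. = FALSE)

  # collapse equal-intensity runs; a run is a peak if both neighbours are lower
  r <- rle(y)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  vals <- r$values
  left <- c(-Inf, vals[-length(vals)])
  right <- c(vals[-1L], -Inf)
  is_peak <- vals > left & vals > right
  pk <- starts[is_peak]

  keep <- y[pk] >= min_rel_height * max(y)
  pk <- pk[keep]
  if (length(pk) == 0L) stop("no peaks at or above the retention threshold", call. = FALSE)

  cag <- bp_to_cag(x[pk], calib)
  out <- tibble::tibble(cag = cag, intensity = y[pk])
  modal <- min(out$cag[out$intensity == max(out$intensity)])
  attr(out, "modal_cag") <- modal
  out
}

#' Normalize a peak set into a repeat-length distribution
#'
#' Weights are peak intensities divided by their total, so the distribution
#' sums to one and is invariant to uniform intensity rescaling.
#'
#' @param peaks A tibble with columns `cag` and `intensity` (e.g. from
#'   [call_peaks()]).
#' @return A tibble (`cag`, `weight`) with `weight >= 0` summing to 1 and
#'   strictly increasing `cag`.
#' @export
build_distribution <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("cag", "intensity") %in% names(peaks)))
  if (nrow(peaks) == 0L) stop("empty peak set", call. = FALSE)
  if (any(peaks$intensity < 0)) stop("negative peak intensity", call. = FALSE)
  tot <- sum(peaks$intensity)
  if (tot <= 0) stop("total peak intensity must be positive", call. = FALSE)
  out <- peaks |>
    dplyr::group_by(.data$cag) |>
    dplyr::summarise(weight = sum(.data$intensity) / tot, .groups = "drop") |>
    dplyr::arrange(.data$cag)
  out
}

#' Modal repeat of a distribution
#'
#' The support value with maximal weight; ties resolve to the smallest
#' (shortest) repeat, a deterministic choice that is conservative against
#' inflating apparent expansion.
#'
#' @param dist A tibble with a repeat column (`cag` or `dcag`) and `weight`.
#' @return A single repeat number.
#' @export
modal_repeat <- function(dist) {
  stopifnot(is.data.frame(dist), "weight" %in% names(dist))
  val_col <- intersect(c("cag", "dcag"), names(dist))[1]
  if (is.na(val_col)) stop("no `cag` or `dcag` column", call. = FALSE)
  if (nrow(dist) == 0L) stop("empty distribution", call. = FALSE)
  min(dist[[val_col]][dist$weight == max(dist$weight)])
}

#' Call peaks and build distributions for every sample in a peak table
#'
#' Convenience wrapper mapping [call_peaks()] + [build_distribution()] over a
#' multi-sample peak table.
#'
#' @param peak_table A tibble (`sample_id`, `size_bp`, `intensity`), e.g.
#'   from [read_peak_table()] or [simulate_cohort()].
#' @inheritParams call_peaks
#' @return A tibble (`sample_id`, `cag`, `weight`).
#' @export
build_distributions <- function(peak_table, min_rel_height = 0.10,
                                calib = cag_calibration()) {
  stopifnot(is.data.frame(peak_table),
            all(c("sample_id", "size_bp", "intensity") %in% names(peak_table)))
  peak_table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      build_distribution(call_peaks(df, min_rel_height, calib))
    }) |>
    dplyr::ungroup()
}

# ---- weighted-distribution primitives (internal) ---------------------------

# left-continuous inverse CDF: smallest x with CDF(x) >= p (within fp slack)
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) {
    x[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)
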