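# Germline normalization and group pooling of repeat-length distributions.

#' Change-in-repeat-length distribution for one tissue sample
#'
#' Somatic change is expressed relative to the animal's germline allele: the
#' tissue distribution's support is shifted by the modal repeat of the same
#' animal's tail (weaning) distribution, giving a distribution over
#' \eqn{\Delta}CAG. The baseline is the modal repeat (a scalar anchor), not a
#' full-distribution deconvolution, so the tissue weights carry over
#' unchanged and remain a valid probability distribution.
#'
#' @param tissue_dist Tibble (`cag`, `weight`) for the tissue sample.
#' @param baseline_dist Tibble (`cag`, `weight`) for the tail sample of the
#'   same animal.
#' @param animal,baseline_animal Optional animal codes; if both are given
#'   they must match (guards against mispairing).
#' @return A tibble (`dcag`, `weight`) with weights summing to 1.
#' @export
delta_distribution <- function(tissue_dist, baseline_dist,
                               animal = NULL, baseline_animal = NULL) {
  stopifnot(is.data.frame(tissue_dist), is.data.frame(baseline_dist))
  if (!is.null(animal) && !is.null(baseline_animal) &&
      !identical(animal, baseline_animal)) {
    stop("baseline is from animal '", baseline_animal,
         "' but tissue is from '", animal, "'", call. = FALSE)
  }
  if (nrow(tissue_dist) == 0L || nrow(baseline_dist) == 0L) {
    stop("empty distribution", call. = FALSE)
  }
  anchor <- modal_repeat(baseline_dist)
  tibble::tibble(dcag = tissue_dist$cag - anchor,
                 weight = tissue_dist$weight)
}

#' Per-animal delta distributions for a whole cohort
#'
#' Joins sample distributions with the manifest and subtracts each animal's
#' tail modal repeat from its tissue distributions.
#'
#' @param dists Tibble (`sample_id`, `cag`, `weight`), e.g. from
#'   [build_distributions()].
#' @param manifest A [build_manifest()] result.
#' @return A tibble (`animal`, `sample_id`, `tissue`, `group`, `age_weeks`,
#'   `dcag`, `weight`) with one distribution per non-tail sample.
#' @export
delta_distributions <- function(dists, manifest) {
  stopifnot(is.data.frame(dists), is.data.frame(manifest))
  baselines <- manifest |>
    dplyr::filter(.data$tissue == "tail") |>
    dplyr::select("sample_id", "animal")
  base_modal <- dists |>
    dplyr::inner_join(baselines, by = "sample_id") |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(baseline_modal = modal_repeat(dplyr::pick("cag", "weight")),
                     .groups = "drop")
  tissue_rows <- manifest |>
    dplyr::filter(.data$tissue != "tail") |>
    dplyr::select("sample_id", "animal", "tissue", "group", "age_weeks")
  missing_base <- setdiff(tissue_rows$animal, base_modal$animal)
  if (length(missing_base) > 0) {
    stop("no tail distribution for animal(s): ",
         paste(missing_base, collapse = ", "), call. = FALSE)
  }
  dists |>
    dplyr::inner_join(tissue_rows, by = "sample_id") |>
    dplyr::inner_join(base_modal, by = "animal") |>
    dplyr::mutate(dcag = .data$cag - .data$baseline_modal) |>
    dplyr::select("animal", "sample_id", "tissue", "group", "age_weeks",
                  "dcag", "weight") |>
    dplyr::arrange(.data$animal, .data$tissue, .data$dcag)
}

#' Pool per-animal delta distributions into a group global distribution
#'
#' Animals are the biological replicates, so each animal's distribution
#' enters with equal weight (one bright sample cannot dominate); the pooled
#' weights are renormalized to total mass 1.
#'
#' @param deltas A tibble with columns `dcag`, `weight`, and `animal` (or a
#'   list of per-animal (`dcag`, `weight`) tibbles).
#' @return A tibble (`dcag`, `weight`) with attribute `n_animals`.
#' @export
pool_group <- function(deltas) {
  if (is.list(deltas) && !is.data.frame(deltas)) {
    if (length(deltas) == 0L) stop("no distributions to pool", call. = FALSE)
    deltas <- dplyr::bind_rows(deltas, .id = "animal")
  }
  stopifnot(is.data.frame(deltas), all(c("dcag", "weight") %in% names(deltas)))
  if (nrow(deltas) == 0L) stop("no distributions to pool", call. = FALSE)
  if (!"animal" %in% names(deltas)) deltas$animal <- "animal1"
  n_animals <- dplyr::n_distinct(deltas$animal)
  out <- deltas |>
    dplyr::group_by(.data$animal) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$dcag) |>
    dplyr::summarise(weight = sum(.data$weight) / n_animals, .groups = "drop") |>
    dplyr::arrange(.data$dcag)
  attr(out, "n_animals") <- n_animals
  out
}

#' Summary statistics of a delta distribution
#'
#' The weighted mean \eqn{\Delta}CAG and the leading-edge \eqn{\Delta}CAG
#' (weighted 95th percentile), the two scalar descriptors of an expansion
#' shift: overall drift and upper-tail reach.
#'
#' @param delta A tibble (`dcag`, `weight`).
#' @param edge_prob Percentile defining the leading edge (default 0.95).
#' @return A one-row tibble (`mean_dcag`, `leading_edge_dcag`).
#' @export
expansion_summary <- function(delta, edge_prob = 0.95) {
  stopifnot(is.data.frame(delta), all(c("dcag", "weight") %in% names(delta)))
  if (nrow(delta) == 0L) stop("empty distribution", call. = FALSE)
  tibble::tibble(
    mean_dcag = weighted_mean(delta$dcag, delta$weight),
    leading_edge_dcag = weighted_quantile(delta$dcag, delta$weight, edge_prob)
  )
}
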