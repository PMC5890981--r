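# Synthetic electropherogram generator: known-truth cohorts for end-to-end
# verification of the expansion pipeline.

#' Drift model: tissue/age/treatment-dependent somatic expansion
#'
#' The change-in-repeat-length (\eqn{\Delta}CAG) distribution of a tissue is
#' modeled as a Gaussian core plus a geometric (discretized exponential)
#' right tail, reproducing the leading-edge asymmetry of expanding repeats.
#' `mean_shift` is the total mean of the \eqn{\Delta} distribution (the core
#' is centred so that core + tail average to `mean_shift`), which is what
#' [expansion_summary()] estimates. Each animal draws its own mean drift
#' from `N(mean_shift, inter_animal_sd)`.
#'
#' @param mean_shift Mean \eqn{\Delta}CAG of the tissue distribution
#'   (repeat units); 0 = no expansion.
#' @param skew Mean of the exponential right tail (repeat units); 0 = no
#'   leading-edge asymmetry.
#' @param within_sd SD of the Gaussian core: within-animal mosaic spread
#'   across cells of the tissue (repeat units).
#' @param inter_animal_sd Between-animal SD of the mean drift (repeat units).
#' @return A `drift_model` list.
#' @export
drift_model <- function(mean_shift = 0, skew = 0, within_sd = 0.8,
                        inter_animal_sd = 0) {
  stopifnot(skew >= 0, within_sd >= 0, inter_animal_sd >= 0)
  structure(list(mean_shift = mean_shift, skew = skew, within_sd = within_sd,
                 inter_animal_sd = inter_animal_sd),
            class = "drift_model")
}

#' Named drift presets for the study regimes
#'
#' Qualitative encodings of the three regimes seen in R6/2 fragment data:
#' no expansion at 8 weeks in any group; prominent right-skewed expansion at
#' 12 weeks in vehicle-treated animals; strongly suppressed expansion at 12
#' weeks under treatment. Numeric values are generator presets, not
#' measurements.
#'
#' @param name One of `"week8_null"`, `"week12_veh"`, `"week12_xjb"`.
#' @return A [drift_model()].
#' @export
drift_preset <- function(name = c("week8_null", "week12_veh", "week12_xjb")) {
  name <- match.arg(name)
  switch(name,
    week8_null = drift_model(mean_shift = 0, skew = 0, within_sd = 0.8,
                             inter_animal_sd = 0),
    week12_veh = drift_model(mean_shift = 8, skew = 4, within_sd = 3,
                             inter_animal_sd = 0.5),
    week12_xjb = drift_model(mean_shift = 1, skew = 1, within_sd = 2,
                             inter_animal_sd = 0.5))
}

#' Trace model: how a repeat distribution renders as an electropherogram
#'
#' Each true allele becomes a Gaussian-shaped signal peak at its calibrated
#' fragment size, preceded by a geometric PCR-stutter ladder toward shorter
#' sizes; peak positions carry Gaussian sizing jitter and the sampled signal
#' carries additive Gaussian intensity noise truncated at zero.
#'
#' @param modal_cag Population modal repeat of the transgene (default 255).
#' @param modal_sd_between_animals SD of the germline modal across animals
#'   (default 1, the reported 255 +/- 1 spread).
#' @param stutter_decay Intensity ratio of each successive stutter peak one
#'   repeat shorter, in \[0, 1) (default 0.2).
#' @param noise_sd Additive intensity noise SD, signal units (default 3).
#' @param amplitude Intensity scale of unit distribution weight (default 1000).
#' @param peak_sd_bp Width (SD, bp) of one rendered peak (default 0.5).
#' @param size_jitter_sd Sizing error SD per peak, bp (default 0.1).
#' @param n_points Number of evenly spaced samples across the rendered
#'   window (default 500).
#' @return A `trace_model` list.
#' @export
trace_model <- function(modal_cag = 255, modal_sd_between_animals = 1,
                        stutter_decay = 0.2, noise_sd = 3, amplitude = 1000,
                        peak_sd_bp = 0.5, size_jitter_sd = 0.1,
                        n_points = 500) {
  stopifnot(stutter_decay >= 0, stutter_decay < 1, noise_sd >= 0,
            amplitude > 0, peak_sd_bp > 0, size_jitter_sd >= 0, n_points >= 2)
  structure(list(modal_cag = modal_cag,
                 modal_sd_between_animals = modal_sd_between_animals,
                 stutter_decay = stutter_decay, noise_sd = noise_sd,
                 amplitude = amplitude, peak_sd_bp = peak_sd_bp,
                 size_jitter_sd = size_jitter_sd,
                 n_points = as.integer(n_points)),
            class = "trace_model")
}

# Discrete delta distribution on the repeat lattice: Gaussian core (binned at
# integers) convolved with a geometric right tail whose mean is subtracted
# from the core centre so the total mean equals `total_mean` exactly (up to
# core binning).
.discrete_delta <- function(total_mean, within_sd, skew) {
  if (skew > 0) {
    r <- exp(-1 / skew)
    J <- ceiling(log(1e-6) / log(r))
    tail_w <- r^(0:J)
    tail_w <- tail_w / sum(tail_w)
    tail_mean <- sum((0:J) * tail_w)
  } else {
    tail_w <- 1
    tail_mean <- 0
    J <- 0L
  }
  core_mean <- total_mean - tail_mean
  if (within_sd > 0) {
    k <- seq(floor(core_mean - 5 * within_sd), ceiling(core_mean + 5 * within_sd))
    core_w <- stats::pnorm(k + 0.5, core_mean, within_sd) -
      stats::pnorm(k - 0.5, core_mean, within_sd)
  } else {
    k <- core_mean
    core_w <- 1
  }
  x <- as.vector(outer(k, 0:J, `+`))
  w <- as.vector(outer(core_w, tail_w))
  agg <- tapply(w, x, sum)
  x <- as.numeric(names(agg))
  w <- as.numeric(agg) / sum(agg)
  keep <- w > 1e-9
  tibble::tibble(dcag = x[keep], weight = w[keep] / sum(w[keep]))
}

#' Render a repeat-length distribution as a synthetic electropherogram
#'
#' Deterministic under a fixed seed. With `noise_sd = 0`,
#' `stutter_decay = 0` and `size_jitter_sd = 0` a single allele renders as a
#' single clean peak that [call_peaks()] recovers exactly (up to the sample
#' grid).
#'
#' @param true_dist Tibble (`cag`, `weight`): the true allele distribution.
#' @param tm A [trace_model()].
#' @param seed Optional integer seed (uses and restores the RNG state via
#'   [withr::with_seed()]); `NULL` draws from the current RNG stream.
#' @param calib A [cag_calibration()].
#' @return A tibble (`size_bp`, `intensity`) with strictly increasing sizes.
#' @export
simulate_trace <- function(true_dist, tm = trace_model(), seed = NULL,
                           calib = cag_calibration()) {
  stopifnot(is.data.frame(true_dist),
            all(c("cag", "weight") %in% names(true_dist)))
  render <- function() {
    w <- true_dist$weight / sum(true_dist$weight)
    cag <- true_dist$cag
    if (tm$stutter_decay > 0) {
      J <- ceiling(log(1e-3) / log(tm$stutter_decay))
      j <- 0:J
      ratio <- tm$stutter_decay^j
    } else {
      j <- 0L
      ratio <- 1
    }
    comp_cag <- as.vector(outer(cag, j, `-`))
    comp_int <- as.vector(outer(w * tm$amplitude, ratio))
    keep <- comp_int >= 1e-4 * max(comp_int)
    comp_cag <- comp_cag[keep]
    comp_int <- comp_int[keep]
    pos <- cag_to_bp(comp_cag, calib)
    if (tm$size_jitter_sd > 0) {
      pos <- pos + stats::rnorm(length(pos), 0, tm$size_jitter_sd)
    }
    grid <- seq(min(pos) - 4, max(pos) + 4, length.out = tm$n_points)
    shape <- exp(-(outer(grid, pos, `-`))^2 / (2 * tm$peak_sd_bp^2))
    y <- as.vector(shape %*% comp_int)
    if (tm$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, tm$noise_sd)
    y[y < 0] <- 0
    tibble::tibble(size_bp = grid, intensity = y)
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Simulate one animal: tail baseline plus tissue traces
#'
#' Draws the animal's germline modal from
#' `N(modal_cag, modal_sd_between_animals)`, renders the tail (weaning)
#' trace at that single allele, then for each tissue draws the animal-level
#' mean drift from `N(mean_shift, inter_animal_sd)` and renders the shifted
#' \eqn{\Delta} distribution.
#'
#' @param dm A [drift_model()] (shared by all tissues) or a named list of
#'   drift models keyed by tissue.
#' @param tm A [trace_model()].
#' @param tissues Character vector of non-tail tissues
#'   (`"striatum"`/`"cerebellum"`).
#' @param animal Animal code (must contain the sex letter, e.g. `"BRM1001"`).
#' @param seed Optional integer seed.
#' @param calib A [cag_calibration()].
#' @return A list: `traces` tibble (`sample_id`, `size_bp`, `intensity`) and
#'   `truth` tibble (`sample_id`, `animal`, `tissue`, `germline_modal`,
#'   `true_mean_shift`).
#' @export
simulate_animal <- function(dm, tm = trace_model(), tissues = "striatum",
                            animal = "BRM1001", seed = NULL,
                            calib = cag_calibration()) {
  letter <- c(tail = "t", striatum = "s", cerebellum = "c")
  stopifnot(all(tissues %in% names(letter)[-1]))
  gen <- function() {
    g <- stats::rnorm(1, tm$modal_cag, tm$modal_sd_between_animals)
    tail_id <- paste0(animal, "t")
    tail_dist <- tibble::tibble(cag = g, weight = 1)
    traces <- list(
      dplyr::mutate(simulate_trace(tail_dist, tm, calib = calib),
                    sample_id = tail_id, .before = 1))
    truth <- list(tibble::tibble(sample_id = tail_id, animal = animal,
                                 tissue = "tail", germline_modal = g,
                                 true_mean_shift = 0))
    for (ts in tissues) {
      d <- if (inherits(dm, "drift_model")) dm else dm[[ts]]
      shift <- stats::rnorm(1, d$mean_shift, d$inter_animal_sd)
      dd <- .discrete_delta(shift, d$within_sd, d$skew)
      dist <- tibble::tibble(cag = g + dd$dcag, weight = dd$weight)
      sid <- paste0(animal, letter[[ts]])
      traces <- c(traces, list(
        dplyr::mutate(simulate_trace(dist, tm, calib = calib),
                      sample_id = sid, .before = 1)))
      truth <- c(truth, list(
        tibble::tibble(sample_id = sid, animal = animal, tissue = ts,
                       germline_modal = g, true_mean_shift = shift)))
    }
    list(traces = dplyr::bind_rows(traces), truth = dplyr::bind_rows(truth))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a full treatment cohort with known ground truth
#'
#' Deterministic given `seed`. Animal codes are generated in the
#' supplementary-legend style (`BRM1001s` etc.), sexes alternate within each
#' group, and the whole cohort is emitted as one combined peak table plus a
#' design table and a ground-truth table.
#'
#' @param drift Named list mapping each group label to a [drift_model()]
#'   (or to a named per-tissue list of drift models).
#' @param n_per_group Animals per group (default 3, the study's group size
#'   for the expansion analysis).
#' @param tissues Non-tail tissues to simulate (default `"striatum"`).
#' @param age_weeks Age label recorded in the design (default 12).
#' @param tm A [trace_model()].
#' @param seed Integer seed.
#' @param calib A [cag_calibration()].
#' @return A list: `peaks` (combined trace table: `sample_id`, `size_bp`,
#'   `intensity`), `design` (`animal`, `group`, `age_weeks`), `manifest`
#'   (from [build_manifest()]), and `truth`.
#' @export
simulate_cohort <- function(drift, n_per_group = 3, tissues = "striatum",
                            age_weeks = 12, tm = trace_model(), seed = 1,
                            calib = cag_calibration()) {
  stopifnot(is.list(drift), !is.null(names(drift)), n_per_group >= 1)
  withr::with_seed(seed, {
    traces <- list()
    truth <- list()
    design <- list()
    idx <- 0L
    for (grp in names(drift)) {
      for (i in seq_len(n_per_group)) {
        idx <- idx + 1L
        sex <- if (i %% 2L == 1L) "M" else "F"
        animal <- sprintf("BR%s%04d", sex, 1000L + idx)
        sim <- simulate_animal(drift[[grp]], tm, tissues, animal,
                               seed = NULL, calib = calib)
        traces <- c(traces, list(sim$traces))
        truth <- c(truth, list(dplyr::mutate(sim$truth, group = grp,
                                             age_weeks = age_weeks)))
        design <- c(design, list(tibble::tibble(animal = animal, group = grp,
                                                age_weeks = age_weeks)))
      }
    }
    peaks <- dplyr::bind_rows(traces)
    design <- dplyr::bind_rows(design)
    manifest <- build_manifest(peaks["sample_id"], design)
    list(peaks = peaks, design = design, manifest = manifest,
         truth = dplyr::bind_rows(truth))
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the combined TSV peak table, a TSV design table, a JSON manifest
#' and the ground-truth JSON (true per-animal shifts).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_distribution_table(cohort$peaks, file.path(dir, "peaks.tsv"))
  readr::write_tsv(cohort$design, file.path(dir, "design.tsv"), progress = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(dir)
}
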