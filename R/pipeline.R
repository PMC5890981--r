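# End-to-end pipeline: peak table -> distributions -> deltas -> cell report.

#' Run the full somatic-expansion pipeline
#'
#' Reads (or accepts) a peak table and a design table, builds per-sample
#' repeat distributions, normalizes every tissue against its animal's tail
#' baseline, and for each non-tail tissue runs the quantile-cell
#' untreated-versus-treated comparison plus the one-way ANOVA of per-animal
#' mean \eqn{\Delta}CAG. All tabular outputs are written as TSV (floats at 6
#' significant digits) with a machine-readable JSON run log (inputs hashed,
#' parameters, package version), so reruns with identical inputs are
#' byte-identical.
#'
#' @param peaks Peak table path (TSV) or tibble (`sample_id`, `size_bp`,
#'   `intensity`).
#' @param design Design table path (TSV) or tibble (`animal`, `group`,
#'   optional `age_weeks`).
#' @param out_dir Output directory, created if needed.
#' @param untreated,treated Group labels compared per cell (difference is
#'   untreated minus treated).
#' @param cfg An [analysis_config()].
#' @param min_rel_height Peak retention threshold for [call_peaks()].
#' @param calib A [cag_calibration()].
#' @param cells Cell basis passed to [compare_groups()].
#' @param make_plot Also write a diff-versus-cell PDF per tissue (optional
#'   artifact; all downstream checks read the TSV/JSON only).
#' @param seed Recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with `distributions`, `deltas`, and per-tissue
#'   `comparisons` (each a `cag_cell_test`), plus `paths` of files written.
#' @export
run_pipeline <- function(peaks, design, out_dir,
                         untreated = "R6/2-Veh", treated = "R6/2-XJB",
                         cfg = analysis_config(), min_rel_height = 0.10,
                         calib = cag_calibration(),
                         cells = c("quantile_slices", "shared_edges"),
                         make_plot = FALSE, seed = NULL) {
  cells <- match.arg(cells)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  peaks_tab <- stage("read_peaks", read_peak_table(peaks))
  design_tab <- stage("read_design", {
    if (is.data.frame(design)) tibble::as_tibble(design)
    else readr::read_tsv(design, show_col_types = FALSE, progress = FALSE)
  })
  manifest <- stage("manifest", build_manifest(peaks_tab["sample_id"], design_tab))
  dists <- stage("distributions",
                 build_distributions(peaks_tab, min_rel_height, calib))
  deltas <- stage("deltas", delta_distributions(dists, manifest))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    distributions = file.path(out_dir, "distributions.tsv"),
    deltas = file.path(out_dir, "deltas.tsv"),
    run_log = file.path(out_dir, "run_log.json"))
  write_distribution_table(dists, paths$distributions)
  write_distribution_table(deltas, paths$deltas)

  tissues <- sort(unique(deltas$tissue))
  comparisons <- list()
  anova_list <- list()
  for (ts in tissues) {
    d_ts <- deltas |> dplyr::filter(.data$tissue == ts)
    cmp <- stage(paste0("compare_", ts),
                 compare_groups(d_ts, untreated, treated, cfg, cells))
    comparisons[[ts]] <- cmp
    anova_list[[ts]] <- dplyr::mutate(cmp$anova, tissue = ts, .before = 1)
    p_cells <- file.path(out_dir, paste0("cells_", ts, ".tsv"))
    write_distribution_table(tidy(cmp), p_cells)
    paths[[paste0("cells_", ts)]] <- p_cells
    if (make_plot) {
      p_pdf <- file.path(out_dir, paste0("cells_", ts, ".pdf"))
      ggplot2::ggsave(p_pdf, autoplot(cmp), width = 8, height = 4)
      paths[[paste0("plot_", ts)]] <- p_pdf
    }
  }
  anova_tab <- dplyr::bind_rows(anova_list)
  paths$anova <- file.path(out_dir, "anova.tsv")
  write_distribution_table(anova_tab, paths$anova)

  log <- list(
    package = "cagdrift",
    version = as.character(utils::packageVersion("cagdrift")),
    seed = seed,
    input_hash = list(peaks = rlang::hash(peaks_tab),
                      design = rlang::hash(design_tab)),
    parameters = list(
      untreated = untreated, treated = treated, cell_basis = cells,
      min_rel_height = min_rel_height,
      calibration = unclass(calib),
      n_cells = cfg$n_cells, n_exclude_each_end = cfg$n_exclude_each_end,
      alpha = cfg$alpha, variance_gate_alpha = cfg$variance_gate_alpha,
      two_sided = cfg$two_sided, p_adjust = cfg$p_adjust),
    n_samples = dplyr::n_distinct(peaks_tab$sample_id),
    tissues = tissues)
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)

  invisible(list(distributions = dists, deltas = deltas,
                 comparisons = comparisons, anova = anova_tab, paths = paths))
}
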