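# S3 methods for the cell-comparison result: print, tidy, glance, autoplot.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.cag_cell_test <- function(x, ...) {
  tab <- x$cells
  cat("<cag_cell_test>", nrow(tab), "retained quantile cells",
      sprintf("(of %d, %d excluded per end)\n", x$config$n_cells,
              x$config$n_exclude_each_end))
  if (!is.null(x$groups)) {
    cat("  untreated:", x$groups[["untreated"]],
        sprintf("(n = %d)", x$n_untreated),
        " treated:", x$groups[["treated"]],
        sprintf("(n = %d)\n", x$n_treated))
  }
  cat(sprintf("  cell basis: %s\n",
              if (is.null(x$cell_basis)) "matrix input" else x$cell_basis))
  cat(sprintf("  significant cells (p < %g): %d / %d tested\n",
              x$config$alpha, sum(tab$significant), sum(tab$tested)))
  if (!is.null(x$anova)) {
    cat(sprintf("  one-way ANOVA of mean dCAG: F = %.3f, p = %.4g\n",
                x$anova$f_statistic, x$anova$p_value))
  }
  invisible(x)
}

#' Tidy a quantile-cell comparison
#'
#' @param x A `cag_cell_test` from [compare_cells()]/[compare_groups()].
#' @param ... Unused.
#' @return The per-cell tibble: one row per retained cell with group means,
#'   difference (untreated - treated), SE, chosen test, p-value and
#'   significance flag.
#' @exportS3Method generics::tidy
tidy.cag_cell_test <- function(x, ...) x$cells

#' One-row summary of a quantile-cell comparison
#'
#' @inheritParams tidy.cag_cell_test
#' @return A one-row tibble: cell counts, number significant, the largest
#'   difference, and the ANOVA F/p when present.
#' @exportS3Method generics::glance
glance.cag_cell_test <- function(x, ...) {
  tab <- x$cells
  out <- tibble::tibble(
    n_cells = x$config$n_cells,
    n_retained = nrow(tab),
    n_tested = sum(tab$tested),
    n_significant = sum(tab$significant),
    max_diff = if (any(tab$tested)) max(tab$diff[tab$tested]) else NA_real_,
    alpha = x$config$alpha)
  if (!is.null(x$anova)) {
    out$anova_f <- x$anova$f_statistic
    out$anova_p <- x$anova$p_value
  }
  out
}

#' Plot a quantile-cell comparison (difference vs cell index)
#'
#' Bars show the untreated-minus-treated mean difference per retained cell
#' with 1 SE whiskers; cells with a significant increase (p < alpha) are
#' red, non-significant cells blue, untested cells grey.
#'
#' @param object A `cag_cell_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cag_cell_test <- function(object, ...) {
  tab <- object$cells |>
    dplyr::mutate(status = dplyr::case_when(
      !.data$tested ~ "untested",
      .data$significant ~ sprintf("p < %g", object$config$alpha),
      TRUE ~ "not significant"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cell, y = .data$diff,
                                    fill = .data$status)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$diff - .data$se_diff,
                                        ymax = .data$diff + .data$se_diff),
                           width = 0, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = stats::setNames(
      c("#c23b22", "#4a7fb5", "grey70"),
      c(sprintf("p < %g", object$config$alpha), "not significant", "untested"))) +
    ggplot2::labs(x = "quantile cell", y = expression(Delta * "CAG (untreated - treated)"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-animal expansion shift: tissue vs weaning baseline
#'
#' Overlays each animal's tissue \eqn{\Delta}CAG distribution (red) on the
#' germline baseline at \eqn{\Delta = 0} (blue dashed), one facet per
#' animal.
#'
#' @param deltas Tibble from [delta_distributions()].
#' @return A ggplot object.
#' @export
plot_expansion_shift <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$dcag, y = .data$weight)) +
    ggplot2::geom_col(width = 0.4, fill = "#c23b22") +
    ggplot2::geom_vline(xintercept = 0, colour = "#4a7fb5", linetype = 2) +
    ggplot2::facet_wrap(~ animal + tissue) +
    ggplot2::labs(x = expression(Delta * "CAG (tissue - weaning modal)"),
                  y = "weight") +
    ggplot2::theme_minimal()
}
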