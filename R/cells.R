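# Quantile-cell construction and variance-gated two-sample comparison.

#' Analysis configuration for the quantile-cell comparison
#'
#' Defaults follow the published procedure: the distribution is divided into
#' 100 equal-mass cells, the first and last 5 quantile cells are excluded
#' (retained cells 6..95), and per-cell tests are two-sided at
#' \eqn{\alpha = 0.05} with an F-test variance gate at the same level and no
#' multiple-testing correction (each cell is colored by its own p < 0.05;
#' Benjamini-Hochberg is available behind `p_adjust`).
#'
#' @param n_cells Number of equal-mass quantile cells (default 100).
#' @param n_exclude_each_end Quantile cells dropped at each end (default 5).
#' @param alpha Per-cell significance level (default 0.05).
#' @param variance_gate_alpha Level of the preliminary F-test choosing
#'   Welch's over Student's t-test (default 0.05).
#' @param two_sided Two-sided per-cell tests (default TRUE).
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method,
#'   applied across tested cells.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_cells = 100, n_exclude_each_end = 5,
                            alpha = 0.05, variance_gate_alpha = 0.05,
                            two_sided = TRUE, p_adjust = "none") {
  stopifnot(n_cells >= 2, n_exclude_each_end >= 0)
  if (2 * n_exclude_each_end >= n_cells) {
    stop("2 * n_exclude_each_end must be < n_cells", call. = FALSE)
  }
  structure(
    list(n_cells = as.integer(n_cells),
         n_exclude_each_end = as.integer(n_exclude_each_end),
         alpha = alpha, variance_gate_alpha = variance_gate_alpha,
         two_sided = isTRUE(two_sided), p_adjust = p_adjust),
    class = "analysis_config")
}

retained_cells <- function(cfg) {
  seq.int(cfg$n_exclude_each_end + 1L, cfg$n_cells - cfg$n_exclude_each_end)
}

#' Quantile edges of the combined distribution of two groups
#'
#' The two group distributions are mass-averaged (each contributes half) and
#' the interior weighted quantiles at i/n_cells, i = 1..n_cells-1, are
#' returned. Cells are half-open on the left and closed on the right, except
#' cell 1 which includes its left edge.
#'
#' @param a,b Tibbles (`dcag`, `weight`), each summing to 1.
#' @param cfg An [analysis_config()].
#' @return Numeric vector of n_cells - 1 edges (non-decreasing).
#' @export
combined_quantile_edges <- function(a, b, cfg = analysis_config()) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty group distribution", call. = FALSE)
  comb <- dplyr::bind_rows(
    dplyr::mutate(a[, c("dcag", "weight")], weight = .data$weight / sum(.data$weight) / 2),
    dplyr::mutate(b[, c("dcag", "weight")], weight = .data$weight / sum(.data$weight) / 2)
  ) |>
    dplyr::group_by(.data$dcag) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  if (nrow(comb) < 2L) {
    stop("combined distribution has a single support value; ",
         "use fewer cells or richer input", call. = FALSE)
  }
  probs <- seq_len(cfg$n_cells - 1L) / cfg$n_cells
  weighted_quantile(comb$dcag, comb$weight, probs)
}

#' Per-cell weighted means of one distribution against shared edges
#'
#' Cell k is the interval (edge\[k-1\], edge\[k\]\] on the \eqn{\Delta}CAG
#' axis (cell 1 extends to -Inf, the last cell to +Inf). Each entry is the
#' weight-weighted mean of the distribution's mass falling in that cell;
#' cells holding no mass are `NA`.
#'
#' @param delta Tibble (`dcag`, `weight`).
#' @param edges Edges from [combined_quantile_edges()].
#' @return Numeric vector of length `length(edges) + 1`.
#' @export
cell_means_from_edges <- function(delta, edges) {
  stopifnot(is.data.frame(delta), is.numeric(edges))
  n_cells <- length(edges) + 1L
  cell <- findInterval(delta$dcag, edges, left.open = TRUE) + 1L
  out <- rep(NA_real_, n_cells)
  agg <- tapply(delta$weight * delta$dcag, cell, sum) /
    tapply(delta$weight, cell, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Per-cell means by equal-mass quantile slices of one distribution
#'
#' Cuts a single distribution into `n_cells` slices of equal probability
#' mass and returns the weighted mean \eqn{\Delta}CAG inside each slice
#' (an atom whose mass straddles a slice boundary contributes to both
#' slices in proportion to the mass on each side). Slice k of every
#' animal's distribution indexes the same quantile range, so slice means
#' are comparable across animals and groups; every slice holds mass 1/n by
#' construction.
#'
#' @param delta Tibble (`dcag`, `weight`).
#' @param n_cells Number of equal-mass cells.
#' @return Numeric vector of length `n_cells` (no missing values).
#' @export
quantile_cell_means <- function(delta, n_cells = 100) {
  stopifnot(is.data.frame(delta), all(c("dcag", "weight") %in% names(delta)))
  if (nrow(delta) == 0L) stop("empty distribution", call. = FALSE)
  o <- order(delta$dcag)
  x <- delta$dcag[o]
  w <- delta$weight[o]
  w <- w / sum(w)
  cw <- cumsum(w)
  cxw <- cumsum(x * w)
  # I(p) = integral_0^p Q(u) du; piecewise linear with slope x_j on (cw[j-1], cw[j]]
  p <- seq(0, 1, length.out = n_cells + 1L)
  p <- pmin(p, cw[length(cw)])
  j <- findInterval(p, cw, left.open = TRUE) + 1L
  j <- pmin(j, length(x))
  cw0 <- c(0, cw)[j]
  cxw0 <- c(0, cxw)[j]
  Ip <- cxw0 + x[j] * (p - cw0)
  n_cells * diff(Ip)
}

#' Choose Student's or Welch's t-test by a preliminary F-test
#'
#' A two-sided F-test of variance equality at `gate_alpha`: a significant
#' variance difference selects Welch's unequal-variance t-test, otherwise
#' Student's equal-variance t-test.
#'
#' @param x,y Numeric sample vectors, each of length >= 2 with nonzero
#'   combined variance.
#' @param gate_alpha Gate level (default 0.05).
#' @return A list with `test` (`"Student"` or `"Welch"`), `f_statistic`,
#'   and `p_value` of the F-test.
#' @export
variance_gate <- function(x, y, gate_alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("variance gate needs at least 2 observations per sample", call. = FALSE)
  }
  if (stats::var(x) + stats::var(y) == 0) {
    stop("zero combined variance: variances cannot be compared", call. = FALSE)
  }
  ft <- stats::var.test(x, y)
  list(test = if (ft$p.value < gate_alpha) "Welch" else "Student",
       f_statistic = unname(ft$statistic),
       p_value = ft$p.value)
}

# one cell's two-sample comparison; x = untreated, y = treated
.cell_test <- function(x, y, cfg) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  blank <- list(n_untreated = length(x), n_treated = length(y),
                mean_untreated = if (length(x)) mean(x) else NA_real_,
                mean_treated = if (length(y)) mean(y) else NA_real_,
                diff = NA_real_, se_diff = NA_real_, test = NA_character_,
                statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                tested = FALSE)
  if (length(x) < 2L || length(y) < 2L) return(blank)
  d <- mean(x) - mean(y)
  if (stats::var(x) + stats::var(y) == 0) {
    # degenerate: both samples constant; equal constants are indistinguishable
    blank$diff <- d
    blank$se_diff <- 0
    blank$test <- "Student"
    blank$statistic <- if (d == 0) 0 else sign(d) * Inf
    blank$df <- length(x) + length(y) - 2
    blank$p_value <- if (d == 0) 1 else 0
    blank$tested <- TRUE
    return(blank)
  }
  gate <- variance_gate(x, y, cfg$variance_gate_alpha)
  tt <- stats::t.test(x, y, var.equal = (gate$test == "Student"),
                      alternative = if (cfg$two_sided) "two.sided" else "greater")
  blank$diff <- d
  blank$se_diff <- unname(tt$stderr)
  blank$test <- gate$test
  blank$statistic <- unname(tt$statistic)
  blank$df <- unname(tt$parameter)
  blank$p_value <- tt$p.value
  blank$tested <- TRUE
  blank
}

#' Per-cell comparison of untreated versus treated animals
#'
#' For every retained quantile cell, the per-animal cell means of the two
#' groups are compared with a two-sample t-test chosen by the variance gate
#' ([variance_gate()]); the reported difference is untreated minus treated,
#' with its standard error. Cells with fewer than 2 non-missing animals in
#' either group are flagged untested (never dropped silently). No
#' multiple-testing correction is applied unless `cfg$p_adjust` says so.
#'
#' @param untreated,treated Matrices of per-animal cell means (rows =
#'   animals, columns = all `cfg$n_cells` cells), from
#'   [quantile_cell_means()] or [cell_means_from_edges()].
#' @param cfg An [analysis_config()].
#' @return A `cag_cell_test` object; its `cells` tibble has one row per
#'   retained cell with `cell`, group means, `diff`, `se_diff`, `test`,
#'   `statistic`, `df`, `p_value`, `significant`, `tested`.
#' @export
compare_cells <- function(untreated, treated, cfg = analysis_config()) {
  untreated <- as.matrix(untreated)
  treated <- as.matrix(treated)
  if (ncol(untreated) != cfg$n_cells || ncol(treated) != cfg$n_cells) {
    stop("cell-mean matrices must have n_cells = ", cfg$n_cells, " columns",
         call. = FALSE)
  }
  cells <- retained_cells(cfg)
  rows <- purrr::map(cells, function(k) {
    res <- .cell_test(untreated[, k], treated[, k], cfg)
    tibble::as_tibble(res[c("mean_untreated", "mean_treated", "diff",
                            "se_diff", "test", "statistic", "df", "p_value",
                            "n_untreated", "n_treated", "tested")])
  })
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::bind_cols(tibble::tibble(cell = cells), tab)
  if (!identical(cfg$p_adjust, "none")) {
    tab$p_value[tab$tested] <- stats::p.adjust(tab$p_value[tab$tested],
                                               method = cfg$p_adjust)
  }
  tab$significant <- tab$tested & !is.na(tab$p_value) & tab$p_value < cfg$alpha
  structure(
    list(cells = tab, config = cfg,
         n_untreated = nrow(untreated), n_treated = nrow(treated)),
    class = "cag_cell_test")
}

#' One-way ANOVA on per-animal overall expansion
#'
#' Standard one-way analysis of variance of per-animal mean
#' \eqn{\Delta}CAG with group (treatment or age) as the factor. The
#' degenerate all-constant case (zero variance everywhere, equal means)
#' returns F = 0, p = 1 by convention.
#'
#' @param values Numeric vector of per-animal summary values (e.g. mean
#'   \eqn{\Delta}CAG from [expansion_summary()]).
#' @param groups Factor or character vector of group labels, same length.
#' @return A one-row tibble (`f_statistic`, `df_between`, `df_within`,
#'   `p_value`).
#' @export
anova_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(values) == 0) {
    return(tibble::tibble(f_statistic = 0,
                          df_between = nlevels(groups) - 1L,
                          df_within = length(values) - nlevels(groups),
                          p_value = 1))
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tibble::tibble(f_statistic = s[["F value"]][1],
                 df_between = s[["Df"]][1],
                 df_within = s[["Df"]][2],
                 p_value = s[["Pr(>F)"]][1])
}

#' Full group comparison from per-animal delta distributions
#'
#' Orchestrates the per-cell procedure for one tissue: computes per-animal
#' cell means (equal-mass quantile slices by default, or cells defined by
#' shared edges of the mass-averaged combined group distribution), then
#' runs [compare_cells()] and the one-way ANOVA of per-animal mean
#' \eqn{\Delta}CAG.
#'
#' @param deltas Tibble of per-animal delta distributions (`animal`,
#'   `group`, `dcag`, `weight`), e.g. from [delta_distributions()],
#'   already filtered to one tissue/age.
#' @param untreated,treated Group labels to compare (difference is
#'   untreated minus treated).
#' @param cfg An [analysis_config()].
#' @param cells `"quantile_slices"` (default): each animal's distribution
#'   is cut into its own equal-mass cells; `"shared_edges"`: cells are
#'   intervals between quantile edges of the combined group distribution
#'   and animals missing mass in a cell are excluded pairwise.
#' @return A `cag_cell_test` object with an `anova` element added.
#' @export
compare_groups <- function(deltas, untreated, treated,
                           cfg = analysis_config(),
                           cells = c("quantile_slices", "shared_edges")) {
  cells <- match.arg(cells)
  stopifnot(is.data.frame(deltas),
            all(c("animal", "group", "dcag", "weight") %in% names(deltas)))
  pick_group <- function(label) {
    d <- deltas |> dplyr::filter(.data$group == label)
    if (nrow(d) == 0L) stop("no animals in group '", label, "'", call. = FALSE)
    split(d[, c("dcag", "weight")], d$animal)
  }
  ul <- pick_group(untreated)
  tl <- pick_group(treated)

  if (cells == "quantile_slices") {
    mat <- function(lst) t(vapply(lst, quantile_cell_means,
                                  numeric(cfg$n_cells), n_cells = cfg$n_cells))
    m_u <- mat(ul)
    m_t <- mat(tl)
  } else {
    pooled_u <- pool_group(deltas |> dplyr::filter(.data$group == untreated))
    pooled_t <- pool_group(deltas |> dplyr::filter(.data$group == treated))
    edges <- combined_quantile_edges(pooled_u, pooled_t, cfg)
    mat <- function(lst) t(vapply(lst, cell_means_from_edges,
                                  numeric(cfg$n_cells), edges = edges))
    m_u <- mat(ul)
    m_t <- mat(tl)
  }
  out <- compare_cells(m_u, m_t, cfg)
  per_animal <- deltas |>
    dplyr::filter(.data$group %in% c(untreated, treated)) |>
    dplyr::group_by(.data$animal, .data$group) |>
    dplyr::summarise(mean_dcag = weighted_mean(.data$dcag, .data$weight),
                     .groups = "drop")
  out$anova <- anova_groups(per_animal$mean_dcag, per_animal$group)
  out$groups <- c(untreated = untreated, treated = treated)
  out$cell_basis <- cells
  out
}
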