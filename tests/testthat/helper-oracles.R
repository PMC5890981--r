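# Independent brute-force oracles used to cross-check the package's
# quantile/cell/test computations. Deliberately naive implementations:
# explicit loops and textbook formulas, sharing no code with the package.

# smallest support value whose cumulative weight reaches p (linear scan)
oracle_weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + w[i]
    if (acc >= p - 1e-12) return(x[i])
  }
  x[length(x)]
}

# per-cell weighted means against edges; cell k = (e[k-1], e[k]], ends open
oracle_cell_means_edges <- function(x, w, edges) {
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  out <- rep(NA_real_, length(lo))
  for (k in seq_along(lo)) {
    inside <- x > lo[k] & x <= hi[k]
    if (k == 1L) inside <- x <= hi[k]
    if (any(inside) && sum(w[inside]) > 0) {
      out[k] <- sum(x[inside] * w[inside]) / sum(w[inside])
    }
  }
  out
}

# equal-mass slice means via explicit interval-overlap double loop
oracle_slice_means <- function(x, w, n_cells) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  hi <- cumsum(w)
  lo <- c(0, hi[-length(hi)])
  means <- numeric(n_cells)
  for (k in seq_len(n_cells)) {
    a <- (k - 1) / n_cells
    b <- k / n_cells
    num <- 0
    den <- 0
    for (j in seq_along(x)) {
      ov <- max(0, min(hi[j], b) - max(lo[j], a))
      num <- num + x[j] * ov
      den <- den + ov
    }
    means[k] <- num / den
  }
  means
}

# textbook two-sample t statistics
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mean(x) - mean(y)) / se
  df <- nx + ny - 2
  list(t = t, df = df, se = se, p = 2 * pt(-abs(t), df))
}

oracle_welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  se <- sqrt(vx + vy)
  t <- (mean(x) - mean(y)) / se
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, se = se, p = 2 * pt(-abs(t), df))
}

# two-sided F test of variance equality, textbook form
oracle_f_test <- function(x, y) {
  f <- var(x) / var(y)
  df1 <- length(x) - 1
  df2 <- length(y) - 1
  p <- 2 * min(pf(f, df1, df2), 1 - pf(f, df1, df2))
  list(f = f, p = min(p, 1))
}

# one-way ANOVA by explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_b <- 0
  ss_w <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - gm)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  df_b <- length(unique(groups)) - 1
  df_w <- length(values) - length(unique(groups))
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# random discrete distribution on a jittered lattice
random_distribution <- function(n_points = NULL, value_col = "dcag") {
  if (is.null(n_points)) n_points <- sample(2:40, 1)
  x <- sort(sample(seq(-20, 40), n_points)) + rnorm(n_points, 0, 0.05)
  w <- rexp(n_points) + 1e-3
  out <- tibble::tibble(v = x, weight = w / sum(w))
  names(out)[1] <- value_col
  out
}
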