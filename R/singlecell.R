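## Asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^{k-1}
## exp(-2 k^2 lambda^2)
.kolmogorovQ <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sample points of the absolute difference
#' between the two empirical CDFs (ties allowed: both ECDFs are evaluated at
#' the sorted union of observed values). The p-value uses the asymptotic
#' Kolmogorov distribution with effective size `n_x * n_y / (n_x + n_y)`;
#' for small samples (`n_x * n_y <= exact_limit`) the exact null
#' distribution is used instead (conditional on ties when present).
#'
#' @param x,y numeric samples (non-empty, finite).
#' @param exact_limit use the exact p-value when `n_x * n_y` is at most this
#'   (default 10^4); set 0 to force the asymptotic form.
#' @return list with `statistic` (D), `p_value`, `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' ksTwoSample(c(1, 3), c(2, 4))$statistic  # 0.5
ksTwoSample <- function(x, y, exact_limit = 1e4) {
  .checkTrue(length(x) >= 1 && length(y) >= 1, "samples must be non-empty")
  .checkTrue(all(is.finite(x)) && all(is.finite(y)),
             "samples must be finite")
  nx <- length(x); ny <- length(y)
  pts <- sort(unique(c(x, y)))
  Fx <- findInterval(pts, sort(x)) / nx
  Fy <- findInterval(pts, sort(y)) / ny
  D <- max(abs(Fx - Fy))
  if (nx * ny <= exact_limit) {
    p <- stats::psmirnov(D, sizes = c(nx, ny), z = c(x, y),
                         two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
    method <- "exact"
  } else {
    n_eff <- nx * ny / (nx + ny)
    p <- .kolmogorovQ(sqrt(n_eff) * D)
    method <- "asymptotic"
  }
  list(statistic = D, p_value = p, n_x = nx, n_y = ny, method = method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties share the mean rank).
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return rho in `[-1, 1]`, or `NA` (with a warning) when either vector has
#'   zero rank variance.
#' @export
#' @examples
#' spearmanRho(1:5, c(2, 4, 6, 8, 10))  # 1
spearmanRho <- function(x, y) {
  .checkTrue(length(x) == length(y), "x and y must be paired")
  .checkTrue(length(x) >= 3, "need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("zero rank variance: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Compare single-cell feature distributions between conditions
#'
#' For each condition versus the reference: the two-sample KS statistic and
#' p-value on the per-cell feature values, the mean difference, and the
#' variance ratio (condition / reference) -- the latter quantifying
#' population-variability changes that a mean alone would miss.
#'
#' @param cells data.frame of per-cell values with a condition column.
#' @param feature feature column to compare (e.g. `"circularity"`, `"area"`).
#' @param reference reference condition label.
#' @param condition_col name of the condition column.
#' @param ... passed to [ksTwoSample()].
#' @return data.frame per non-reference condition: `condition`, `n`,
#'   `n_reference`, `ks_D`, `p_value`, `mean_diff`, `variance_ratio`.
#' @export
#' @examples
#' cells <- data.frame(
#'   condition = rep(c("WT", "MUT"), each = 100),
#'   circularity = c(rnorm(100, 0.9, 0.04), rnorm(100, 0.8, 0.08)))
#' compareConditions(cells, "circularity", reference = "WT")
compareConditions <- function(cells, feature, reference,
                              condition_col = "condition", ...) {
  .checkTrue(condition_col %in% names(cells), "no condition column '",
             condition_col, "'")
  .checkTrue(feature %in% names(cells), "no feature column '", feature, "'")
  conds <- unique(cells[[condition_col]])
  if (!reference %in% conds) {
    stop("unknown reference condition '", reference, "'", call. = FALSE)
  }
  ref <- cells[cells[[condition_col]] == reference, feature]
  .checkTrue(length(ref) >= 1 && all(is.finite(ref)),
             "reference sample must be non-empty and finite")
  out <- lapply(setdiff(conds, reference), function(cd) {
    v <- cells[cells[[condition_col]] == cd, feature]
    ks <- ksTwoSample(v, ref, ...)
    data.frame(condition = cd, n = length(v), n_reference = length(ref),
               ks_D = ks$statistic, p_value = ks$p_value,
               mean_diff = mean(v) - mean(ref),
               variance_ratio = stats::var(v) / stats::var(ref),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
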