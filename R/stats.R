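#' Clinical reference range of a parameter
#'
#' Median and 2.5th/97.5th percentiles, the standard central-95% reference
#' interval of clinical chemistry. Percentiles are linearly interpolated
#' between order statistics at position `1 + (n - 1) * p` (the default
#' sample-quantile definition, `type = 7`); this choice is fixed so that
#' ranges are reproducible across implementations.
#'
#' @param values Numeric vector; missing values are dropped.
#' @return Object of class `reference_range`: list with `median`, `p2_5`,
#'   `p97_5`, `n`.
#' @examples
#' reference_range(1:40)  # p2.5 = 1.975, p97.5 = 39.025
#' @export
reference_range <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("reference_range needs at least 2 non-missing values")
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  structure(list(median = q[2L], p2_5 = q[1L], p97_5 = q[3L],
                 n = length(values)),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("<reference_range> median %.4g [%.4g, %.4g] (n = %d)\n",
              x$median, x$p2_5, x$p97_5, x$n))
  invisible(x)
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2L], q1 = q[1L], q3 = q[3L])
}

# Dunn's z-statistics for unpaired groups: pooled mid-ranks with tie
# correction; two-sided normal p-values, family-wise adjustment over pairs.
dunn_unpaired <- function(values, labels, p_adjust = "bonferroni") {
  N <- length(values)
  r <- rank(values)
  groups <- split(r, labels)
  nbar <- vapply(groups, length, 0L)
  rbar <- vapply(groups, mean, 0)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  gn <- names(groups)
  pairs <- utils::combn(gn, 2)
  z <- apply(pairs, 2, function(pr) {
    if (v0 <= 0) return(0)  # every observation tied: no rank information
    (rbar[pr[1L]] - rbar[pr[2L]]) /
      sqrt(v0 * (1 / nbar[pr[1L]] + 1 / nbar[pr[2L]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = unname(z),
             p_unadjusted = unname(p),
             p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

# Dunn's z-statistics after a Friedman test: within-block ranks, variance
# k(k+1) / (6 n) for mean ranks.
dunn_paired <- function(mat, p_adjust = "bonferroni") {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1L, rank))
  rbar <- colMeans(R)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(colnames(mat), 2)
  z <- apply(pairs, 2, function(pr) (rbar[pr[1L]] - rbar[pr[2L]]) / se)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = unname(z),
             p_unadjusted = unname(p),
             p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Paired comparison of conditions across subjects
#'
#' Friedman omnibus test on complete cases, followed by Dunn's pairwise
#' z-tests on within-block mean ranks with family-wise adjustment
#' (Bonferroni by default, matching the common "Dunn's multiple comparison"
#' convention).
#'
#' @param table Data frame; rows are subjects.
#' @param columns Names of >= 3 numeric columns (the paired conditions).
#' @param p_adjust Adjustment method for [stats::p.adjust()].
#' @return Object of class `paired_comparison`: list with `statistic`
#'   (Friedman chi-squared), `df`, `p_value`, `n` (complete cases used),
#'   `n_dropped`, `summary` (median/IQR per column) and `pairwise` (Dunn
#'   table).
#' @export
compare_paired <- function(table, columns, p_adjust = "bonferroni") {
  stopifnot(is.data.frame(table))
  if (length(columns) < 3L)
    stop("the Friedman omnibus test needs >= 3 paired columns")
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  mat <- as.matrix(table[, columns])
  keep <- stats::complete.cases(mat)
  dropped <- sum(!keep)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 3L)
    stop("fewer than 3 complete subjects after dropping missing rows")
  ft <- stats::friedman.test(mat)
  stat <- unname(ft$statistic)
  pval <- ft$p.value
  if (is.nan(stat)) {  # zero rank variance (identical columns): null result
    stat <- 0
    pval <- 1
  }
  summ <- t(apply(mat, 2L, med_iqr))
  structure(list(statistic = stat, df = unname(ft$parameter),
                 p_value = pval, n = nrow(mat), n_dropped = dropped,
                 summary = summ,
                 pairwise = dunn_paired(mat, p_adjust)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> Friedman chi^2 = %.3f (df %d), p = %.3g, n = %d\n",
              x$statistic, x$df, x$p_value, x$n))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Unpaired comparison of independent groups
#'
#' Kruskal--Wallis omnibus test followed by Dunn's pairwise z-tests on
#' pooled mean ranks (tie-corrected) with family-wise adjustment. The
#' canonical use is comparing men, women without oral contraceptives, and
#' women using them.
#'
#' @param values Numeric vector of observations.
#' @param labels Group labels, same length; >= 2 groups with >= 2
#'   observations each.
#' @param p_adjust Adjustment method for [stats::p.adjust()].
#' @return Object of class `group_comparison`: list with `statistic`
#'   (Kruskal--Wallis H), `df`, `p_value`, `summary` (n and median/IQR per
#'   group), `pairwise` (Dunn table).
#' @export
compare_groups <- function(values, labels, p_adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels[keep])
  counts <- table(labels)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 groups with >= 2 observations each; got counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  kw <- stats::kruskal.test(values, factor(labels))
  stat <- unname(kw$statistic)
  pval <- kw$p.value
  if (is.nan(stat)) {  # all observations tied: no evidence against the null
    stat <- 0
    pval <- 1
  }
  summ <- do.call(rbind, lapply(split(values, labels), med_iqr))
  summ <- cbind(n = as.integer(counts[rownames(summ)]), summ)
  structure(list(statistic = stat, df = unname(kw$parameter),
                 p_value = pval, summary = summ,
                 pairwise = dunn_unpaired(values, labels, p_adjust)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis H = %.3f (df %d), p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Shapiro--Wilk normality check
#'
#' Thin wrapper with explicit handling of the degenerate constant-vector
#' case (W is undefined; a flagged result is returned rather than an error,
#' so batch summaries keep running).
#'
#' @param values Numeric vector, 3 <= n <= 5000 after dropping missing.
#' @return List with `statistic` (W), `p_value`, `n`, `degenerate`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (diff(range(values)) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value, n = n,
       degenerate = FALSE)
}
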