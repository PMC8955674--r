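#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact null distribution when the smaller group has at most
#' `exact_max_n` observations and the pooled data are tie-free;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction). The small-sample exact cutoff matches study designs with
#' 4--8 animals per group.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_max_n Largest min(n) for which the exact distribution is
#'   used.
#' @return A list of class `hrv_test` with `statistic` (U), `p_value`,
#'   `group_sizes` and `method`.
#' @export
mann_whitney <- function(a, b, exact_max_n = 8L) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= exact_max_n
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 adjusted_p = NULL,
                 group_sizes = c(length(a), length(b)),
                 method = if (exact) "mann_whitney_exact"
                          else "mann_whitney_normal_tie_corrected"),
            class = "hrv_test")
}

#' Kruskal-Wallis rank test across two or more groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom. When every value across every group is
#' identical there is no rank separation at all: H = 0 and p = 1 are
#' returned rather than an error.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return A list of class `hrv_test` with `statistic` (H), `p_value`,
#'   `group_sizes` and `method`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need >= 2 non-empty groups", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  if (length(unique(vals)) == 1L) {
    h <- 0; p <- 1
  } else {
    g <- factor(rep.int(seq_along(groups), sizes))
    kt <- stats::kruskal.test(vals, g)
    h <- unname(kt$statistic); p <- kt$p.value
  }
  structure(list(statistic = h, p_value = p, adjusted_p = NULL,
                 group_sizes = unname(sizes), method = "kruskal_wallis"),
            class = "hrv_test")
}

#' Bonferroni multiple-comparison adjustment
#'
#' `min(1, p * m)` per p-value; `m` defaults to the number of
#' comparisons supplied.
#'
#' @param p_values Numeric vector of p-values (possibly empty).
#' @param m Number of comparisons.
#' @return Adjusted p-values, same length as the input.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (!length(p_values)) return(numeric(0))
  pmin(1, p_values * m)
}

#' Pairwise post hoc comparisons after Kruskal-Wallis
#'
#' Pairwise Mann-Whitney tests over all group pairs, Bonferroni-adjusted
#' for the number of pairs.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame with one row per pair: `group1`, `group2`, `U`,
#'   `p_value`, `adjusted_p`.
#' @export
posthoc_pairwise <- function(groups) {
  stopifnot(length(groups) >= 2L)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  res <- apply(pairs, 2L, function(ij) {
    t <- mann_whitney(groups[[ij[1L]]], groups[[ij[2L]]])
    c(t$statistic, t$p_value)
  })
  out <- data.frame(group1 = nms[pairs[1L, ]], group2 = nms[pairs[2L, ]],
                    U = res[1L, ], p_value = res[2L, ],
                    stringsAsFactors = FALSE)
  out$adjusted_p <- bonferroni(out$p_value)
  out
}

#' Group summary as mean and standard error of the mean
#'
#' @param values Non-empty numeric vector.
#' @return A list of class `group_summary` with `mean`, `sem`
#'   (sample sd / sqrt(n); 0 with a warning when n = 1) and `n`.
#' @export
summarize_group <- function(values) {
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  n <- length(values)
  sem <- if (n == 1L) {
    warning("SEM undefined for a single observation; reporting 0",
            call. = FALSE)
    0
  } else stats::sd(values) / sqrt(n)
  structure(list(mean = mean(values), sem = sem, n = n),
            class = "group_summary")
}

#' @export
print.hrv_test <- function(x, ...) {
  cat(sprintf("<hrv_test> %s: statistic %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}
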