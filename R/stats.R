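# Nonparametric group statistics: Kruskal-Wallis, Dunn's post hoc with Holm
# adjustment, Wilcoxon signed-rank. Outputs are tidy StatResult tibbles.

#' Kruskal-Wallis rank-sum test
#'
#' Compares a metric across groups with the midrank-tie-corrected H
#' statistic, referred to a chi-square distribution with k - 1 degrees of
#' freedom. If every value is identical, H = 0 and p = 1.
#'
#' @param data A data frame of per-animal values.
#' @param value,group Unquoted column names of the metric and grouping
#'   variable.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p`, `n`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' kruskal_wallis(d, y, g)  # H = 3.857
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(v) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(v)) == 1) {
    return(tibble::tibble(test = "kruskal_wallis", statistic = 0,
                          df = nlevels(g) - 1, p = 1, n = length(v)))
  }
  kt <- stats::kruskal.test(v, g)
  tibble::tibble(test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p = kt$p.value,
                 n = length(v))
}

#' Dunn's multiple-comparison post hoc test
#'
#' Pairwise mean-rank comparisons after a Kruskal-Wallis test. For groups i
#' and j, `z = (Ri - Rj) / SE` with
#' `SE = sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))` where `Ri` are mean
#' midranks over the pooled sample and `T = sum(t^3 - t)` over tie groups.
#' P-values are two-sided normal; the Holm family is the full set of pairwise
#' comparisons of the metric.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"holm"` (default) or `"none"`.
#' @return A tibble with one row per pair: `test`, `group1`, `group2`,
#'   `statistic` (z), `p`, `p_adj`, `n1`, `n2`, `stars`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' dunn_posthoc(d, y, g)  # z = 1.964
#' @export
dunn_posthoc <- function(data, value, group, adjust = c("holm", "none")) {
  adjust <- match.arg(adjust)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  N <- length(v)
  r <- rank(v)  # midranks
  ties <- table(r)
  Tsum <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - Tsum / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(var_term * (1 / ns[[a]] + 1 / ns[[b]]))
    # sign convention: positive when group2 has the higher mean rank
    z <- if (se > 0) (mr[[b]] - mr[[a]]) / se else 0
    tibble::tibble(test = "dunn", group1 = a, group2 = b,
                   statistic = z, p = 2 * stats::pnorm(-abs(z)),
                   n1 = ns[[a]], n2 = ns[[b]])
  })
  res$p_adj <- if (adjust == "holm") holm_adjust(res$p) else res$p
  res$stars <- p_stars(res$p_adj)
  res[, c("test", "group1", "group2", "statistic", "p", "p_adj",
          "n1", "n2", "stars")]
}

#' Holm step-down p-value adjustment
#'
#' Sort ascending, multiply the i-th smallest of m p-values by (m - i + 1),
#' enforce a running maximum, cap at 1, and return in the input order. Output
#' is always elementwise >= input and monotone in the input ranks.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "holm")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests for a symmetric shift between paired measurements. Zero differences
#' are dropped before ranking (|differences| are midranked, so ties are
#' handled throughout). With n <= 12 informative pairs the exact two-sided p
#' is computed by enumerating all 2^n sign patterns of the midranks; beyond
#' that, the normal approximation with continuity correction and
#' tie-corrected variance is used. The reported `statistic` is the smaller of
#' the positive- and negative-rank sums.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A one-row tibble: `test`, `statistic` (W), `p`, `n` (informative
#'   pairs), `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))  # W = 0, p = 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(test = "wilcoxon_signed_rank", statistic = 0,
                          p = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- min(sum(r[d > 0]), sum(r[d < 0]))
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_plus <- as.vector(signs %*% r)
    w_all <- pmin(w_plus, sum(r) - w_plus)
    p <- mean(w_all <= W + 1e-9)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x = d, mu = 0, exact = FALSE, correct = TRUE)$p.value
    )
    method <- "normal"
  }
  tibble::tibble(test = "wilcoxon_signed_rank", statistic = W, p = p,
                 n = n, method = method)
}

#' Significance stars
#'
#' The conventional star coding: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}
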