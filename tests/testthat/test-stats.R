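# Independent oracles used throughout this file -------------------------------

# Kruskal-Wallis H from first principles (midranks, tie correction)
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
wsr_oracle_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- apply(signs, 1, function(s) {
    wp <- sum(r[s == 1])
    min(wp, total - wp)
  })
  mean(w_all <= w_obs)
}

# ------------------------------------------------------------------------------

test_that("Kruskal-Wallis reproduces the hand-computed two-group H", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  res <- kruskal_wallis(d, y, g)
  # H = (12/42)(36/3 + 225/3) - 21 = 3.857
  expect_equal(res$statistic, 3.857, tolerance = 5e-4)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
})

test_that("identical groups give H = 0, p = 1", {
  d <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(2.5, 8))
  res <- kruskal_wallis(d, y, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("Kruskal-Wallis matches the midrank oracle on tied small samples", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:4, sample(2:4, 1), replace = TRUE))  # heavy ties, N <= 10 regime
    d <- data.frame(y = unlist(groups),
                    g = rep(letters[seq_len(k)], lengths(groups)))
    if (length(unique(d$y)) == 1) next
    expect_equal(kruskal_wallis(d, y, g)$statistic, kw_oracle(groups),
                 tolerance = 1e-10)
  }
})

test_that("Dunn z and p reproduce the hand computation", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  res <- dunn_posthoc(d, y, g, adjust = "none")
  # z = (5 - 2) / sqrt((6*7/12) * (2/3)) = 1.964
  expect_equal(res$statistic, 1.964, tolerance = 5e-4)
  expect_lt(abs(res$p - 0.0495), 5e-4)
  same <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(1:3, 2))
  res2 <- dunn_posthoc(same, y, g, adjust = "none")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
})

test_that("Dunn-Holm equals composing raw Dunn with holm_adjust", {
  set.seed(11)
  d <- data.frame(g = rep(letters[1:4], each = 5), y = rnorm(20))
  raw <- dunn_posthoc(d, y, g, adjust = "none")
  adj <- dunn_posthoc(d, y, g, adjust = "holm")
  expect_equal(adj$p_adj, holm_adjust(raw$p))
  expect_equal(nrow(adj), choose(4, 2))
  expect_true(all(adj$p_adj >= adj$p))
})

test_that("Holm step-down follows the worked example and its invariants", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.5), 0.5)
  expect_error(holm_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    out <- holm_adjust(p)
    expect_true(all(out >= p))
    expect_true(all(out <= 1))
    perm <- sample(seq_along(p))
    expect_equal(holm_adjust(p[perm]), out[perm])
    # monotone in the input order statistics
    expect_true(all(diff(out[order(p)]) >= 0))
  }
})

test_that("signed-rank test: all-positive differences give W = 0, p = 1/16", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.0625)
  expect_equal(res$method, "exact")
  same <- wilcoxon_signed_rank(1:6, 1:6)
  expect_equal(same$p, 1)
})

test_that("signed-rank exact path equals the enumeration oracle", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p, wsr_oracle_p(x - y), tolerance = 1e-10)
    # midrank ties are enumerated too
    res_t <- wilcoxon_signed_rank(round(x, 1), round(y, 1))
    d_t <- round(x, 1) - round(y, 1)
    if (any(d_t != 0)) expect_equal(res_t$p, wsr_oracle_p(d_t),
                                    tolerance = 1e-10)
  }
})

test_that("signed-rank normal approximation tracks the exact law", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(13, 0.4)
    y <- rnorm(13)
    res <- wilcoxon_signed_rank(x, y)  # n = 13 forces the normal path
    expect_equal(res$method, "normal")
    expect_lt(abs(res$p - wsr_oracle_p(x - y)), 0.02)
  }
})

test_that("significance stars follow the published convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
               c("ns", "*", "**", "***", "****"))
})
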