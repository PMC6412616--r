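# Rank-based statistics used for the score-vs-MBG association and the
# motion-correction analysis. Ties are handled by mid-ranks throughout.
# Each function returns a one-row tibble (method, statistic, p_value, n)
# so results stack naturally into reporting tables.

stat_result <- function(method, statistic, p_value, n, ...) {
  out <- tibble(method = method, statistic = statistic, p_value = p_value,
                n = as.integer(n), ...)
  class(out) <- c("qube_stat", class(out))
  out
}

#' Spearman rank correlation between scores and grades
#'
#' Mid-rank rho with a two-sided p-value from the t approximation
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df). If all grades (or
#' all scores) are identical, the association is undefined and both
#' statistic and p-value are flagged missing.
#'
#' @param scores Numeric vector.
#' @param grades Integer vector (e.g. MBG 0-3), same length (>= 4).
#' @return A one-row tibble: `method`, `statistic` (rho), `p_value`, `n`.
#' @export
spearman_association <- function(scores, grades) {
  if (length(scores) != length(grades)) {
    abort_content("`scores` and `grades` lengths differ")
  }
  n <- length(scores)
  if (n < 4L) abort_content("spearman_association needs >= 4 pairs")
  if (length(unique(grades)) < 2L || length(unique(scores)) < 2L) {
    return(stat_result("spearman (t approximation)", NA_real_, NA_real_, n))
  }
  rho <- cor(rank(scores), rank(grades))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  stat_result("spearman (t approximation)", rho, p, n)
}

#' Kruskal-Wallis test across grade groups
#'
#' H with the usual tie correction and a chi-square p-value on `k - 1`
#' degrees of freedom (delegates to [stats::kruskal.test()]). The
#' degenerate case of all values identical across groups is reported as
#' `H = 0`, `p = 1`.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return A one-row tibble: `method`, `statistic` (H), `p_value`, `n`,
#'   `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[vapply(groups, length, 0L) > 0L]
  if (length(groups) < 2L) {
    abort_content("kruskal_wallis needs >= 2 non-empty groups")
  }
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 5L) abort_content("kruskal_wallis needs total n >= 5")
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L) {
    return(stat_result("kruskal-wallis", 0, 1, n, df = df))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  kt <- stats::kruskal.test(x, g)
  stat_result("kruskal-wallis", unname(kt$statistic), kt$p.value, n, df = df)
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments, per Lin's original estimator; the
#' sample (n-1) variant is available via `moments = "sample"`. Undefined
#' (flagged `NA`) when both vectors are constant with equal means.
#'
#' @param x,y Numeric vectors of equal length (>= 2), e.g. two observers'
#'   scores for the same patients.
#' @param moments `"population"` (default) or `"sample"`.
#' @return A single value in `[-1, 1]`, or `NA`.
#' @export
lin_ccc <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  if (length(x) != length(y)) abort_content("`x` and `y` lengths differ")
  n <- length(x)
  if (n < 2L) abort_content("lin_ccc needs >= 2 pairs")
  mx <- mean(x); my <- mean(y)
  denom_n <- if (moments == "population") n else n - 1L
  sxy <- sum((x - mx) * (y - my)) / denom_n
  sxx <- sum((x - mx)^2) / denom_n
  syy <- sum((y - my)^2) / denom_n
  den <- sxx + syy + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * sxy / den
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (classical Wilcoxon convention, count
#' logged via a message), tied absolute differences get mid-ranks. The
#' two-sided p-value is exact for n <= 25 (distribution of the positive
#' rank sum over all 2^n sign patterns, computed by dynamic programming
#' so ties are handled exactly), and uses the normal approximation with
#' tie correction and continuity correction for n > 25. All-zero
#' differences give statistic 0 and p = 1.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A one-row tibble: `method`, `statistic` (V, positive rank
#'   sum), `p_value`, `n` (non-zero pairs), `n_zero`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) abort_content("`x` and `y` lengths differ")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n_zero > 0 && n > 0) {
    inform(sprintf("wilcoxon_signed_rank: dropped %d zero difference(s)", n_zero))
  }
  if (n == 0L) {
    return(stat_result("wilcoxon signed-rank", 0, 1, 0L, n_zero = n_zero))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    # exact: distribution of V over all sign patterns, ranks doubled so
    # mid-ranks (k + 0.5) become integers
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    dist <- numeric(tot + 1L)
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(tot + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- round(2 * v)
    p_le <- sum(dist[seq_len(v2 + 1L)])
    p_ge <- sum(dist[(v2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "wilcoxon signed-rank (normal approximation)"
  }
  stat_result(method, v, p, n, n_zero = n_zero)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation of order statistics (the inclusive
#' method, `stats::quantile()` type 7).
#'
#' @param values Non-empty numeric vector.
#' @return A named numeric vector `c(median, q1, q3)`.
#' @export
summarize_median_iqr <- function(values) {
  if (length(values) == 0L) abort_content("empty value vector")
  if (anyNA(values)) {
    n_na <- sum(is.na(values))
    inform(sprintf("summarize_median_iqr: skipping %d missing value(s)", n_na))
    values <- values[!is.na(values)]
    if (length(values) == 0L) abort_content("all values missing")
  }
  q <- unname(quantile(values, c(0.5, 0.25, 0.75), type = 7))
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}
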