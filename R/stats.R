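#' Division symmetry from daughter apical-domain calls
#'
#' A division is symmetric when both daughters carry the re-formed apical
#' domain at the 16-cell stage, asymmetric when exactly one does. Divisions
#' where neither daughter is polar are anomalous: they are recorded but
#' excluded from the two-class symmetry table.
#'
#' @param d1_polar,d2_polar daughter apical-domain flags.
#' @return `"symmetric"`, `"asymmetric"` or `"anomalous"` (vectorized).
#' @export
division_symmetry <- function(d1_polar, d2_polar) {
  stopifnot(length(d1_polar) == length(d2_polar))
  if (any(is.na(d1_polar) | is.na(d2_polar)))
    stopf("both daughters must be observed post-division")
  n_polar <- d1_polar + d2_polar
  c("anomalous", "asymmetric", "symmetric")[n_polar + 1L]
}

#' Trophectoderm fate assignment
#'
#' A 16-cell-stage daughter is trophectoderm iff it is an outer cell and
#' marker-positive; all other combinations are inner cell mass.
#'
#' @param position `"outer"` or `"inner"` (vectorized).
#' @param marker_positive logical.
#' @return `"TE"` or `"ICM"`.
#' @export
te_assignment <- function(position, marker_positive) {
  if (any(is.na(position)))
    stopf("unassigned fate: missing position")
  if (!all(position %in% c("outer", "inner")))
    stopf("position must be 'outer' or 'inner'")
  ifelse(position == "outer" & marker_positive, "TE", "ICM")
}

#' Two-group proportion table
#'
#' Counts and percentages of a binary outcome per group, as reported in
#' contingency-figure legends (percentages to one decimal for display).
#'
#' @param group group labels (two levels).
#' @param success logical outcome per record.
#' @return a `proportion_table`: data.frame with `group`, `successes`, `n`,
#'   `percent`.
#' @export
proportion_table <- function(group, success) {
  stopifnot(length(group) == length(success))
  if (length(group) == 0L) stopf("undefined proportion: empty group")
  levels <- unique(group)
  n <- vapply(levels, function(g) sum(group == g), integer(1))
  if (any(n == 0L)) stopf("undefined proportion: empty group")
  x <- vapply(levels, function(g) sum(success[group == g]), integer(1))
  structure(data.frame(group = levels, successes = x, n = n,
                       percent = 100 * x / n, row.names = NULL),
            class = c("proportion_table", "data.frame"))
}

#' @export
print.proportion_table <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s: %d / %d (%.1f%%)\n", x$group[i], x$successes[i],
                x$n[i], x$percent[i]))
  invisible(x)
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-tailed p-value is the sum of
#' probabilities of all tables (with the observed margins) as or less
#' probable than the observed one.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return a list: `p_value`, `odds_ratio` (conditional MLE), `counts`.
#' @export
#' @examples
#' fisher_exact(matrix(c(33, 77, 13, 122), 2))$p_value   # < 1e-4
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stopf("counts must be a 2x2 table")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stopf("invalid input: counts must be non-negative integers")
  ft <- stats::fisher.test(round(counts), alternative = "two.sided")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       counts = round(counts))
}

#' Two-proportion z-test (pooled)
#'
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`; two-tailed p from the standard normal.
#'
#' @param x1,n1 successes and size of group 1.
#' @param x2,n2 successes and size of group 2.
#' @return a list: `z`, `p_value`, `p1`, `p2`.
#' @export
#' @examples
#' two_proportion_ztest(73, 385, 37, 377)$p_value   # < 0.01
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stopf("invalid input: group sizes must be positive")
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    stopf("degenerate test: pooled proportion is 0 or 1")
  z <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = x1 / n1, p2 = x2 / n2)
}

#' Test whether early polarization is a cell-autonomous (independent) event
#'
#' Under cell autonomy, the number of early-polarizing cells per embryo is
#' Binomial(cells_per_embryo, p). The per-cell rate is estimated from the
#' pooled data and goodness of fit is assessed by a Monte-Carlo chi-square:
#' the null distribution of the statistic is obtained by parametric bootstrap
#' (re-estimating the rate in each replicate), which respects the small
#' expected counts in the upper categories.
#'
#' @param ep_counts early-polarizing cell count per embryo.
#' @param cells_per_embryo cells per embryo (default 8).
#' @param n_boot bootstrap replicates (default 10000).
#' @param min_embryos minimum number of embryos (default 10).
#' @return a list: `p_hat`, `statistic`, `p_value`, `observed`, `expected`
#'   (per count category 0..cells_per_embryo), `n_embryos`. Degenerate inputs
#'   (`p_hat` 0 or 1) return `p_value = NA` with a message field.
#' @export
binomial_independence_test <- function(ep_counts, cells_per_embryo = 8L,
                                       n_boot = 10000L, min_embryos = 10L) {
  n_emb <- length(ep_counts)
  if (n_emb < min_embryos)
    stopf("insufficient data: need at least %d embryos, got %d",
          min_embryos, n_emb)
  if (any(ep_counts < 0 | ep_counts > cells_per_embryo))
    stopf("invalid input: counts must lie in 0..cells_per_embryo")
  p_hat <- sum(ep_counts) / (cells_per_embryo * n_emb)
  cats <- 0:cells_per_embryo
  obs <- tabulate(ep_counts + 1L, nbins = cells_per_embryo + 1L)
  if (p_hat <= 0 || p_hat >= 1) {
    return(list(p_hat = p_hat, statistic = NA_real_, p_value = NA_real_,
                observed = obs,
                expected = n_emb * stats::dbinom(cats, cells_per_embryo, p_hat),
                n_embryos = n_emb,
                message = "degenerate: all-or-none polarization, test skipped"))
  }
  chisq_stat <- function(counts, p) {
    exp_counts <- n_emb * stats::dbinom(cats, cells_per_embryo, p)
    keep <- exp_counts > 0
    sum((counts[keep] - exp_counts[keep])^2 / exp_counts[keep])
  }
  stat_obs <- chisq_stat(obs, p_hat)
  stat_null <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sim <- stats::rbinom(n_emb, cells_per_embryo, p_hat)
    p_b <- sum(sim) / (cells_per_embryo * n_emb)
    stat_null[b] <- chisq_stat(tabulate(sim + 1L,
                                        nbins = cells_per_embryo + 1L), p_b)
  }
  list(p_hat = p_hat, statistic = stat_obs,
       p_value = (1 + sum(stat_null >= stat_obs)) / (1 + n_boot),
       observed = obs,
       expected = n_emb * stats::dbinom(cats, cells_per_embryo, p_hat),
       n_embryos = n_emb)
}

#' D'Agostino K-squared normality test
#'
#' Omnibus test combining the skewness and kurtosis z-transformations;
#' `K2 = Z1(g1)^2 + Z2(g2)^2` is referred to a chi-square with 2 degrees of
#' freedom.
#'
#' @param x numeric sample (n >= 9).
#' @return a list: `statistic`, `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 9L) stopf("normality untestable: need n >= 9, got %d", n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stopf("normality untestable: zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness transformation (D'Agostino)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transformation (Anscombe-Glynn)
  e_g2 <- 3 * (n - 1) / (n + 1)
  v_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - e_g2) / sqrt(v_g2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Select the statistical test for a group comparison
#'
#' Decision tree: each group is checked for normality with the D'Agostino
#' K-squared test (alpha 0.05). If all groups look normal, two groups are
#' compared with a two-tailed t-test (Welch correction when an F-test finds
#' unequal variances at 0.05) and more than two groups with one-way ANOVA.
#' Otherwise the rank-based analogues are used: Mann-Whitney U for two
#' groups, Kruskal-Wallis with Dunn's post-hoc for more. Groups too small for
#' normality testing (n < 8) default to the rank-based branch.
#'
#' @param samples a list of numeric vectors, one per group.
#' @param alpha significance level for the normality and variance checks.
#' @return a list: `test` (name), `normal` (per-group flags or NA),
#'   `welch` (for the t-test branch), `note`.
#' @export
test_selector <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  k <- length(samples)
  ns <- lengths(samples)
  if (any(ns < 8L)) {
    test <- if (k == 2L) "Mann-Whitney U" else "Kruskal-Wallis + Dunn"
    return(list(test = test, normal = rep(NA, k), welch = NA,
                note = "group below n = 8: normality untestable, rank-based test used"))
  }
  normal <- vapply(samples, function(s) dagostino_k2(s)$p_value > alpha,
                   logical(1))
  if (all(normal)) {
    if (k == 2L) {
      vr <- stats::var.test(samples[[1]], samples[[2]])
      welch <- vr$p.value < alpha
      list(test = if (welch) "Welch t-test" else "t-test",
           normal = normal, welch = welch, note = NA_character_)
    } else {
      list(test = "one-way ANOVA", normal = normal, welch = NA,
           note = NA_character_)
    }
  } else {
    list(test = if (k == 2L) "Mann-Whitney U" else "Kruskal-Wallis + Dunn",
         normal = normal, welch = NA, note = NA_character_)
  }
}
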