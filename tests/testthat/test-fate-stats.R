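test_that("division symmetry follows apical-domain inheritance", {
  expect_equal(division_symmetry(TRUE, TRUE), "symmetric")
  expect_equal(division_symmetry(TRUE, FALSE), "asymmetric")
  expect_equal(division_symmetry(FALSE, TRUE), "asymmetric")
  expect_equal(division_symmetry(FALSE, FALSE), "anomalous")
  expect_equal(division_symmetry(c(TRUE, FALSE), c(TRUE, FALSE)),
               c("symmetric", "anomalous"))
  expect_error(division_symmetry(TRUE, NA), "observed")
})

test_that("trophectoderm assignment needs outer position and marker", {
  expect_equal(te_assignment("outer", TRUE), "TE")
  expect_equal(te_assignment("inner", TRUE), "ICM")
  expect_equal(te_assignment("outer", FALSE), "ICM")
  expect_equal(te_assignment(c("outer", "inner"), c(TRUE, TRUE)),
               c("TE", "ICM"))
  expect_error(te_assignment(NA_character_, TRUE), "unassigned")
  expect_error(te_assignment("middle", TRUE), "outer")
})

test_that("proportion tables reproduce published contingency percentages", {
  grp <- c(rep("EP", 46), rep("LP", 199))
  sym <- c(rep(TRUE, 33), rep(FALSE, 13), rep(TRUE, 77), rep(FALSE, 122))
  tab <- proportion_table(grp, sym)
  expect_equal(round(tab$percent[tab$group == "EP"], 1), 71.7)
  expect_equal(round(tab$percent[tab$group == "LP"], 1), 38.7)

  tab0 <- proportion_table(rep("A", 10), rep(FALSE, 10))
  expect_equal(tab0$percent, 0)
  expect_error(proportion_table(character(0), logical(0)),
               "empty group")
})

test_that("Fisher's exact test matches fixed-margin enumeration", {
  # published symmetry and fate tables reach their printed significance
  expect_lt(fisher_exact(matrix(c(33, 77, 13, 122), 2))$p_value, 1e-4)
  p_te <- fisher_exact(matrix(c(72, 188, 15, 87), 2))$p_value
  expect_lt(p_te, 0.01)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")

  # exhaustive agreement with the enumeration oracle on small tables
  for (n in c(8, 12, 16)) {
    for (a in 0:min(n, 6)) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      m <- matrix(c(a, cc, b, n - a - b - cc), 2)
      expect_equal(fisher_exact(m)$p_value, fisher_enum(m),
                   tolerance = 1e-10)
    }
  }
  # random tables up to total 60
  set.seed(19)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    m <- matrix(c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2],
                  n - cuts[3]), 2)
    expect_equal(fisher_exact(m)$p_value, fisher_enum(m), tolerance = 1e-10)
  }
})

test_that("the pooled z-test matches its closed form and prop.test", {
  r <- two_proportion_ztest(73, 385, 37, 377)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$z, 0)
  r2 <- two_proportion_ztest(35, 140, 16, 120)
  expect_lt(r2$p_value, 0.05)
  # equal proportions, equal n: z = 0, p = 1
  r0 <- two_proportion_ztest(20, 100, 20, 100)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)
  # cross-check: uncorrected chi-square equals z^2
  pt <- prop.test(c(73, 37), c(385, 377), correct = FALSE)
  expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(r$p_value, pt$p.value, tolerance = 1e-9)

  expect_error(two_proportion_ztest(0, 10, 0, 12), "degenerate")
  expect_error(two_proportion_ztest(1, 0, 1, 5), "positive")
})

test_that("the binomial independence test flags structured counts", {
  set.seed(3)
  # i.i.d. per-cell polarization: no rejection expected
  iid <- rbinom(300, 8, 0.15)
  r <- binomial_independence_test(iid, n_boot = 2000)
  expect_gt(r$p_value, 0.01)
  expect_equal(r$p_hat, sum(iid) / (8 * 300))

  # severe underdispersion (every embryo exactly 4 of 8) is rejected
  r2 <- binomial_independence_test(rep(4L, 60), n_boot = 2000)
  expect_lt(r2$p_value, 0.05)

  # degenerate all-zero input is reported, not tested
  r3 <- binomial_independence_test(rep(0L, 20), n_boot = 100)
  expect_true(is.na(r3$p_value))
  expect_match(r3$message, "degenerate")

  expect_error(binomial_independence_test(c(1L, 2L)), "insufficient data")
  expect_error(binomial_independence_test(rep(9L, 20)), "0..cells_per_embryo")
})

test_that("D'Agostino K-squared reproduces reference values", {
  # frozen values computed independently with scipy.stats.normaltest
  set.seed(5)
  x1 <- rnorm(50); x2 <- rexp(40); x3 <- rnorm(20)
  r1 <- dagostino_k2(x1)
  expect_equal(r1$statistic, 2.270529, tolerance = 1e-5)
  expect_equal(r1$p_value, 0.321337, tolerance = 1e-5)
  r2 <- dagostino_k2(x2)
  expect_equal(r2$statistic, 24.515601, tolerance = 1e-5)
  expect_equal(r2$p_value, 0.000005, tolerance = 1e-5)
  r3 <- dagostino_k2(x3)
  expect_equal(r3$statistic, 2.497433, tolerance = 1e-5)
  expect_error(dagostino_k2(rnorm(5)), "n >= 9")
})

test_that("test selection follows the normality / variance decision tree", {
  set.seed(8)
  a <- rnorm(40, 5, 1); b <- rnorm(40, 5.5, 1)
  expect_equal(test_selector(list(a, b))$test, "t-test")
  b_wide <- rnorm(40, 5.5, 4)
  expect_equal(test_selector(list(a, b_wide))$test, "Welch t-test")
  skew <- rexp(40)
  expect_equal(test_selector(list(a, skew))$test, "Mann-Whitney U")
  expect_equal(test_selector(list(a, b, rnorm(40, 6)))$test,
               "one-way ANOVA")
  expect_equal(test_selector(list(a, skew, rexp(40)))$test,
               "Kruskal-Wallis + Dunn")
  small <- test_selector(list(rnorm(5), rnorm(40)))
  expect_equal(small$test, "Mann-Whitney U")
  expect_match(small$note, "rank-based")
})

test_that("lineage statistics conserve daughters and surface anomalies", {
  cfg <- simulation_config(n_embryos = 60, ep_probability = 0.25, seed = 12)
  lin <- generate_lineage_table(cfg)
  st <- lineage_stats(lin, n_boot = 500)
  # daughter conservation: 2 x EP mothers = EP-derived daughters
  pol <- st$daughter_polarity
  expect_equal(sum(pol$n), 2 * nrow(lin))
  expect_equal(pol$n[pol$group == "EP"], 2 * sum(lin$ep))
  expect_true(st$fisher_symmetry$p_value >= 0 &&
                st$fisher_symmetry$p_value <= 1)
  expect_equal(st$n_anomalous, 0)   # generator never emits anomalous pairs
})
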