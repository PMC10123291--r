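test_that("welch t matches the closed form and handles degeneracy", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  r <- welch_t(a, b)
  oracle <- brute_welch(a, b)
  expect_equal(r$statistic, oracle$t)
  expect_equal(r$df, oracle$df)
  expect_equal(r$p, oracle$p)
  expect_lt(r$p, 0.01)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # Satterthwaite df strictly below the pooled df with unequal variances
  un <- welch_t(c(1, 1.1, 0.9, 1.05), c(5, 9, 1, 7))
  expect_lt(un$df, 4 + 4 - 2)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("2x2 chi-square equals the closed form, scales with counts", {
  r <- chi2_morphotype(c(20, 10), c(10, 20))
  expect_equal(r$statistic, brute_chi2_2x2(rbind(c(20, 10), c(10, 20))))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  flat <- chi2_morphotype(c(10, 10), c(10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  r2 <- chi2_morphotype(c(40, 20), c(20, 40))
  expect_equal(r2$statistic, 2 * r$statistic, tolerance = 1e-12)
  expect_error(chi2_morphotype(c(0, 0), c(10, 20)), "margins")
})

test_that("Kruskal-Wallis H matches brute-force ranks, with ties", {
  kw <- suppressWarnings(
    kw_dunn(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)))
  expect_equal(kw$omnibus$statistic, 27 / 7, tolerance = 1e-12)
  flat <- kw_dunn(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$omnibus$statistic, 0)
  expect_equal(flat$omnibus$p, 1)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(6:12, 1)
    g <- sample(letters[1:3], n, replace = TRUE)
    while (length(unique(g)) < 3) g <- sample(letters[1:3], n, replace = TRUE)
    v <- sample(1:5, n, replace = TRUE)  # heavy ties
    kw <- kw_dunn(v, g)
    expect_equal(kw$omnibus$statistic, brute_kw_H(v, g),
                 tolerance = 1e-12)
  }
})

test_that("Dunn pairwise z follows the pooled-rank formula", {
  v <- c(1, 3, 5, 7, 2, 4, 6, 8, 10, 12, 14, 9)
  g <- rep(c("a", "b", "c"), each = 4)
  kw <- kw_dunn(v, g)
  expect_true(all(kw$pairwise$p_adj >= kw$pairwise$p))
  expect_true(all(kw$pairwise$p_adj <= 1))
  # hand computation for the a-c pair (no ties in v)
  r <- rank(v)
  N <- length(v)
  se <- sqrt(N * (N + 1) / 12 * (1 / 4 + 1 / 4))
  z_ac <- (mean(r[g == "a"]) - mean(r[g == "c"])) / se
  got <- kw$pairwise[kw$pairwise$comparison == "a vs c", ]
  expect_equal(got$statistic, z_ac, tolerance = 1e-12)
  expect_equal(got$p_adj, min(1, 3 * 2 * pnorm(-abs(z_ac))),
               tolerance = 1e-12)
  expect_equal(kw$p_adjust_method, "bonferroni")
})

test_that("one-way ANOVA F matches the closed form; Tukey flags the shift", {
  vals <- c(1, 2, 1.5, 2.5, 10, 11, 10.5, 11.5, 1.2, 2.2, 1.7, 2.7)
  grp <- rep(c("a", "b", "c"), each = 4)
  at <- anova_tukey(vals, grp)
  # closed-form F
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(x) sum((x - mean(x))^2)))
  Fo <- (ssb / 2) / (ssw / 9)
  expect_equal(at$omnibus$statistic, Fo, tolerance = 1e-12)
  expect_lt(at$omnibus$p, 0.001)
  sig <- at$pairwise$p_adj < 0.05
  names(sig) <- at$pairwise$comparison
  expect_true(sig[["b vs a"]])
  expect_true(sig[["c vs b"]])
  expect_false(sig[["c vs a"]])
  flat <- anova_tukey(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$omnibus$statistic, 0)
  expect_equal(flat$omnibus$p, 1)
})

test_that("significance tiers follow the four thresholds", {
  expect_equal(stars(c(0.2, 0.05, 0.03, 0.01, 0.005, 0.001, 5e-4, 5e-5)),
               c("ns", "ns", "*", "*", "**", "**", "***", "****"))
  expect_error(stars(1.2))
})
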