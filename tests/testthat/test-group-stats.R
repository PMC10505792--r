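test_that("one-way ANOVA matches hand-computed sums of squares", {
  # SSB = 6 over df 2, SSW = 6 over df 6 -> F = 3
  an <- oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(an$F, 3)
  expect_equal(an$dfBetween, 2)
  expect_equal(an$dfWithin, 6)
  # identical groups: no between-group variance
  an0 <- oneWayAnova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)
  # location invariance
  anShift <- oneWayAnova(list(a = c(1, 2, 3) + 10, b = c(2, 3, 4) + 10,
                              c = c(3, 4, 5) + 10))
  expect_equal(anShift$F, 3)
  expect_error(oneWayAnova(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(oneWayAnova(list(a = c(1, 1), b = c(1, 1))), "variance")
})

test_that("the Dunnett tail matches mvtnorm's multivariate t", {
  skip_if_not_installed("mvtnorm")
  lam <- rep(sqrt(15 / 30), 3)
  R <- diag(3); R[row(R) != col(R)] <- 0.5
  for (q in c(1.5, 2.2, 3)) {
    mine <- pDunnettMax(q, lam, df = 56)
    set.seed(1)
    ref <- 1 - as.numeric(mvtnorm::pmvt(
      lower = rep(-q, 3), upper = rep(q, 3), df = 56, corr = R,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-6)))
    expect_lt(abs(mine - ref), 1e-4)
  }
})

test_that("Dunnett with a single treatment reduces to the pooled t-test", {
  set.seed(91)
  g <- list(ctrl = rnorm(10), trt = rnorm(10, 0.8))
  dt <- dunnettTest(g, "ctrl")
  tt <- t.test(g$trt, g$ctrl, var.equal = TRUE)
  expect_equal(dt@comparisons$p_adj, tt$p.value, tolerance = 1e-4)
  expect_equal(unname(dt@comparisons$estimate), mean(g$trt) - mean(g$ctrl))
})

test_that("adjusted p-values dominate unadjusted ones and stay in [0, 1]", {
  set.seed(92)
  for (rep in 1:10) {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(6))
    dt <- dunnettTest(g, "a")
    unadj <- 2 * pt(-abs(dt@comparisons$t), dt@anova$dfWithin)
    expect_true(all(dt@comparisons$p_adj >= unadj - 1e-6))
    expect_true(all(dt@comparisons$p_adj >= 0 & dt@comparisons$p_adj <= 1))
    tk <- tukeyTest(g)
    unadjT <- 2 * pt(-abs(tk@comparisons$t), tk@anova$dfWithin)
    expect_true(all(tk@comparisons$p_adj >= unadjT - 1e-6))
  }
})

test_that("Dunnett agrees with multcomp's implementation", {
  skip_if_not_installed("multcomp")
  set.seed(93)
  g <- list(WT = rnorm(12, 10), HET = rnorm(12, 10.8), HD = rnorm(12, 12),
            KO = rnorm(12, 12.2))
  dt <- dunnettTest(g, "WT")
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(names(g), lengths(g)), levels = names(g)))
  set.seed(1)  # multcomp's mvt integration is quasi-random
  mc <- summary(multcomp::glht(stats::aov(y ~ grp, df),
                               linfct = multcomp::mcp(grp = "Dunnett")))
  expect_equal(unname(dt@comparisons$p_adj),
               unname(as.numeric(mc$test$pvalues)), tolerance = 2e-3)
})

test_that("Tukey HSD agrees with stats::TukeyHSD", {
  set.seed(94)
  g <- list(a = rnorm(10, 0), b = rnorm(10, 1), c = rnorm(10, 1.5))
  tk <- tukeyTest(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(names(g), lengths(g))))
  ref <- TukeyHSD(stats::aov(y ~ grp, df))$grp
  # same pairs, possibly reversed sign convention
  expect_equal(sort(tk@comparisons$p_adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-8)
  # a pair of identical groups adjusts to p near 1
  tk2 <- tukeyTest(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 10, 11)))
  pAB <- tk2@comparisons$p_adj[tk2@comparisons$comparison == "b - a"]
  expect_gt(pAB, 0.99)
})

test_that("summaries and stars follow the reporting conventions", {
  expect_equal(pStars(c(0.03, 0.2, 0.0005, 5e-5, 0.05)),
               c("*", "ns", "***", "****", "ns"))
  s <- summarizeGroups(list(a = c(2, 2, 2), b = c(1, 3)), control = "a")
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$sd, c(0, sqrt(2)))
  expect_equal(s$n, c(3, 2))
  expect_true(is.na(s$p_adj[s$group == "a"]))
  expect_error(dunnettTest(list(a = c(1, 2), b = c(2, 3)), "zz"),
               "not found")
})
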