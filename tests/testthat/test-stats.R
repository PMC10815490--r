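# Statistical battery: normality routing, two-group tests against
# enumeration oracles, multiplicity adjustments, ANOVA, summaries.

test_that("normality screening routes by ties as specified", {
  set.seed(30)
  distinct <- rnorm(12)
  r1 <- normalityScreen(distinct)
  expect_equal(r1$test, "shapiro_wilk")
  tied <- c(distinct[1:10], distinct[1], distinct[2])
  r2 <- normalityScreen(tied)
  expect_equal(r2$test, "dagostino_pearson")
  r3 <- normalityScreen(tied, tiesRule = FALSE)
  expect_equal(r3$test, "shapiro_wilk")
  expect_error(normalityScreen(c(1, 2)), "n >= 3")
  expect_error(normalityScreen(c(1, 1, 2, 3, 4)), "n >= 8")
})

test_that("the omnibus K2 test matches independently computed values", {
  # frozen oracle values from an independent implementation of the
  # D'Agostino-Pearson K2 statistic
  r1 <- dagostinoPearsonTest(c(1, 2, 3, 4, 5, 6, 7, 8.5))
  expect_equal(r1$statistic, 0.3935729275, tolerance = 1e-8)
  expect_equal(r1$p.value, 0.821366006, tolerance = 1e-8)
  r2 <- dagostinoPearsonTest(c(1:20, 50))
  expect_equal(r2$statistic, 27.9790047389, tolerance = 1e-8)
  expect_equal(r2$p.value, 8.403e-07, tolerance = 1e-4)
  r3 <- dagostinoPearsonTest(c(0.5, 1.1, 2.3, 3.1, 4.9, 5.5, 6.2, 7.8,
                               8.1, 9.9))
  expect_equal(r3$statistic, 0.885364148, tolerance = 1e-8)
  expect_equal(r3$p.value, 0.6423113821, tolerance = 1e-8)
  expect_error(dagostinoPearsonTest(1:7), "n >= 8")
})

test_that("identical groups compare as null", {
  r <- compareTwo(c(1, 2, 3), c(1, 2, 3), route = "t")
  expect_equal(r$p.value, 1)
  expect_equal(r$statistic, 0)
  deg <- compareTwo(c(2, 2, 2), c(2, 2, 2))
  expect_equal(deg$p.value, 1)
  expect_match(deg$flag, "convention")
})

test_that("well-separated small samples give the exact U = 0, p = 0.1", {
  r <- compareTwo(c(1, 2, 3), c(101, 102, 103), route = "mann_whitney")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 0.1)
  expect_equal(r$p.value, mwExact(c(1, 2, 3), c(101, 102, 103)))
})

test_that("Mann-Whitney agrees with enumeration for all sizes up to 5", {
  set.seed(31)
  for (na in 2:5) for (nb in 2:5) {
    for (rep in 1:3) {
      a <- sample(seq_len(50), na)      # distinct integers: no ties
      b <- sample(setdiff(seq_len(50), a), nb)
      got <- compareTwo(a, b, route = "mann_whitney")$p.value
      expect_equal(got, mwExact(a, b), tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d rep=%d", na, nb, rep))
    }
  }
})

test_that("auto-routed comparisons keep their nominal type-I error", {
  set.seed(1)
  rej <- replicate(1000, {
    compareTwo(rnorm(10), rnorm(10))$p.value < 0.05
  })
  expect_gte(mean(rej), 0.036)
  expect_lte(mean(rej), 0.065)
})

test_that("Sidak and Holm-Sidak match their closed forms", {
  expect_equal(sidakAdjust(0.3, m = 1), 0.3)
  expect_equal(sidakAdjust(0.02, m = 2), 1 - 0.98^2)
  expect_equal(sidakAdjust(c(0.02, 0.5)), 1 - c(0.98, 0.5)^2)
  # hand-evaluated step-down: {0.01, 0.04} ->
  # {1 - 0.99^2, max(1 - 0.99^2, 1 - 0.96^1)}
  hs <- holmSidakAdjust(c(0.01, 0.04))
  expect_equal(hs, c(1 - 0.99^2, max(1 - 0.99^2, 1 - 0.96)))
  expect_equal(hs, c(0.0199, 0.04))
  # order preserved and monotone under permutation
  p <- c(0.04, 0.01)
  expect_equal(holmSidakAdjust(p), rev(hs))
  expect_error(sidakAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("adjusted p-values never fall below raw ones", {
  set.seed(32)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_true(all(sidakAdjust(p) >= p))
    hs <- holmSidakAdjust(p)
    expect_true(all(hs >= p - 1e-12))
    # monotone in the order statistics
    expect_true(all(diff(hs[order(p)]) >= -1e-12))
  }
})

test_that("a flat two-factor table yields null F statistics", {
  tab <- expand.grid(genotype = c("WT", "Mut"),
                     treatment = c("control", "drug"),
                     rep = 1:3)
  tab$value <- 5
  res <- twoWayAnova(tab)
  expect_true(all(res$anova$F == 0))
  expect_true(all(res$anova$p == 1))
  expect_true(all(res$contrasts$p.sidak == 1))
})

test_that("underpopulated cells are rejected with the cell named", {
  tab <- expand.grid(genotype = c("WT", "Mut"),
                     treatment = c("control", "drug"), rep = 1:3)
  tab$value <- rnorm(nrow(tab))
  tab <- tab[!(tab$genotype == "Mut" & tab$treatment == "drug" &
               tab$rep > 1), ]
  expect_error(twoWayAnova(tab), "Mut.*drug|drug.*Mut")
})

test_that("a control-only tone effect is detected only under control", {
  sig <- vapply(1:100, function(i) {
    coh <- simulateLengthCohort(LengthScenario(nPerGroup = 20,
      toneShortening = c(WT = 3.7, Mut = 2.3),
      nicardipineResidualTone = 0, sd = 0.5, seed = 7000 + i))
    res <- twoWayAnova(coh, response = "length", genotype = "group",
                       treatment = "treatment")
    ps <- res$contrasts$p.sidak
    names(ps) <- as.character(res$contrasts$treatment)
    c(ps[["control"]] < 0.05, ps[["nicardipine"]] >= 0.05)
  }, logical(2))
  expect_gte(mean(sig[1, ] & sig[2, ]), 0.95)
})

test_that("summaries report mean, SEM and n with the 1/sqrt(n) law", {
  s <- summarizeSample(c(1, 2, 3, 4))
  expect_equal(unname(s["mean"]), 2.5)
  expect_equal(unname(s["sem"]), sd(c(1, 2, 3, 4)) / 2)
  expect_equal(unname(s["n"]), 4)
  set.seed(33)
  base <- rnorm(1600)
  sems <- vapply(c(100, 400, 1600), function(n)
    unname(summarizeSample(base[seq_len(n)])["sem"]), numeric(1))
  expect_true(all(diff(sems) < 0))
  expect_equal(sems[1] / sems[3], 4, tolerance = 0.3)
})

test_that("percent change reproduces the reported reductions", {
  expect_equal(percentChange(152.9, 105.6), 30.9)
  expect_equal(percentChange(85.2, 63.4), 25.6)
  expect_equal(percentChange(4.2, 4.2), 0)
  expect_error(percentChange(0, 5), "nonzero")
})
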