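## fixed small vectors; reference p-values frozen from an independent
## implementation (scipy.stats 1.17: ttest_ind, mannwhitneyu method="exact",
## kruskal, tukey_hsd, dunnett)
fixA <- c(4.1, 5.2, 6.3, 5.8, 4.9, 5.5)
fixB <- c(6.0, 7.1, 6.8, 7.5, 6.2)
fixC <- c(5.0, 5.9, 6.4, 6.1, 5.3, 6.6, 5.7)

test_that("two-sample tests match the independent reference to 1e-6", {
  expect_equal(runTest(list(a = fixA, b = fixB), "welch_t")@pTwoSided,
               0.007829333436044333, tolerance = 1e-6)
  expect_equal(runTest(list(a = fixA, b = fixB), "student_t")@pTwoSided,
               0.008719141595535966, tolerance = 1e-6)
  mw <- runTest(list(a = fixA, b = fixB), "mann_whitney")
  expect_equal(mw@statistic, 2)
  expect_equal(mw@pTwoSided, 0.017316017316017316, tolerance = 1e-6)
  kw <- runTest(list(a = fixA, b = fixB, c = fixC), "kruskal_dunn")
  expect_equal(kw@pTwoSided, 0.021407226361739792, tolerance = 1e-6)
})

test_that("Tukey all-pairs matches the studentized-range reference", {
  tk <- runTest(list(a = fixA, b = fixB, c = fixC), "tukey")
  ref <- c(ab = 0.00720751, ac = 0.30546766, bc = 0.09454641)
  expect_equal(tk@comparisons$p_adjusted, unname(ref), tolerance = 1e-6)
})

test_that("Dunnett adjusted p matches quadrature oracle and reference", {
  dn <- runTest(list(a = fixA, b = fixB, c = fixC), "dunnett", control = "a")
  expect_equal(dn@comparisons$statistic, c(3.58308297, 1.53011394),
               tolerance = 1e-6)
  # independent fixed-grid quadrature of the same distribution
  ns <- c(6, 5, 7)
  lambdas <- sqrt(ns[2:3] / (ns[2:3] + ns[1]))
  df <- sum(ns) - 3
  oracle <- vapply(abs(dn@comparisons$statistic), function(q)
    1 - dunnettOracleP(q, lambdas, df), numeric(1))
  expect_equal(dn@comparisons$p_adjusted, oracle, tolerance = 1e-6)
  # frozen randomized-QMC reference values (accurate to ~1e-4 only)
  expect_equal(dn@comparisons$p_adjusted, c(0.00505484, 0.2478963),
               tolerance = 1e-3)
})

test_that("degenerate and closed-form cases behave as documented", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(runTest(list(a = a, b = a), "welch_t")@pTwoSided, 1,
               tolerance = 1e-9)
  # identical equal-length samples: U = n^2 / 2
  mw <- suppressWarnings(runTest(list(a = a, b = a), "mann_whitney"))
  expect_equal(mw@statistic, 18)
  expect_gt(mw@pTwoSided, 0.99)
  dn <- runTest(list(a = a, b = a, c = a), "dunnett")
  expect_true(all(dn@comparisons$p_adjusted > 0.999))
  # unknown method / insufficient n
  expect_error(runTest(list(a = a, b = a), "banana"))
  expect_error(runTest(list(a = 1, b = a), "welch_t"), "two observations")
})

test_that("adjusted p never decreases when the family grows", {
  # at a fixed per-comparison statistic, growing the family (more lambdas /
  # more means) can only inflate the adjusted p
  q <- 2.2; df <- 15
  dd <- vapply(1:4, function(k)
    1 - AstroMigrate:::pDunnettMax(q, rep(sqrt(0.5), k), df), numeric(1))
  expect_true(all(diff(dd) >= -1e-10))
  tk <- vapply(2:5, function(k)
    ptukey(q * sqrt(2), k, df, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(tk) >= -1e-12))
  # and adjusted >= unadjusted within any single report
  g4 <- list(a = fixA, b = fixB, c = fixC, d = fixC + 0.3)
  rep <- runTest(g4, "dunnett", control = "a")
  expect_true(all(rep@comparisons$p_adjusted >= rep@comparisons$p - 1e-12))
  rep2 <- runTest(g4, "kruskal_dunn")
  expect_true(all(rep2@comparisons$p_adjusted >= rep2@comparisons$p - 1e-12))
})

test_that("Dunn post hoc follows the tie-corrected rank formula", {
  dn <- runTest(list(a = fixA, b = fixB, c = fixC), "kruskal_dunn")
  # independent recomputation of the a-vs-b z statistic
  x <- c(fixA, fixB, fixC)
  g <- rep(c("a", "b", "c"), c(6, 5, 7))
  rk <- rank(x)
  N <- length(x)
  ties <- table(x)
  tieT <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tieT) * (1 / 6 + 1 / 5))
  z <- (mean(rk[g == "a"]) - mean(rk[g == "b"])) / se
  row <- dn@comparisons[dn@comparisons$group1 == "a" &
                          dn@comparisons$group2 == "b", ]
  expect_equal(row$statistic, z, tolerance = 1e-9)
  expect_equal(row$p_adjusted, min(1, 3 * 2 * pnorm(-abs(z))),
               tolerance = 1e-9)
  expect_identical(dn@details$adjustment, "dunn-bonferroni")
})

test_that("variance gate: convention, type-I behaviour, and power", {
  expect_equal(varianceGate(fixA, fixA)$decision, "equal")
  zero <- rep(2, 5)
  g <- varianceGate(zero, zero)
  expect_equal(g$decision, "equal")
  expect_false(is.na(g$flag))

  eqHits <- uneqHits <- 0
  for (r in 1:20) {
    set.seed(r)
    a <- rnorm(50); b <- rnorm(50)
    if (varianceGate(a, b)$decision == "equal") eqHits <- eqHits + 1
    b4 <- rnorm(50, sd = 4)  # variance ratio 16
    if (varianceGate(a, b4)$decision == "unequal") uneqHits <- uneqHits + 1
  }
  expect_gte(eqHits, 18)    # >= 90% correct under equal variances
  expect_gte(uneqHits, 19)  # >= 95% power at ratio 16, n = 50
})

test_that("star mapping follows the reporting convention exactly", {
  expect_equal(significanceStars(c(0.2, 0.049, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(significanceStars(0.05), "ns")  # strict boundaries
})
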