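test_that("detection requires co-localization and the size filter", {
  # blob present in only one channel -> product ~ 0 -> no detection
  one <- detectionStack(data.frame(x = 30, y = 30, z = 16, volume = 9000,
                                   channels = "a"), c(64, 64, 32))
  expect_equal(nrow(detectDoublePositive(one, "a", "b", 2500)), 0L)

  # rendered volume 5000 um^3 -> rejected by the 6000 um^3 filter
  small <- detectionStack(data.frame(x = 30, y = 30, z = 16, volume = 5000,
                                     channels = "both"), c(64, 64, 32))
  expect_equal(nrow(detectDoublePositive(small, "a", "b", 2500)), 0L)

  # k planted double-positive blobs >= 8000 um^3 among distractors -> exactly
  # k; an 8000 um^3 blob has a ~12.4 um half-max radius, so keep them far
  # apart in a roomy field
  blobs <- data.frame(
    x = c(26, 102, 64, 26, 102), y = c(26, 102, 64, 102, 26),
    z = c(16, 32, 24, 24, 24),
    volume = c(8000, 9000, 3000, 9000, 9000),
    channels = c("both", "both", "both", "a", "b"))
  st <- detectionStack(blobs, c(128, 128, 48))
  det <- detectDoublePositive(st, "a", "b", 2500)
  expect_equal(nrow(det), 2L)
  expect_true(all(det$volume_um3 > 6000))
  # centroids land near the planted ones
  planted <- blobs[blobs$volume >= 8000 & blobs$channels == "both", ]
  for (i in seq_len(nrow(det))) {
    dd <- sqrt((planted$x - det$x[i])^2 + (planted$y - det$y[i])^2 +
                 (planted$z - det$z[i])^2)
    expect_lt(min(dd), 1.5)
  }
})

test_that("detection is monotone in the size filter", {
  blobs <- data.frame(x = c(16, 48), y = c(16, 48), z = c(12, 20),
                      volume = c(7000, 12000), channels = "both")
  st <- detectionStack(blobs, c(64, 64, 32))
  counts <- vapply(c(1000, 6000, 8000, 13000), function(sf)
    nrow(detectDoublePositive(st, "a", "b", 2500,
                              analysisConfig(sizeFilterUm3 = sf))), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 2L)
  expect_equal(counts[4], 0L)
})

test_that("relative depth: borders, midpoint, hand projection oracle", {
  fr <- corticalFrame(radialAxis = c(0, 1), upperBorderUm = -200,
                      lowerBorderUm = -40)
  # +y is toward the pia: y = 200 is the upper border, y = 40 the lower
  expect_equal(relativeDepth(data.frame(x = 0, y = 200), fr)$depth_rel, 0)
  expect_equal(relativeDepth(data.frame(x = 0, y = 120), fr)$depth_rel, 0.5)
  expect_equal(relativeDepth(data.frame(x = 0, y = 40), fr)$depth_rel, 1)
  out <- relativeDepth(data.frame(x = 0, y = 250), fr)
  expect_false(out$in_range)

  # tilted axis: agree with an explicit dot-product projection
  ax <- c(1, 2) / sqrt(5)
  fr2 <- corticalFrame(radialAxis = ax, upperBorderUm = -100,
                       lowerBorderUm = 0)
  set.seed(31)
  pts <- data.frame(x = runif(20, 0, 100), y = runif(20, 0, 100))
  got <- relativeDepth(pts, fr2)$depth_rel
  sProj <- -(pts$x * ax[1] + pts$y * ax[2])
  expect_equal(got, (sProj - (-100)) / (0 - (-100)), tolerance = 1e-12)
})

test_that("binning: edges, conservation, and the uniform binomial check", {
  cfgA <- analysisConfig()
  expect_equal(unname(binDistribution(0.10, cfgA)["bin1"]), 1L)
  # exactly 0.25 goes to the deeper bin (half-open edges)
  expect_equal(unname(binDistribution(0.25, cfgA)["bin2"]), 1L)
  expect_equal(unname(binDistribution(1, cfgA)["bin4"]), 1L)  # last bin closed
  expect_error(binDistribution(c(0.5, 1.2), cfgA), "0, 1")

  set.seed(12)
  u <- runif(10000)
  counts <- binDistribution(u, cfgA)
  expect_equal(sum(counts), 10000L)  # count conservation, always
  # each bin within the binomial 99% interval of n/4
  ci <- qbinom(c(0.005, 0.995), 10000, 0.25)
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
})

test_that("per-brain fractions and group comparison behave sanely", {
  set.seed(21)
  ctl <- simulateDepthDataset(6, 80, 0.4, seed = 1)
  same <- simulateDepthDataset(6, 80, 0.4, seed = 2)
  d <- rbind(cbind(group = "control", perBrainBinFractions(ctl)),
             cbind(group = "same", perBrainBinFractions(same)))
  d$brain <- paste(d$group, d$brain)
  res <- compareBinFractions(d, control = "control")
  # identical generating distributions: no significant bin comparisons
  pb1 <- res$reports$bin1@comparisons$p_adjusted
  expect_gt(pb1, 0.05)
  # fractions per brain sum to one across bins
  sums <- tapply(d$fraction, d$brain, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # two-group Dunnett reduces to the two-sample comparison
  g1 <- d$fraction[d$group == "control" & d$bin == 1]
  g2 <- d$fraction[d$group == "same" & d$bin == 1]
  tt <- runTest(list(control = g1, same = g2), "student_t")
  expect_equal(pb1, tt@pTwoSided, tolerance = 1e-6)

  # single-brain group: inference rejected, descriptives only
  solo <- data.frame(group = "solo", brain = "solo b1", bin = 1:4,
                     fraction = c(0.4, 0.2, 0.2, 0.2))
  expect_warning(r2 <- compareBinFractions(rbind(d, solo),
                                           control = "control"),
                 "single brain")
  expect_null(r2$reports)
})

test_that("a designed superficial depletion shifts bin-1 mass as designed", {
  ctl <- simulateDepthDataset(10, 100, 0.4, seed = 5)
  kd <- simulateDepthDataset(10, 100, 0.2, seed = 6)
  f1 <- function(d) mean(perBrainBinFractions(d)$fraction[
    perBrainBinFractions(d)$bin == 1])
  drop <- f1(ctl) - f1(kd)
  expect_lt(abs(drop - 0.2), 0.05)
})
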