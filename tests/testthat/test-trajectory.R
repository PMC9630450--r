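mkTrack <- function(x, y, z = 0, dt = 0.5, hemi = "right") {
  n <- length(x)
  track("t", data.frame(t_h = (seq_len(n) - 1) * dt, x_um = x, y_um = y,
                        z_um = rep_len(z, n)), hemisphere = hemi)
}

defaultFrame <- corticalFrame(radialAxis = c(0, 1), upperBorderUm = -100,
                              lowerBorderUm = 0, hemisphere = "right")

test_that("frame steps: stationary, gate boundary, duplicate timestamps", {
  st <- frameSteps(mkTrack(rep(0, 10), rep(0, 10)))
  expect_true(all(st$speed_umh == 0))
  expect_false(any(st$gated))
  expect_true(all(is.na(st$direction_deg)))

  # 5 um in 0.5 h = exactly 10 um/h: strict inequality, not gated
  st <- frameSteps(mkTrack(c(0, 5), c(0, 0)))
  expect_equal(st$speed_umh, 10)
  expect_false(st$gated)

  tr <- mkTrack(c(0, 1, 2), c(0, 0, 0))
  tr@samples$t_h <- c(0, 1, 1)
  expect_error(frameSteps(tr), "index 3")
})

test_that("frame speeds match an independent recomputation on random tracks", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 20
    x <- cumsum(rnorm(n, sd = 8)); y <- cumsum(rnorm(n, sd = 8))
    z <- cumsum(rnorm(n, sd = 2))
    tr <- mkTrack(x, y, z)
    st <- frameSteps(tr)
    # brute-force oracle from the raw coordinates
    oracle <- sapply(seq_len(n - 1), function(i)
      sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2 + (z[i + 1] - z[i])^2) / 0.5)
    expect_equal(st$speed_umh, oracle, tolerance = 1e-12)
    expect_equal(st$gated, oracle > 10)
  }
})

test_that("directional changes: straight line, wrap-around, hemisphere flip", {
  # straight gated line -> all changes zero
  expect_equal(directionalChanges(mkTrack(seq(0, 100, by = 20), rep(0, 6))),
               rep(0, 4))

  # direction 170 deg then -170 deg: raw difference -340 wraps to +20
  p1 <- c(0, 0)
  p2 <- p1 + 20 * c(cos(170 * pi / 180), sin(170 * pi / 180))
  p3 <- p2 + 20 * c(cos(-170 * pi / 180), sin(-170 * pi / 180))
  trR <- mkTrack(c(p1[1], p2[1], p3[1]), c(p1[2], p2[2], p3[2]))
  expect_equal(directionalChanges(trR), 20, tolerance = 1e-9)

  trL <- trR; trL@hemisphere <- "left"
  expect_equal(directionalChanges(trL), -directionalChanges(trR))

  # fewer than two gated steps -> empty, not an error
  expect_length(directionalChanges(mkTrack(c(0, 1, 2), c(0, 0, 0))), 0)
})

test_that("sub-gate frames are skipped, not interpolated", {
  # gated +x step, tiny pause, gated +y step: one change of +90
  tr <- mkTrack(c(0, 20, 20.5, 20.5), c(0, 0, 0, 20))
  expect_equal(directionalChanges(tr), 90)
})

test_that("angles to radial axis: parallel, lateral, and oracle agreement", {
  expect_equal(anglesToRadial(mkTrack(c(0, 0), c(0, 20)), defaultFrame), 0)
  # purely lateral (+x in the right hemisphere) -> +90
  expect_equal(anglesToRadial(mkTrack(c(0, 20), c(0, 0)), defaultFrame), 90)
  # same geometry, left hemisphere -> sign involution
  frL <- corticalFrame(radialAxis = c(0, 1), upperBorderUm = -100,
                       lowerBorderUm = 0, hemisphere = "left")
  expect_equal(anglesToRadial(mkTrack(c(0, 20), c(0, 0), hemi = "left"), frL),
               -90)

  set.seed(7)
  for (rep in 1:5) {
    x <- cumsum(rnorm(15, sd = 15)); y <- cumsum(rnorm(15, sd = 15))
    tr <- mkTrack(x, y)
    got <- anglesToRadial(tr, defaultFrame)
    # independent oracle via atan2 of cross/dot products with the axis
    st <- frameSteps(tr)
    keep <- st$gated & !is.na(st$direction_deg)
    dx <- diff(x)[keep]; dy <- diff(y)[keep]
    ax <- c(0, 1)
    cross <- dx * ax[2] - dy * ax[1]   # lateral(+x) positive in right hemi
    dot <- dx * ax[1] + dy * ax[2]
    expect_equal(got, atan2(cross, dot) * 180 / pi, tolerance = 1e-9)
  }
})

test_that("polar summary: closed loop, straight radial run, endpoint oracle", {
  loop <- polarSummary(mkTrack(c(0, 20, 20, 0, 0), c(0, 0, 20, 20, 0)),
                       defaultFrame)
  expect_equal(loop$netDistanceUm, 0)
  expect_true(loop$degenerate)
  expect_true(is.na(loop$netDirectionDeg))

  run <- polarSummary(mkTrack(c(0, 0), c(0, 100)), defaultFrame)
  expect_equal(run$netDistanceUm, 100)
  expect_equal(run$netDirectionDeg, 0)

  set.seed(13)
  x <- cumsum(rnorm(10, sd = 10)); y <- cumsum(rnorm(10, sd = 10))
  ps <- polarSummary(mkTrack(x, y), defaultFrame)
  expect_equal(ps$netDistanceUm,
               sqrt((x[10] - x[1])^2 + (y[10] - y[1])^2), tolerance = 1e-12)
})

test_that("motility filter matches a brute-force displacement scan", {
  # oscillation of amplitude 10 um -> stationary; straight 25 um -> motile
  osc <- mkTrack(rep(c(0, 10), 25), rep(0, 50))
  straight <- mkTrack(seq(0, 25, length.out = 49), rep(0, 49))
  res <- motileFilter(list(osc, straight))
  expect_equal(unname(res$isMotile), c(FALSE, TRUE))

  set.seed(5)
  trks <- lapply(1:100, function(i)
    mkTrack(cumsum(rnorm(30, sd = 4)), cumsum(rnorm(30, sd = 4))))
  got <- motileFilter(trks)$isMotile
  oracle <- vapply(trks, function(tr) {
    s <- samples(tr)
    w <- s$t_h - s$t_h[1] <= 24
    any(sqrt((s$x_um[w] - s$x_um[1])^2 + (s$y_um[w] - s$y_um[1])^2) > 20)
  }, logical(1))
  expect_equal(unname(got), oracle)
})

test_that("angle wrap is idempotent and outputs stay in (-180, 180]", {
  set.seed(3)
  x <- runif(1000, -2000, 2000)
  w <- wrapAngle(x)
  expect_true(all(w > -180 & w <= 180))
  expect_equal(wrapAngle(w), w)
  expect_equal(wrapAngle(180), 180)
  expect_equal(wrapAngle(-180), 180)
})

test_that("raising the speed gate never increases the gated frame count", {
  cfg <- smallConfig(seed = 17)
  trks <- generateTracks(cfg, generateVesselNetwork(cfg))
  counts <- vapply(c(0, 5, 10, 15, 25, 40), function(g) {
    sum(vapply(trks, function(tr)
      sum(frameSteps(tr, analysisConfig(speedGateUmh = g))$gated), 0L))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("Welch comparison on identical and hand-computed groups", {
  set.seed(1)
  g <- data.frame(speed_umh = rnorm(50, 20, 3), gated = TRUE)
  same <- compareSpeedDistributions(g, g)
  expect_equal(same@statistic, 0, tolerance = 1e-12)
  expect_equal(same@pTwoSided, 1, tolerance = 1e-9)

  # n = 5 fixed values vs the textbook Welch formula
  a <- c(10, 12, 14, 11, 13); b <- c(20, 18, 22, 19, 21)
  ga <- data.frame(speed_umh = a, gated = TRUE)
  gb <- data.frame(speed_umh = b, gated = TRUE)
  rep <- compareSpeedDistributions(ga, gb)
  se <- sqrt(var(a) / 5 + var(b) / 5)
  tHand <- (mean(a) - mean(b)) / se
  dfHand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(rep@statistic, tHand, tolerance = 1e-12)
  expect_equal(rep@df, dfHand, tolerance = 1e-12)
  expect_equal(rep@pTwoSided, 2 * pt(-abs(tHand), dfHand), tolerance = 1e-12)

  expect_error(compareSpeedDistributions(ga[1, ], gb), "two gated frames")
})

test_that("group summaries follow the 1.5 x IQR whisker convention", {
  x <- c(1, 2, 3, 4, 100)
  s <- boxStats(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  expect_equal(s$whisker_lo, q[1] - 1.5 * diff(q))
  expect_equal(s$whisker_hi, q[2] + 1.5 * diff(q))
  expect_equal(s$median, 3)
})
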