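## a static mask: one straight capsule along y
contactWorld <- function() {
  seg <- data.frame(x0 = 20.5, y0 = 5, z0 = 10.5, x1 = 20.5, y1 = 55,
                    z1 = 10.5, radius_um = 3)
  st <- capsuleStack(seg, c(40, 60, 20))
  list(seg = seg,
       mask = buildVesselMask(st, "vessel", 50, skeletonize = FALSE))
}

test_that("contact labels: inside on, far off, run segmentation", {
  w <- contactWorld()
  onTr <- track("on", data.frame(t_h = c(0, 1), x_um = 20.5,
                                 y_um = c(20, 30), z_um = 10.5))
  offTr <- track("off", data.frame(t_h = c(0, 1), x_um = c(2, 2),
                                   y_um = c(2, 3), z_um = 2))
  expect_true(all(classifyTrackContacts(onTr, w$mask)$labels$on))
  expect_false(any(classifyTrackContacts(offTr, w$mask)$labels$on))

  # alternating on/off -> run-length segmentation with correct durations
  tr <- track("alt", data.frame(t_h = 0:5,
                                x_um = c(20.5, 20.5, 2, 2, 20.5, 20.5),
                                y_um = c(20, 25, 2, 2, 30, 35), z_um = 10.5))
  ct <- classifyTrackContacts(tr, w$mask)
  expect_equal(ct$runs$on, c(TRUE, FALSE, TRUE))
  expect_equal(ct$runs$duration_h, c(1, 1, 1))
})

test_that("a positive contact tolerance extends the on-call by distance", {
  w <- contactWorld()
  nearTr <- track("near", data.frame(t_h = c(0, 1), x_um = 26.5,
                                     y_um = c(20, 30), z_um = 10.5))
  strict <- classifyTrackContacts(nearTr, w$mask)
  loose <- classifyTrackContacts(nearTr, w$mask,
                                 analysisConfig(contactToleranceUm = 5))
  expect_false(any(strict$labels$on))
  expect_true(all(loose$labels$on))
})

test_that("persistence selection: boundary, arithmetic, brute-force oracle", {
  w <- contactWorld()
  cfgA <- analysisConfig()
  # 4.5 h continuous on-period only -> not selected
  t45 <- track("t45", data.frame(
    t_h = seq(0, 6, by = 0.5),
    x_um = c(rep(20.5, 10), rep(2, 3)),
    y_um = c(seq(20, 38, by = 2), 2, 2, 2), z_um = 10.5))
  ct <- classifyTrackContacts(t45, w$mask)
  expect_equal(max(ct$runs$duration_h[ct$runs$on]), 4.5)
  expect_true(is.na(onVesselPersistence(t45, ct, cfgA)))

  # straight on-vessel run, 6 h at 10 um/h -> 60 um
  t6 <- track("t6", data.frame(t_h = seq(0, 6, by = 0.5), x_um = 20.5,
                               y_um = seq(0, 60, by = 5) + 5, z_um = 10.5))
  ct6 <- classifyTrackContacts(t6, w$mask)
  expect_equal(onVesselPersistence(t6, ct6, cfgA), 60)

  # seeded tracks: equals brute-force max over samples when selected
  set.seed(4)
  for (i in 1:5) {
    y <- cumsum(abs(rnorm(30, 2)))
    y <- 5 + 50 * (y - min(y)) / diff(range(y))
    tr <- track("r", data.frame(t_h = seq(0, 14.5, by = 0.5), x_um = 20.5,
                                y_um = y, z_um = 10.5))
    ct <- classifyTrackContacts(tr, w$mask)
    got <- onVesselPersistence(tr, ct, cfgA)
    s <- samples(tr)
    oracle <- max(sqrt((s$x_um - s$x_um[1])^2 + (s$y_um - s$y_um[1])^2 +
                         (s$z_um - s$z_um[1])^2))
    expect_equal(got, oracle)
  }
})

test_that("off/on ratios per field with the traceability filter", {
  w <- contactWorld()
  cfgA <- analysisConfig()
  mkOn <- function(id, hours = 24) track(id, data.frame(
    t_h = seq(0, hours, by = 1), x_um = 20.5,
    y_um = seq(5, 55, length.out = hours + 1), z_um = 10.5))
  mkOff <- function(id, hours = 24) track(id, data.frame(
    t_h = seq(0, hours, by = 1), x_um = 2,
    y_um = seq(2, 50, length.out = hours + 1), z_um = 2))

  trks <- c(lapply(1:4, function(i) mkOn(paste0("on", i))),
            lapply(1:4, function(i) mkOff(paste0("off", i))),
            list(mkOff("short", hours = 9)))   # 9 h: below the 10 h filter
  cts <- lapply(trks, classifyTrackContacts, masks = w$mask, config = cfgA)
  res <- offOnRatio(trks, cts, rep("f1", length(trks)), cfgA)
  expect_equal(res$ratio, 1)          # 4 off / 4 on
  expect_equal(res$n_excluded, 1L)

  # a field with zero on-cells is flagged, not infinite
  offOnly <- lapply(1:3, function(i) mkOff(paste0("o", i)))
  cts2 <- lapply(offOnly, classifyTrackContacts, masks = w$mask,
                 config = cfgA)
  res2 <- offOnRatio(offOnly, cts2, rep("f2", 3), cfgA)
  expect_true(is.na(res2$ratio))
  expect_true(res2$flagged)

  # constructed two-field composition -> exact ratios
  trks3 <- c(lapply(1:2, function(i) mkOn(paste0("a", i))),
             lapply(1:6, function(i) mkOff(paste0("b", i))))
  cts3 <- lapply(trks3, classifyTrackContacts, masks = w$mask,
                 config = cfgA)
  fields <- c("fA", "fA", "fA", "fA", "fB", "fB", "fB", "fB")
  # fA: on a1, a2 + off b1, b2 -> 1.0; fB: off b3..b6, zero on -> NA
  res3 <- offOnRatio(trks3, cts3, fields, cfgA)
  expect_equal(res3$ratio[res3$field == "fA"], 1)
  expect_true(is.na(res3$ratio[res3$field == "fB"]))
})
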