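test_that("distances: on-surface zero, sphere geometry, empty-mask error", {
  # spherical blob of radius 2 at the centre of a small field
  occ <- array(FALSE, c(21, 21, 21))
  ctr <- c(10.5, 10.5, 10.5)
  for (iz in 1:21) for (iy in 1:21) for (ix in 1:21)
    if (sum((c(ix, iy, iz) - 0.5 - ctr)^2) <= 4) occ[iz, iy, ix] <- TRUE
  m <- new("VesselMask", occupancy = occ, voxelSizeUm = c(1, 1, 1),
           skeleton = matrix(integer(), 0, 3),
           surface = which(AstroMigrate:::surfaceMask(occ), arr.ind = TRUE),
           emptyForeground = FALSE)

  # centroid on a surface voxel -> 0 (inside occupancy)
  sv <- surfaceVoxels(m)[1, ]
  p0 <- c((sv[3] - 0.5), (sv[2] - 0.5), (sv[1] - 0.5))
  r0 <- nearestVesselDistance(rbind(p0), m)
  expect_equal(r0$distance_um, 0)

  # centroid 10 um from the centre of a radius-2 blob -> ~8 um
  r1 <- nearestVesselDistance(rbind(ctr + c(8, 0, 0)), m)
  expect_lt(abs(r1$distance_um - 6), sqrt(3) / 2 + 0.6)

  empty <- new("VesselMask", occupancy = array(FALSE, c(2, 2, 2)),
               voxelSizeUm = c(1, 1, 1), skeleton = matrix(integer(), 0, 3),
               surface = matrix(integer(), 0, 3), emptyForeground = TRUE)
  expect_error(nearestVesselDistance(rbind(c(1, 1, 1)), empty), "empty")
})

test_that("nearest distances equal the brute-force surface scan (property)", {
  for (seed in 1:5) {
    cfg <- simulationConfig(seed = seed, fieldSizeUm = c(64, 64, 64),
                            vesselNSegments = sample(1:5, 1),
                            vesselSegmentLengthUm = 30, noiseSd = 0)
    net <- generateVesselNetwork(cfg)
    st <- rasterizeFrame(net, list(), 1L, cfg)
    m <- buildVesselMask(st, "vessel", 50, skeletonize = FALSE)
    set.seed(seed + 100)
    pts <- cbind(runif(50, 0, 64), runif(50, 0, 64), runif(50, 0, 64))
    got <- nearestVesselDistance(pts, m)$distance_um
    oracle <- bruteSurfaceDistance(pts, occupancy(m), voxelSize(m))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("anisotropic voxels are honoured in physical distances", {
  occ <- array(FALSE, c(4, 8, 8))
  occ[2, 4, 4] <- TRUE
  m <- new("VesselMask", occupancy = occ, voxelSizeUm = c(3, 1, 1),
           skeleton = matrix(integer(), 0, 3),
           surface = which(occ, arr.ind = TRUE), emptyForeground = FALSE)
  # voxel centre at x=3.5, y=3.5, z=4.5 (z voxels are 3 um thick)
  r <- nearestVesselDistance(rbind(c(3.5, 3.5, 10.5)), m)
  expect_equal(r$distance_um, 6)
})

test_that("edge exclusion: reasons, precedence, and zero silent drops", {
  cfgA <- analysisConfig()
  mk <- function(x, y, z) data.frame(cell_id = "c", x = x, y = y, z = z,
                                     distance_um = 1, included = TRUE,
                                     exclusion_reason = "none")
  f <- c(200, 200, 50)
  # z = 10 in a 50 um stack with 15 um limit -> excluded (z_limit)
  r <- applyEdgeExclusion(mk(100, 100, 10), f, cfgA)
  expect_false(r$included); expect_equal(r$exclusion_reason, "z_limit")
  # x = 19 from the border with 20 um margin -> xy_margin
  r <- applyEdgeExclusion(mk(19, 100, 25), f, cfgA)
  expect_false(r$included); expect_equal(r$exclusion_reason, "xy_margin")
  # interior point -> included
  r <- applyEdgeExclusion(mk(100, 100, 25), f, cfgA)
  expect_true(r$included); expect_equal(r$exclusion_reason, "none")
  # bounds must enclose the centroids
  expect_error(applyEdgeExclusion(mk(300, 100, 25), f, cfgA), "enclose")

  set.seed(8)
  recs <- data.frame(cell_id = sprintf("c%d", 1:500),
                     x = runif(500, 0, 200), y = runif(500, 0, 200),
                     z = runif(500, 0, 50), distance_um = runif(500, 0, 30),
                     included = TRUE, exclusion_reason = "none")
  out <- applyEdgeExclusion(recs, f, cfgA)
  expect_equal(nrow(out), nrow(recs))          # no silent drops
  boxOracle <- with(recs, !(z < 15 | z > 35) &
                      !(x < 20 | x > 180 | y < 20 | y > 180))
  expect_equal(out$included, boxOracle)
  expect_true(all((out$exclusion_reason == "none") == out$included))
})

test_that("association fraction: trivial cases and histogram integrity", {
  recs <- data.frame(cell_id = c("a", "b"), x = 0, y = 0, z = 0,
                     distance_um = c(0, 0), included = TRUE,
                     exclusion_reason = "none")
  af <- associationFraction(recs)
  expect_equal(af$fraction, 1)

  recs$included <- FALSE
  expect_error(associationFraction(recs), "no included")

  set.seed(2)
  recs <- data.frame(cell_id = sprintf("c%d", 1:200), x = 0, y = 0, z = 0,
                     distance_um = runif(200, 0, 20), included = TRUE,
                     exclusion_reason = "none")
  af <- associationFraction(recs)
  expect_equal(sum(af$histogram$count), 200L)
  expect_equal(af$fraction, mean(recs$distance_um < 5))
  # the 5 um threshold is strict
  recs$distance_um[1] <- 5
  expect_equal(associationFraction(recs)$fraction,
               mean(recs$distance_um < 5))
})

test_that("cells seeded on vessels sit closer than uniform nuclei", {
  cfg <- simulationConfig(seed = 6)
  net <- generateVesselNetwork(cfg)
  cfg0 <- cfg; cfg0@noiseSd <- 0
  st <- rasterizeFrame(net, list(), 1L, cfg0)
  m <- buildVesselMask(st, "vessel", 50, skeletonize = FALSE)
  nrep <- 5
  hits <- 0
  for (r in seq_len(nrep)) {
    on <- placeCellsNearVessels(net, 200, 1, seed = r)$points
    nucCfg <- simulationConfig(seed = r + 50, nNuclei = 200L)
    nuc <- generateNuclei(nucCfg)
    dOn <- nearestVesselDistance(on, m)$distance_um
    dNuc <- nearestVesselDistance(nuc, m)$distance_um
    if (wilcox.test(dOn, dNuc, alternative = "less")$p.value < 0.001)
      hits <- hits + 1
    # only the on-vessel population has its histogram peak below 5 um
    recOn <- data.frame(cell_id = "x", x = 0, y = 0, z = 0,
                        distance_um = dOn, included = TRUE,
                        exclusion_reason = "none")
    hOn <- associationFraction(recOn)$histogram
    expect_lt(hOn$bin_start[which.max(hOn$count)], 5)
  }
  expect_gte(hits, nrep - 1)
})
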