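## Shared fixtures and independent oracles, all built in code.

## small, fast simulation world for unit tests
smallConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, durationH = 6, fieldSizeUm = c(80, 80, 40),
         nCellsPerMode = 3L, vesselNSegments = 10L,
         vesselSegmentLengthUm = 25, nNuclei = 200L),
    list(...))
  do.call(simulationConfig, args)
}

## a single axis-aligned capsule rasterized noise-free
capsuleStack <- function(seg, fieldSizeUm, voxelSizeUm = c(1, 1, 1)) {
  cfg <- simulationConfig(seed = 1, fieldSizeUm = fieldSizeUm,
                          voxelSizeUm = voxelSizeUm, vesselNSegments = 0L,
                          noiseSd = 0)
  rasterizeFrame(vesselNetwork(seg, fieldSizeUm), list(), 1L, cfg)
}

## independent brute-force oracle: nearest surface-voxel-centre distance.
## Recomputes the surface set by explicit 6-neighbour scanning and takes the
## plain minimum over all surface voxels; points in occupied voxels get 0.
bruteSurfaceDistance <- function(points, occ, voxelSizeUm) {
  d <- dim(occ)
  fgIdx <- which(occ, arr.ind = TRUE)
  isSurf <- logical(nrow(fgIdx))
  for (r in seq_len(nrow(fgIdx))) {
    v <- fgIdx[r, ]
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      nb <- v
      nb[axis] <- nb[axis] + s
      if (nb[axis] < 1L || nb[axis] > d[axis] ||
          !occ[nb[1], nb[2], nb[3]]) {
        isSurf[r] <- TRUE
      }
    }
  }
  surf <- fgIdx[isSurf, , drop = FALSE]
  sx <- (surf[, 3] - 0.5) * voxelSizeUm[3]
  sy <- (surf[, 2] - 0.5) * voxelSizeUm[2]
  sz <- (surf[, 1] - 0.5) * voxelSizeUm[1]
  apply(rbind(points), 1, function(p) {
    iz <- floor(p[3] / voxelSizeUm[1]) + 1
    iy <- floor(p[2] / voxelSizeUm[2]) + 1
    ix <- floor(p[1] / voxelSizeUm[3]) + 1
    if (iz >= 1 && iz <= d[1] && iy >= 1 && iy <= d[2] &&
        ix >= 1 && ix <= d[3] && occ[iz, iy, ix]) return(0)
    min(sqrt((sx - p[1])^2 + (sy - p[2])^2 + (sz - p[3])^2))
  })
}

## independent fixed-grid (Simpson) oracle for the Dunnett max-|T|
## distribution; a different numerical route than the package's nested
## adaptive quadrature
dunnettOracleP <- function(q, lambdas, df, nz = 801L, nu = 801L) {
  sq <- sqrt(1 - lambdas^2)
  z <- seq(-9, 9, length.out = nz)
  innerAt <- function(u) {
    acc <- rep(1, nz)
    for (j in seq_along(lambdas))
      acc <- acc * (pnorm((q * u - lambdas[j] * z) / sq[j]) -
                    pnorm((-q * u - lambdas[j] * z) / sq[j]))
    simpson(acc * dnorm(z), z)
  }
  if (!is.finite(df)) return(innerAt(1))
  lo <- sqrt(qchisq(1e-13, df) / df)
  hi <- sqrt(qchisq(1 - 1e-13, df) / df)
  u <- seq(lo, hi, length.out = nu)
  dens <- exp(log(2) + (df / 2) * log(df / 2) + (df - 1) * log(u) -
                df * u^2 / 2 - lgamma(df / 2))
  simpson(dens * vapply(u, innerAt, numeric(1)), u)
}

simpson <- function(y, x) {
  n <- length(x)
  if (n %% 2 == 0) { y <- y[-n]; x <- x[-n]; n <- n - 1 }
  h <- x[2] - x[1]
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, 2)]) +
             2 * sum(y[seq(3, n - 2, 2)]))
}

## render a two-channel stack with co-localized and distractor blobs
## (helper for detection tests); blobs: data.frame x, y, z, volume, channels
## ("both", "a", "b")
detectionStack <- function(blobs, fieldSizeUm, amplitude = 100) {
  d <- c(fieldSizeUm[3], fieldSizeUm[2], fieldSizeUm[1])
  a <- array(0, d); b <- array(0, d)
  for (i in seq_len(nrow(blobs))) {
    ctr <- as.numeric(blobs[i, c("x", "y", "z")])
    if (blobs$channels[i] %in% c("both", "a"))
      a <- renderGaussianBlobs(a, c(1, 1, 1), ctr, blobs$volume[i], amplitude)
    if (blobs$channels[i] %in% c("both", "b"))
      b <- renderGaussianBlobs(b, c(1, 1, 1), ctr, blobs$volume[i], amplitude)
  }
  volumeStack(list(a = a, b = b), c(1, 1, 1))
}
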