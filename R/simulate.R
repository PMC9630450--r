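#' @include AllClasses.R
NULL

## Precompute per-segment arrays for fast single-point distance queries.
segmentCache <- function(segments) {
  p0 <- as.matrix(segments[, c("x0", "y0", "z0")])
  d <- as.matrix(segments[, c("x1", "y1", "z1")]) - p0
  len2 <- rowSums(d * d)
  list(p0 = p0, d = d, len2 = pmax(len2, .Machine$double.eps),
       radius = segments$radius_um, n = nrow(segments))
}

## Distances from one point to every segment axis (vectorized over segments).
segmentAxisDistances <- function(p, cache) {
  rel <- sweep(cache$p0, 2, p, "-") * -1
  tt <- pmin(1, pmax(0, rowSums(rel * cache$d) / cache$len2))
  diff <- rel - cache$d * tt
  sqrt(rowSums(diff * diff))
}

#' Generate a radially biased synthetic vessel network
#'
#' Draws `vesselNSegments` capsule segments inside the field. With
#' probability `vesselRadialBias` a segment's orientation is sampled
#' uniformly within 30 degrees of the radial (+y) axis, otherwise uniformly
#' outside that cone, so the radially oriented fraction is exactly
#' Binomial(n, bias). Segment lengths are uniform in
#' 0.75--1.25 x `vesselSegmentLengthUm`; segments are shortened where needed
#' to keep both endpoints inside the field. Deterministic given the config
#' seed.
#'
#' @param config a [SimulationConfig-class].
#' @return a [VesselNetwork-class] (empty when zero segments are requested).
#' @examples
#' net <- generateVesselNetwork(simulationConfig(seed = 7, vesselNSegments = 20))
#' net
#' @export
generateVesselNetwork <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@vesselNSegments
  f <- config@fieldSizeUm
  if (n == 0L) return(vesselNetwork(data.frame(), f))
  cosCone <- cos(30 * pi / 180)
  if (any(f <= 2 * config@vesselRadiusUm + 1))
    stop("field too small for the requested vessel radius", call. = FALSE)
  withSeed(subSeed(config@seed, 1L), {
    radial <- stats::runif(n) < config@vesselRadialBias
    seg <- matrix(NA_real_, n, 7)
    for (i in seq_len(n)) {
      if (radial[i]) {
        # uniform on the double cone |dy| >= cos(30 deg)
        cy <- stats::runif(1, cosCone, 1) * sample(c(-1, 1), 1)
        phi <- stats::runif(1, 0, 2 * pi)
        r <- sqrt(1 - cy^2)
        d <- c(r * cos(phi), cy, r * sin(phi))
      } else {
        repeat {
          d <- drop(runifSphere(1))
          if (abs(d[2]) < cosCone) break
        }
      }
      len <- stats::runif(1, 0.75, 1.25) * config@vesselSegmentLengthUm
      # inset by one radius so the whole capsule (not just its axis) stays
      # inside the imaged field
      r <- config@vesselRadiusUm
      repeat {
        ctr <- r + stats::runif(3) * (f - 2 * r)
        # admissible half-extents keeping centre + t*d inside [r, field - r]
        lim <- function(ci, di, fi) {
          if (abs(di) < 1e-12) return(c(-Inf, Inf))
          sort(c((r - ci) / di, (fi - r - ci) / di))
        }
        lx <- lim(ctr[1], d[1], f[1]); ly <- lim(ctr[2], d[2], f[2])
        lz <- lim(ctr[3], d[3], f[3])
        tmin <- max(-len / 2, lx[1], ly[1], lz[1])
        tmax <- min(len / 2, lx[2], ly[2], lz[2])
        if (tmax - tmin >= 1) break
      }
      # clamp away float residue so endpoints sit inside the field exactly
      p0 <- pmin(pmax(ctr + tmin * d, r), f - r)
      p1 <- pmin(pmax(ctr + tmax * d, r), f - r)
      seg[i, ] <- c(p0, p1, config@vesselRadiusUm)
    }
    colnames(seg) <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius_um")
    vesselNetwork(as.data.frame(seg), f)
  })
}

#' Fraction of segments oriented within a cone of the radial axis
#'
#' @param network a [VesselNetwork-class].
#' @param maxAngleDeg half-opening of the cone around +y (default 30).
#' @return fraction of segments whose (undirected) orientation lies within
#'   `maxAngleDeg` of the radial axis; `NaN` for an empty network.
#' @export
radialOrientationFraction <- function(network, maxAngleDeg = 30) {
  seg <- segments(network)
  if (!nrow(seg)) return(NaN)
  d <- cbind(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)
  len <- sqrt(rowSums(d * d))
  mean(abs(d[, 2]) / len >= cos(maxAngleDeg * pi / 180))
}

#' Union-of-capsules volume fraction (Monte Carlo)
#'
#' Estimates the fraction of the field occupied by the vessel network dilated
#' by `dilationUm`, by seeded uniform sampling. This is the analytic
#' reference for nuclei-association checks (the dilated-set fraction equals
#' the expected fraction of uniform points within `dilationUm` of a vessel
#' surface).
#'
#' @param network a [VesselNetwork-class].
#' @param dilationUm dilation of each capsule radius, um (default 0).
#' @param nSamples Monte Carlo sample size.
#' @param seed RNG seed for the estimate (deterministic given seed).
#' @return a volume fraction in [0, 1]; 0 for an empty network.
#' @export
vesselVolumeFraction <- function(network, dilationUm = 0, nSamples = 50000L,
                                 seed = 0L) {
  seg <- segments(network)
  if (!nrow(seg)) return(0)
  f <- fieldSize(network)
  withSeed(subSeed(seed, 17L), {
    pts <- cbind(stats::runif(nSamples) * f[1], stats::runif(nSamples) * f[2],
                 stats::runif(nSamples) * f[3])
    covered <- rep(FALSE, nSamples)
    for (i in seq_len(nrow(seg))) {
      di <- pointSegmentAxisDistance(pts[!covered, , drop = FALSE],
                                     seg[i, , drop = FALSE])
      covered[!covered] <- di <= seg$radius_um[i] + dilationUm
    }
    mean(covered)
  })
}

## Lognormal meanlog/sdlog from arithmetic mean m and sd s.
lnormPars <- function(m, s) {
  if (s <= 0) return(list(meanlog = log(m), sdlog = 0))
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

reflectInto <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Generate synthetic migration tracks of the three observed modes
#'
#' Emulates the trajectory classes seen in cortical slice time-lapse imaging:
#' \describe{
#'   \item{erratic}{a persistent random walk in the slice plane: lognormal
#'     frame speeds, wrapped-normal turning angles, plus a constant
#'     surface-ward (+y) drift velocity. Fast and weakly persistent.}
#'   \item{radial}{surface-ward motion with small independent angular noise
#'     around +y; slower; cells stop on reaching the pial-side margin.}
#'   \item{vessel_guided}{agents that attach to the vessel network (when
#'     within `captureRadiusUm` of a capsule surface, with
#'     `attachProbPerFrame`), crawl along the segment axis at
#'     `vesselGuidedSpeedUmh` while riding at half a radius from the axis,
#'     and detach with `detachProbPerFrame` or at a segment end. Per-sample
#'     contact flags record the ground truth.}
#' }
#' Deterministic given the config seed. Hemisphere tags are assigned at
#' random per track.
#'
#' @param config a [SimulationConfig-class].
#' @param vessels a [VesselNetwork-class]; required non-empty when
#'   `"vessel_guided"` is among `modes`.
#' @param modes character subset of
#'   `c("erratic", "radial", "vessel_guided")`.
#' @return a list of [Track-class] objects (`nCellsPerMode` per mode).
#' @examples
#' cfg <- simulationConfig(seed = 3, nCellsPerMode = 2, durationH = 2)
#' trks <- generateTracks(cfg, generateVesselNetwork(cfg))
#' length(trks)
#' @export
generateTracks <- function(config, vessels,
                           modes = c("erratic", "radial", "vessel_guided")) {
  stopifnot(is(config, "SimulationConfig"))
  modes <- match.arg(modes, several.ok = TRUE)
  if ("vessel_guided" %in% modes &&
      (missing(vessels) || nSegments(vessels) == 0L))
    stop("vessel-guided tracks require a non-empty vessel network",
         call. = FALSE)
  f <- config@fieldSizeUm
  dt <- config@frameIntervalH
  times <- seq(0, config@durationH, by = dt)
  nf <- length(times)
  cache <- if (!missing(vessels) && nSegments(vessels) > 0L)
    segmentCache(segments(vessels)) else NULL

  withSeed(subSeed(config@seed, 2L), {
    out <- list()
    id <- 0L
    for (mode in modes) {
      for (cell in seq_len(config@nCellsPerMode)) {
        id <- id + 1L
        hemi <- sample(c("left", "right"), 1)
        pos <- matrix(NA_real_, nf, 3)
        contact <- rep(FALSE, nf)
        if (mode == "erratic") {
          p <- c(stats::runif(1) * f[1], stats::runif(1) * f[2],
                 stats::runif(1, 0.2, 0.8) * f[3])
          theta <- stats::runif(1, 0, 360)
          lp <- lnormPars(config@erraticSpeedMeanUmh, config@erraticSpeedSd)
          pos[1, ] <- p
          for (k in 2:nf) {
            theta <- theta + stats::rnorm(1, 0, config@erraticTurnSdDeg)
            sp <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
            step <- sp * dt * c(cos(theta * pi / 180), sin(theta * pi / 180), 0)
            step[2] <- step[2] + config@erraticDriftUmh * dt
            q <- p + step
            q[1] <- reflectInto(q[1], 0, f[1])
            q[2] <- reflectInto(q[2], 0, f[2])
            theta <- atan2(q[2] - p[2], q[1] - p[1]) * 180 / pi
            p <- q
            pos[k, ] <- p
          }
        } else if (mode == "radial") {
          p <- c(stats::runif(1) * f[1], stats::runif(1, 0, 0.3) * f[2],
                 stats::runif(1, 0.2, 0.8) * f[3])
          lp <- lnormPars(config@radialSpeedMeanUmh, config@radialSpeedSd)
          ytop <- f[2] - 5
          pos[1, ] <- p
          for (k in 2:nf) {
            if (p[2] >= ytop) { pos[k, ] <- p; next }  # arrived at the pia
            theta <- 90 + stats::rnorm(1, 0, config@radialTurnSdDeg)
            sp <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
            p <- p + sp * dt * c(cos(theta * pi / 180), sin(theta * pi / 180), 0)
            p[1] <- reflectInto(p[1], 0, f[1])
            p[2] <- min(p[2], ytop)
            pos[k, ] <- p
          }
        } else {  # vessel_guided
          p <- c(stats::runif(1) * f[1], stats::runif(1) * f[2],
                 stats::runif(1) * f[3])
          attached <- FALSE
          segi <- NA_integer_; sPos <- NA_real_; sDir <- 1
          radOff <- c(0, 0, 0)
          theta <- stats::runif(1, 0, 360)
          pos[1, ] <- p
          for (k in 2:nf) {
            if (!attached) {
              dists <- segmentAxisDistances(p, cache) - cache$radius
              near <- which.min(dists)
              if (dists[near] <= config@captureRadiusUm &&
                  stats::runif(1) < config@attachProbPerFrame) {
                attached <- TRUE
                segi <- near
                axis <- cache$d[segi, ] / sqrt(cache$len2[segi])
                rel <- p - cache$p0[segi, ]
                sPos <- min(max(sum(rel * axis), 0), sqrt(cache$len2[segi]))
                # travel surface-ward along the vessel when it has a y component
                sDir <- if (abs(axis[2]) > 1e-6) sign(axis[2]) else
                  sample(c(-1, 1), 1)
                perp <- rel - sum(rel * axis) * axis
                pn <- sqrt(sum(perp * perp))
                if (pn < 1e-9) { perp <- c(axis[2], -axis[1], 0); pn <- sqrt(sum(perp^2)) }
                radOff <- perp / pn * (0.5 * cache$radius[segi])
                p <- cache$p0[segi, ] + sPos * axis + radOff
              } else {
                # free search: persistent walk at the vessel-guided speed
                theta <- theta + stats::rnorm(1, 0, 45)
                p <- p + config@vesselGuidedSpeedUmh * dt *
                  c(cos(theta * pi / 180), sin(theta * pi / 180), 0)
                p[1] <- reflectInto(p[1], 0, f[1])
                p[2] <- reflectInto(p[2], 0, f[2])
              }
            } else {
              axis <- cache$d[segi, ] / sqrt(cache$len2[segi])
              segLen <- sqrt(cache$len2[segi])
              sPos <- sPos + sDir * config@vesselGuidedSpeedUmh * dt
              atEnd <- sPos <= 0 || sPos >= segLen
              sPos <- min(max(sPos, 0), segLen)
              p <- cache$p0[segi, ] + sPos * axis + radOff
              contact[k] <- TRUE
              if (atEnd || stats::runif(1) < config@detachProbPerFrame) {
                attached <- FALSE
                contact[k] <- TRUE  # still on the vessel this frame
              }
            }
            if (attached) contact[k] <- TRUE
            pos[k, ] <- p
          }
        }
        out[[id]] <- track(
          trackId = sprintf("%s_%03d", mode, cell),
          samples = data.frame(t_h = times, x_um = pos[, 1], y_um = pos[, 2],
                               z_um = pos[, 3]),
          hemisphere = hemi, trueMode = mode,
          contact = if (mode == "vessel_guided") contact else logical())
      }
    }
    out
  })
}

#' Generate a uniform nuclei reference cloud
#'
#' Emulates the DAPI-stained non-selected nuclei used as the reference
#' population for vessel-distance comparisons: points uniform over the field.
#' Deterministic given the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @param n number of nuclei (defaults to `config@nNuclei`).
#' @return an `n x 3` matrix with columns `x`, `y`, `z` (um).
#' @export
generateNuclei <- function(config, n = config@nNuclei) {
  stopifnot(is(config, "SimulationConfig"))
  n <- as.integer(n)
  if (n == 0L)
    return(matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  f <- config@fieldSizeUm
  withSeed(subSeed(config@seed, 3L), {
    cbind(x = stats::runif(n) * f[1], y = stats::runif(n) * f[2],
          z = stats::runif(n) * f[3])
  })
}

#' Place synthetic cells with a known on-vessel fraction
#'
#' Fixture generator for association-recovery checks: a chosen fraction of
#' cells is placed just outside a vessel surface (surface distance uniform in
#' (0, `maxOffsetUm`), i.e. vessel-associated under the 5 um threshold); the
#' remainder is sampled uniformly over the field but rejection-sampled to lie
#' farther than `offMinDistanceUm` from any vessel surface, so the `onVessel`
#' flags are a true ground-truth labelling under the association threshold.
#'
#' @param network a non-empty [VesselNetwork-class].
#' @param n number of cells.
#' @param onFraction fraction placed on vessels.
#' @param seed RNG seed.
#' @param maxOffsetUm maximum surface offset for on-vessel cells (default 2).
#' @param offMinDistanceUm minimum surface distance for off-vessel cells
#'   (default 5, the association threshold).
#' @return list with `points` (n x 3 matrix) and `onVessel` (logical ground
#'   truth).
#' @export
placeCellsNearVessels <- function(network, n, onFraction, seed = 1L,
                                  maxOffsetUm = 2, offMinDistanceUm = 5) {
  seg <- segments(network)
  if (!nrow(seg)) stop("network must be non-empty", call. = FALSE)
  f <- fieldSize(network)
  nOn <- round(n * onFraction)
  withSeed(subSeed(seed, 11L), {
    d <- cbind(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)
    len <- sqrt(rowSums(d * d))
    pts <- matrix(NA_real_, n, 3)
    i <- 0L
    while (i < nOn) {
      si <- sample.int(nrow(seg), 1, prob = len)
      axis <- d[si, ] / len[si]
      base <- c(seg$x0[si], seg$y0[si], seg$z0[si]) + stats::runif(1) * len[si] * axis
      u <- drop(runifSphere(1))
      perp <- u - sum(u * axis) * axis
      pn <- sqrt(sum(perp * perp))
      if (pn < 1e-6) next
      p <- base + perp / pn * (seg$radius_um[si] + stats::runif(1, 0, maxOffsetUm))
      if (any(p < 0) || any(p > f)) next
      i <- i + 1L
      pts[i, ] <- p
    }
    while (i < n) {
      p <- c(stats::runif(1) * f[1], stats::runif(1) * f[2],
             stats::runif(1) * f[3])
      if (pointCapsuleSurfaceDistance(rbind(p), seg) <= offMinDistanceUm)
        next
      i <- i + 1L
      pts[i, ] <- p
    }
    colnames(pts) <- c("x", "y", "z")
    list(points = pts, onVessel = seq_len(n) <= nOn)
  })
}

#' Simulate a per-brain cortical depth dataset with a known superficial bias
#'
#' Desk-scale analog of a positioning-perturbation experiment: for each
#' brain, each cell falls in the most superficial quarter of the cortical
#' plate (relative depth uniform in [0, 0.25)) with probability
#' `superficialProb`, otherwise uniformly in [0.25, 1]. Lowering
#' `superficialProb` emulates a knockdown that depletes bin 1.
#'
#' @param nBrains brains per group.
#' @param nCellsPerBrain cells per brain.
#' @param superficialProb probability of superficial placement.
#' @param seed RNG seed.
#' @return data.frame with columns `brain` (factor) and `depth` in [0, 1].
#' @export
simulateDepthDataset <- function(nBrains = 10L, nCellsPerBrain = 100L,
                                 superficialProb = 0.4, seed = 1L) {
  withSeed(subSeed(seed, 13L), {
    res <- lapply(seq_len(nBrains), function(b) {
      sup <- stats::runif(nCellsPerBrain) < superficialProb
      depth <- ifelse(sup, stats::runif(nCellsPerBrain) * 0.25,
                      0.25 + stats::runif(nCellsPerBrain) * 0.75)
      data.frame(brain = sprintf("brain%02d", b), depth = depth)
    })
    out <- do.call(rbind, res)
    out$brain <- factor(out$brain)
    out
  })
}
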