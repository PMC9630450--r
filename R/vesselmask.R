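#' @include AllClasses.R
NULL

## neighbour offset tables ----------------------------------------------------

offsets6 <- matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
                   ncol = 3, byrow = TRUE)

offsets26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ])
})

## shift a 3D logical array by one voxel along an axis, padding with FALSE
shiftPad <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (by == 1) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## logical array marking occupied voxels with at least one empty 6-neighbour
## (out-of-bounds neighbours count as empty)
surfaceMask <- function(occ) {
  allNeighborsOcc <- array(TRUE, dim(occ))
  for (axis in 1:3) for (by in c(-1, 1))
    allNeighborsOcc <- allNeighborsOcc & shiftPad(occ, axis, by)
  occ & !allNeighborsOcc
}

#' 3D connected components labelling
#'
#' Breadth-first labelling of a logical (Z, Y, X) array under 6- or
#' 26-connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return list with `labels` (integer array, 0 = background) and `sizes`
#'   (integer vector of component sizes, index = label).
#' @export
connectedComponents3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- if (connectivity == 26) offsets26 else offsets6
  labels <- array(0L, d)
  fg <- which(mask)
  sizes <- integer()
  lab <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    size <- 1L
    frontier <- seed
    while (length(frontier)) {
      # linear -> (iz, iy, ix)
      iz <- (frontier - 1L) %% d[1] + 1L
      rest <- (frontier - 1L) %/% d[1]
      iy <- rest %% d[2] + 1L
      ix <- rest %/% d[2] + 1L
      nz <- rep(iz, each = nrow(off)) + off[, 1]
      ny <- rep(iy, each = nrow(off)) + off[, 2]
      nx <- rep(ix, each = nrow(off)) + off[, 3]
      ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] &
        nx >= 1L & nx <= d[3]
      lin <- unique(nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2])
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      size <- size + length(lin)
      frontier <- lin
    }
    sizes[lab] <- size
  }
  list(labels = labels, sizes = sizes)
}

## ---------------------------------------------------------------------------
## Curve skeleton by ordered topological thinning: boundary voxels are peeled
## in grassfire (erosion-depth) order; a voxel is removed only when it is a
## simple point (removal preserves local topology) and not a curve endpoint.
## Simple-point test per the standard 26/6 characterization: exactly one
## 26-component of foreground among the 26 neighbours, and exactly one
## 6-component of background within the 18-neighbourhood that touches the
## centre by a face.
## ---------------------------------------------------------------------------

## positions in the 3x3x3 cube (coordinates in -1..1), plus adjacency tables,
## precomputed once at load time
.cube <- local({
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  centerIdx <- which(rowSums(abs(g)) == 0)
  n18 <- which(rowSums(abs(g)) <= 2 & rowSums(abs(g)) > 0)
  n26 <- which(rowSums(abs(g)) > 0)
  face <- which(rowSums(abs(g)) == 1)
  dist1 <- as.matrix(stats::dist(g, method = "maximum"))
  adj26 <- dist1 <= 1 & dist1 > 0
  man <- as.matrix(stats::dist(g, method = "manhattan"))
  adj6 <- man == 1
  list(g = g, center = centerIdx, n18 = n18, n26 = n26, face = face,
       adj26 = adj26, adj6 = adj6)
})

## count connected components among cube positions `nodes` under `adj`
countCubeComponents <- function(nodes, adj) {
  if (!length(nodes)) return(0L)
  seen <- logical(length(nodes))
  comp <- 0L
  for (s in seq_along(nodes)) {
    if (seen[s]) next
    comp <- comp + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adj[nodes[cur], nodes] & !seen)
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
  }
  comp
}

## is the foreground voxel at cube `nb` (27-vector, centre foreground) simple?
isSimplePoint <- function(nb) {
  fg <- intersect(.cube$n26, which(nb))
  if (countCubeComponents(fg, .cube$adj26) != 1L) return(FALSE)
  bgFace <- intersect(.cube$face, which(!nb))
  if (!length(bgFace)) return(FALSE)
  bg18 <- intersect(.cube$n18, which(!nb))
  # 6-components of background within N18; count only those meeting a face
  seen <- logical(length(bg18))
  comps <- 0L
  for (s in seq_along(bg18)) {
    if (seen[s]) next
    stack <- s; seen[s] <- TRUE
    members <- bg18[s]
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      nbr <- which(.cube$adj6[bg18[cur], bg18] & !seen)
      seen[nbr] <- TRUE
      members <- c(members, bg18[nbr])
      stack <- c(stack, nbr)
    }
    if (any(members %in% bgFace)) comps <- comps + 1L
  }
  comps == 1L
}

## grassfire (erosion depth) transform: level 1 = first peeled boundary
grassfireLevels <- function(occ) {
  lev <- array(0L, dim(occ))
  cur <- occ
  level <- 0L
  while (any(cur)) {
    level <- level + 1L
    b <- surfaceMask(cur)
    lev[b] <- level
    cur <- cur & !b
  }
  lev
}

## extract the 27-voxel neighbourhood of (iz, iy, ix), FALSE outside
cubeAt <- function(occ, iz, iy, ix, d) {
  nb <- logical(27)
  for (j in 1:27) {
    z <- iz + .cube$g[j, 1]; y <- iy + .cube$g[j, 2]; x <- ix + .cube$g[j, 3]
    if (z >= 1 && z <= d[1] && y >= 1 && y <= d[2] && x >= 1 && x <= d[3])
      nb[j] <- occ[z, y, x]
  }
  nb
}

## prune discretization spurs: iteratively remove curve endpoints whose
## erosion depth is strictly below that of their deepest skeleton neighbour
## (walks tails down the grassfire gradient; genuine axis ends sit on the
## depth plateau and survive)
pruneSpurs <- function(work, lev, d) {
  repeat {
    removed <- FALSE
    for (lin in which(work)) {
      iz <- (lin - 1L) %% d[1] + 1L
      rest <- (lin - 1L) %/% d[1]
      iy <- rest %% d[2] + 1L
      ix <- rest %/% d[2] + 1L
      nz <- iz + offsets26[, 1]; ny <- iy + offsets26[, 2]
      nx <- ix + offsets26[, 3]
      ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] &
        nx >= 1L & nx <= d[3]
      nb <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
      nb <- nb[work[nb]]
      if (length(nb) == 1L && lev[lin] < lev[nb]) {
        work[lin] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  work
}

## 3D medial-axis thinning; returns matrix of (iz, iy, ix) skeleton voxels
thinningSkeleton <- function(occ) {
  d <- dim(occ)
  work <- occ
  lev <- grassfireLevels(occ)
  ord <- which(occ)
  ord <- ord[order(lev[ord])]
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (lin in ord) {
      if (!work[lin]) next
      iz <- (lin - 1L) %% d[1] + 1L
      rest <- (lin - 1L) %/% d[1]
      iy <- rest %% d[2] + 1L
      ix <- rest %/% d[2] + 1L
      nb <- cubeAt(work, iz, iy, ix, d)
      nFg <- sum(nb[.cube$n26])
      if (nFg <= 1L) next                       # curve endpoint: keep
      if (!any(!nb[.cube$face])) next           # interior voxel: not yet peelable
      if (isSimplePoint(nb)) {
        work[lin] <- FALSE
        changed <- TRUE
      }
    }
    ord <- ord[work[ord]]
  }
  work <- pruneSpurs(work, lev, d)
  which(work, arr.ind = TRUE)
}

#' Build a voxelized vessel mask from an intensity channel
#'
#' Thresholds the vessel channel (voxels at or above `threshold` are
#' foreground), removes small objects (26-connected components below
#' `minComponentVoxels`), and derives the 6-connectivity surface and a
#' medial-axis curve skeleton by ordered topological thinning. The skeleton
#' is retained for QC and path projection only; distances are always
#' computed to the surface.
#'
#' @param stack a [VolumeStack-class].
#' @param channel name of the vessel channel.
#' @param threshold intensity threshold (finite).
#' @param config an [AnalysisConfig-class] (small-object removal size).
#' @param skeletonize compute the thinning skeleton (default TRUE; skip for
#'   large masks where only distances are needed).
#' @return a [VesselMask-class]. An empty foreground yields a valid mask
#'   with `emptyForeground = TRUE` and a warning.
#' @export
buildVesselMask <- function(stack, channel, threshold,
                            config = analysisConfig(), skeletonize = TRUE) {
  stopifnot(is(stack, "VolumeStack"))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  ch <- getChannel(stack, channel)
  occ <- ch >= threshold
  if (any(occ) && config@minComponentVoxels > 1L) {
    cc <- connectedComponents3d(occ, 26)
    keep <- which(cc$sizes >= config@minComponentVoxels)
    occ <- array(cc$labels %in% keep, dim(occ)) & occ
  }
  empty <- !any(occ)
  if (empty) warning("thresholding produced an empty vessel mask", call. = FALSE)
  surf <- which(surfaceMask(occ), arr.ind = TRUE)
  skel <- if (!empty && skeletonize) thinningSkeleton(occ)
  else matrix(integer(), 0, 3)
  colnames(skel) <- colnames(surf) <- c("iz", "iy", "ix")
  new("VesselMask", occupancy = occ, voxelSizeUm = voxelSize(stack),
      skeleton = skel, surface = surf, emptyForeground = empty)
}
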