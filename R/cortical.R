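#' @include stats.R
NULL

## shift a numeric 3D array, padding with -Inf (for maxima tests)
shiftPadNum <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(-Inf, d)
  sz <- seq_len(d[1]); sy <- seq_len(d[2]); sx <- seq_len(d[3])
  dstz <- sz + dz; dsty <- sy + dy; dstx <- sx + dx
  okz <- dstz >= 1 & dstz <= d[1]
  oky <- dsty >= 1 & dsty <= d[2]
  okx <- dstx >= 1 & dstx <= d[3]
  out[dstz[okz], dsty[oky], dstx[okx]] <- a[sz[okz], sy[oky], sx[okx]]
  out
}

#' Detect double-positive cells via the channel-product rule
#'
#' Automatic identification of co-labelled cells: the voxelwise product of
#' the two channels (computed in double precision, never wrapped) is
#' thresholded, 26-connected components are extracted, components containing
#' at least one local intensity maximum of the product are kept, and a size
#' filter retains only components with physical volume strictly larger than
#' `sizeFilterUm3` (default 6000 um^3). One detection per component, at the
#' product-intensity-weighted centroid.
#'
#' A blob present in only one channel yields a near-zero product and no
#' detection: co-localization is required.
#'
#' @param stack a [VolumeStack-class].
#' @param chA,chB channel names.
#' @param threshold threshold applied to the channel product (no universal
#'   default exists; it depends on the rendering amplitudes).
#' @param config an [AnalysisConfig-class] (size filter).
#' @return data.frame with `cell_id, x, y, z, volume_um3, mean_a, mean_b`
#'   (possibly zero rows).
#' @export
detectDoublePositive <- function(stack, chA, chB, threshold,
                                 config = analysisConfig()) {
  stopifnot(is(stack, "VolumeStack"))
  a <- getChannel(stack, chA)
  b <- getChannel(stack, chB)
  pr <- a * b  # double precision: saturated products widen, never wrap
  fg <- pr >= threshold
  if (!any(fg))
    return(data.frame(cell_id = character(), x = numeric(), y = numeric(),
                      z = numeric(), volume_um3 = numeric(),
                      mean_a = numeric(), mean_b = numeric()))
  # local maxima of the product under 26-connectivity
  isMax <- array(TRUE, dim(pr))
  for (i in seq_len(nrow(offsets26))) {
    o <- offsets26[i, ]
    isMax <- isMax & pr >= shiftPadNum(pr, o[1], o[2], o[3])
  }
  cc <- connectedComponents3d(fg, 26)
  v <- voxelSize(stack)
  voxelVol <- prod(v)
  maxLabels <- unique(cc$labels[isMax & fg])
  rows <- list()
  cid <- 0L
  for (lab in seq_along(cc$sizes)) {
    vol <- cc$sizes[lab] * voxelVol
    if (!(vol > config@sizeFilterUm3)) next
    if (!lab %in% maxLabels) next
    idx <- which(cc$labels == lab, arr.ind = TRUE)
    w <- pr[cbind(idx)]
    phys <- indexToPhys(idx, v)
    ctr <- colSums(phys * w) / sum(w)
    cid <- cid + 1L
    rows[[cid]] <- data.frame(cell_id = sprintf("det_%d", cid),
                              x = ctr[1], y = ctr[2], z = ctr[3],
                              volume_um3 = vol,
                              mean_a = mean(a[cbind(idx)]),
                              mean_b = mean(b[cbind(idx)]))
  }
  if (!length(rows))
    return(data.frame(cell_id = character(), x = numeric(), y = numeric(),
                      z = numeric(), volume_um3 = numeric(),
                      mean_a = numeric(), mean_b = numeric()))
  do.call(rbind, rows)
}

#' Relative cortical depth of detections
#'
#' Projects each centroid onto the depth axis (the inward normal to the pia,
#' i.e. minus the radial axis of the cortical frame) and maps the projection
#' affinely so the upper (pial-side) cortical-plate border is 0 and the
#' lower border 1. Cells outside [0, 1] are flagged out-of-range and are to
#' be excluded from binning.
#'
#' @param detections data.frame with `x`, `y` centroid columns (um) and
#'   optionally `cell_id`.
#' @param frame a [CorticalFrame-class].
#' @return data.frame with `cell_id, depth_rel, in_range`.
#' @export
relativeDepth <- function(detections, frame) {
  stopifnot(is(frame, "CorticalFrame"))
  ax <- radialAxis(frame)
  s <- -(detections$x * ax[1] + detections$y * ax[2])  # depth increases inward
  depth <- (s - frame@upperBorderUm) /
    (frame@lowerBorderUm - frame@upperBorderUm)
  ids <- if (!is.null(detections$cell_id)) detections$cell_id
  else sprintf("cell_%d", seq_along(depth))
  data.frame(cell_id = ids, depth_rel = depth,
             in_range = depth >= 0 & depth <= 1)
}

#' Binned cortical depth distribution
#'
#' Divides the cortical plate into `nBins` equal-width depth bins; bin 1 is
#' the most superficial (depth near 0). Internal edges are half-open toward
#' the deeper bin (`[a, b)`; a depth of exactly 0.25 with four bins falls in
#' bin 2) and the last bin is closed. Counts always sum to the number of
#' input depths.
#'
#' @param depths numeric vector of relative depths, all in [0, 1].
#' @param config an [AnalysisConfig-class].
#' @return integer vector of counts, one per bin (names `bin1..binN`).
#' @export
binDistribution <- function(depths, config = analysisConfig()) {
  if (length(depths) && (any(depths < 0) || any(depths > 1)))
    stop("all depths must lie in [0, 1]; exclude out-of-range cells first",
         call. = FALSE)
  n <- config@nBins
  idx <- pmin(floor(depths * n) + 1L, n)  # last bin closed at 1
  counts <- tabulate(idx, nbins = n)
  names(counts) <- paste0("bin", seq_len(n))
  counts
}

#' Per-brain bin fractions from a depth dataset
#'
#' @param data data.frame with `brain` and `depth` columns (depths in
#'   [0, 1]).
#' @param config an [AnalysisConfig-class].
#' @return data.frame with `brain, bin, fraction`.
#' @export
perBrainBinFractions <- function(data, config = analysisConfig()) {
  brains <- unique(as.character(data$brain))
  rows <- lapply(brains, function(b) {
    counts <- binDistribution(data$depth[data$brain == b], config)
    data.frame(brain = b, bin = seq_along(counts),
               fraction = as.numeric(counts) / sum(counts))
  })
  do.call(rbind, rows)
}

#' Group comparison of per-brain bin fractions
#'
#' Per-bin multiple comparisons with the brain as the unit of analysis:
#' Dunnett's many-to-one test against a control group (the default), or
#' Tukey all-pairs. Groups with a single brain are rejected for inference
#' (descriptives are still reported). Descriptives follow the mean +/- SD
#' convention of scatter-dot displays.
#'
#' @param data data.frame with columns `group, brain, bin, fraction` (e.g.
#'   built by row-binding [perBrainBinFractions()] results with a `group`
#'   column added).
#' @param control control group name (required for dunnett).
#' @param method `"dunnett"` or `"tukey"`.
#' @return list with `reports` (one [TestReport-class] per bin, named
#'   `bin1..binN`) and `descriptives` (data.frame `group, bin, n_brains,
#'   mean, sd`).
#' @export
compareBinFractions <- function(data, control = NULL,
                                method = c("dunnett", "tukey")) {
  method <- match.arg(method)
  grps <- unique(as.character(data$group))
  if (length(grps) < 2L) stop("at least two groups are required", call. = FALSE)
  nBrains <- vapply(grps, function(g)
    length(unique(data$brain[data$group == g])), 1L)
  desc <- do.call(rbind, lapply(split(data, list(data$group, data$bin),
                                      drop = TRUE), function(d)
    data.frame(group = d$group[1], bin = d$bin[1],
               n_brains = nrow(d), mean = mean(d$fraction),
               sd = stats::sd(d$fraction))))
  rownames(desc) <- NULL
  if (any(nBrains < 2L)) {
    warning("groups with a single brain: inference rejected, descriptives only",
            call. = FALSE)
    return(list(reports = NULL, descriptives = desc))
  }
  bins <- sort(unique(data$bin))
  reports <- lapply(bins, function(bn) {
    g <- lapply(grps, function(gr)
      data$fraction[data$group == gr & data$bin == bn])
    names(g) <- grps
    runTest(g, method = method, control = control, unit = "brain")
  })
  names(reports) <- paste0("bin", bins)
  list(reports = reports, descriptives = desc)
}
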