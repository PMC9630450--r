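#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Track / vessel CSV dialects
## ---------------------------------------------------------------------------

#' Write tracks to CSV
#'
#' One row per sample, header
#' `track_id,hemisphere,frame,t_h,x_um,y_um,z_um,true_mode,contact`.
#'
#' @param tracks list of [Track-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTracksCsv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    s <- samples(tr)
    ct <- contactFlags(tr)
    data.frame(track_id = trackId(tr), hemisphere = hemisphere(tr),
               frame = seq_len(nrow(s)) - 1L, t_h = s$t_h, x_um = s$x_um,
               y_um = s$y_um, z_um = s$z_um, true_mode = trueMode(tr),
               contact = if (length(ct)) ct else NA)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' @param path CSV in the [writeTracksCsv()] dialect.
#' @return list of [Track-class].
#' @export
readTracksCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "hemisphere", "t_h", "x_um", "y_um", "z_um")
  if (!all(need %in% names(d)))
    stop("track CSV must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(d, d$track_id), function(g) {
    g <- g[order(g$t_h), ]
    ct <- if (!is.null(g$contact) && !anyNA(g$contact)) as.logical(g$contact)
    else logical()
    track(g$track_id[1], g[, c("t_h", "x_um", "y_um", "z_um")],
          hemisphere = g$hemisphere[1],
          trueMode = if (is.null(g$true_mode)) NA_character_
          else as.character(g$true_mode[1]),
          contact = ct)
  })
}

#' Write vessel segments to CSV
#'
#' Header `segment_id,x0,y0,z0,x1,y1,z1,radius_um`.
#'
#' @param network a [VesselNetwork-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeVesselsCsv <- function(network, path) {
  utils::write.csv(segments(network), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read vessel segments from CSV
#'
#' @param path CSV in the [writeVesselsCsv()] dialect.
#' @param fieldSizeUm numeric(3) field extents (X, Y, Z), um.
#' @return a [VesselNetwork-class].
#' @export
readVesselsCsv <- function(path, fieldSizeUm) {
  vesselNetwork(utils::read.csv(path), fieldSizeUm)
}

## ---------------------------------------------------------------------------
## TrackMate-dialect XML (spots + edges, physical units required)
## ---------------------------------------------------------------------------

.micronUnits <- c("micron", "microns", "um", "µm", "micrometer",
                  "micrometre")

#' Read tracks from TrackMate-dialect XML
#'
#' Parses the `Model/AllSpots` spot table and `Model/AllTracks` edge lists of
#' a TrackMate file. Physical units are required: the model's
#' `spatialunits` must be micrometres (e.g. "micron", "um"); pixel or other
#' units are a hard error, as is a missing attribute. Spot times come from
#' `POSITION_T` and are interpreted with `timeUnitsToH`.
#'
#' @param path XML file.
#' @param hemisphere hemisphere tag to assign (TrackMate does not carry
#'   one); default "right".
#' @param timeUnitsToH factor converting `POSITION_T` units to hours
#'   (e.g. `1/3600` for seconds; default 1, i.e. already hours).
#' @return list of [Track-class].
#' @export
readTrackMate <- function(path, hemisphere = "right", timeUnitsToH = 1) {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing"))
    stop("not a TrackMate file: no <Model> element", call. = FALSE)
  su <- xml2::xml_attr(model, "spatialunits")
  if (is.na(su) || !tolower(su) %in% .micronUnits)
    stop(sprintf("unit mismatch: spatialunits '%s' are not physical micrometres",
                 if (is.na(su)) "<missing>" else su), call. = FALSE)
  spots <- xml2::xml_find_all(model, ".//AllSpots//Spot")
  if (!length(spots)) stop("no spots in file", call. = FALSE)
  sid <- xml2::xml_attr(spots, "ID")
  sx <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  sy <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  sz <- as.numeric(xml2::xml_attr(spots, "POSITION_Z"))
  st <- as.numeric(xml2::xml_attr(spots, "POSITION_T"))
  sz[is.na(sz)] <- 0
  spotTab <- data.frame(id = sid, x = sx, y = sy, z = sz,
                        t = st * timeUnitsToH)
  trackNodes <- xml2::xml_find_all(model, ".//AllTracks/Track")
  out <- list()
  for (tn in trackNodes) {
    tid <- xml2::xml_attr(tn, "TRACK_ID")
    edges <- xml2::xml_find_all(tn, ".//Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    g <- spotTab[spotTab$id %in% ids, ]
    if (nrow(g) < 2L) next
    g <- g[order(g$t), ]
    out[[paste0("track_", tid)]] <- track(
      paste0("track_", tid),
      data.frame(t_h = g$t, x_um = g$x, y_um = g$y, z_um = g$z),
      hemisphere = hemisphere)
  }
  out
}

## ---------------------------------------------------------------------------
## Minimal baseline TIFF (uncompressed, little-endian, one channel per file).
## No TIFF library exists in this R stack, so the subset needed for volume
## interchange is implemented here: grayscale multi-page, 32-bit float out;
## 8/16-bit unsigned or 32-bit float in. Voxel sizes travel in a sidecar
## JSON, never in TIFF tags.
## ---------------------------------------------------------------------------

tiffEntry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits in 4 bytes for all our tags
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == 3L)
      c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
        as.raw(c(0, 0)))
    else writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

#' Write a (Z, Y, X) volume as a multi-page 32-bit float TIFF
#'
#' @param vol numeric 3D array in (Z, Y, X) order.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeVolumeTiff <- function(vol, path) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  nz <- d[1]; height <- d[2]; width <- d[3]
  pageBytes <- height * width * 4
  nEntries <- 9L
  ifdBytes <- 2 + nEntries * 12 + 4
  dataStart <- 8
  ifdStart <- dataStart + nz * pageBytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifdStart), con, size = 4, endian = "little")
  for (z in seq_len(nz))
    writeBin(as.numeric(t(vol[z, , ])), con, size = 4, endian = "little")
  for (z in seq_len(nz)) {
    off <- dataStart + (z - 1) * pageBytes
    nextIfd <- if (z < nz) ifdStart + z * ifdBytes else 0L
    writeBin(as.integer(nEntries), con, size = 2, endian = "little")
    writeBin(c(tiffEntry(256, 4, 1, width),
               tiffEntry(257, 4, 1, height),
               tiffEntry(258, 3, 1, 32),
               tiffEntry(259, 3, 1, 1),
               tiffEntry(262, 3, 1, 1),
               tiffEntry(273, 4, 1, off),
               tiffEntry(278, 4, 1, height),
               tiffEntry(279, 4, 1, pageBytes),
               tiffEntry(339, 3, 1, 3)), con)
    writeBin(as.integer(nextIfd), con, size = 4, endian = "little")
  }
  invisible(path)
}

readUint <- function(r, size) {
  sum(as.numeric(r) * 256^(seq_len(size) - 1))
}

#' Read a multi-page grayscale TIFF into a (Z, Y, X) volume
#'
#' Supports the uncompressed little-endian baseline subset written by
#' [writeVolumeTiff()] plus 8/16-bit unsigned grayscale.
#'
#' @param path TIFF file.
#' @return numeric 3D array (Z, Y, X).
#' @export
readVolumeTiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(raw[1:2]), "II"))
    stop("only little-endian TIFF is supported", call. = FALSE)
  u <- function(off, size) readUint(raw[(off + 1):(off + size)], size)
  if (u(2, 2) != 42) stop("not a TIFF file", call. = FALSE)
  ifd <- u(4, 4)
  pages <- list()
  typeSize <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)
  while (ifd != 0) {
    n <- u(ifd, 2)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2 + (i - 1) * 12
      tag <- u(e, 2); type <- u(e + 2, 2); cnt <- u(e + 4, 4)
      sz <- typeSize[as.character(type)]
      if (is.na(sz)) next
      valOff <- if (cnt * sz <= 4) e + 8 else u(e + 8, 4)
      tags[[as.character(tag)]] <- vapply(seq_len(cnt) - 1, function(k)
        u(valOff + k * sz, min(sz, 4)), numeric(1))
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    width <- g(256)[1]; height <- g(257)[1]
    bits <- g(258, 8)[1]; comp <- g(259, 1)[1]; fmt <- g(339, 1)[1]
    spp <- g(277, 1)[1]
    offs <- g(273); nbytes <- g(279)
    if (comp != 1) stop("compressed TIFF is not supported", call. = FALSE)
    if (spp != 1)
      stop("only single-sample (grayscale) TIFF is supported", call. = FALSE)
    bytes <- do.call(c, lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + nbytes[k])]))
    vals <- if (fmt == 3 && bits == 32)
      readBin(bytes, "numeric", width * height, size = 4, endian = "little")
    else if (fmt == 1 && bits == 8) as.numeric(bytes)
    else if (fmt == 1 && bits == 16)
      readBin(bytes, "integer", width * height, size = 2, signed = FALSE,
              endian = "little")
    else stop("unsupported sample format", call. = FALSE)
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = height,
                                          ncol = width, byrow = TRUE)
    ifd <- u(ifd + 2 + n * 12, 4)
  }
  d <- dim(pages[[1]])
  vol <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  vol
}

#' Write a VolumeStack as per-channel TIFFs with a sidecar JSON
#'
#' Voxel sizes are recorded in `<prefix>_meta.json` (never trusted from TIFF
#' tags).
#'
#' @param stack a [VolumeStack-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
writeVolumeStack <- function(stack, dir, prefix = "volume") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (ch in channelNames(stack)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    writeVolumeTiff(getChannel(stack, ch), p)
    paths[ch] <- p
  }
  meta <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(list(voxel_size_um = voxelSize(stack),
                            channels = channelNames(stack)),
                       meta, auto_unbox = FALSE, digits = NA)
  paths["meta"] <- meta
  invisible(paths)
}

#' Read a VolumeStack written by [writeVolumeStack()]
#'
#' @param dir directory.
#' @param prefix file-name prefix.
#' @return a [VolumeStack-class].
#' @export
readVolumeStack <- function(dir, prefix = "volume") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", prefix)),
                              simplifyVector = TRUE)
  chans <- lapply(meta$channels, function(ch)
    readVolumeTiff(file.path(dir, sprintf("%s_%s.tif", prefix, ch))))
  names(chans) <- meta$channels
  volumeStack(chans, meta$voxel_size_um)
}

## ---------------------------------------------------------------------------
## JSON configuration (snake_case keys; unknown keys rejected)
## ---------------------------------------------------------------------------

snakeToCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)

configFromList <- function(lst, constructor, what) {
  if (!length(lst)) return(constructor())
  keys <- snakeToCamel(names(lst))
  known <- setdiff(names(formals(constructor)), "")
  bad <- keys[!keys %in% known]
  if (length(bad))
    stop(sprintf("unknown %s config key(s): %s", what,
                 paste(names(lst)[!keys %in% known], collapse = ", ")),
         call. = FALSE)
  names(lst) <- keys
  lst <- lapply(lst, unlist)
  do.call(constructor, lst)
}

#' Read a pipeline configuration JSON
#'
#' The file holds per-module sections: `{"simulation": {...}, "analysis":
#' {...}}` with snake_case keys mirroring the constructor arguments (e.g.
#' `frame_interval_h`, `speed_gate_umh`). Unknown keys and unknown sections
#' are rejected.
#'
#' @param path JSON file.
#' @return list with `simulation` ([SimulationConfig-class]) and `analysis`
#'   ([AnalysisConfig-class]).
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), c("simulation", "analysis"))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  list(simulation = configFromList(cfg$simulation, simulationConfig,
                                   "simulation"),
       analysis = configFromList(cfg$analysis, analysisConfig, "analysis"))
}

#' Write a pipeline configuration JSON
#'
#' @param simulation a [SimulationConfig-class].
#' @param analysis an [AnalysisConfig-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePipelineConfig <- function(simulation, analysis, path) {
  toSnake <- function(x) tolower(gsub("([A-Z])", "_\\1", x))
  dump <- function(obj) {
    nm <- slotNames(class(obj))
    vals <- lapply(nm, function(s) slot(obj, s))
    names(vals) <- vapply(nm, toSnake, "")
    vals
  }
  jsonlite::write_json(list(simulation = dump(simulation),
                            analysis = dump(analysis)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
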