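#' @include io.R contacts.R cortical.R trajectory.R rasterize.R
NULL

pipelineStages <- c("simulate", "track-stats", "vessel-dist", "classify",
                    "distribution", "report")

needFile <- function(path, stage, producer) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' needs missing upstream output '%s'; run stage '%s' first",
                 stage, basename(path), producer), call. = FALSE)
  path
}

reportToList <- function(rep) {
  list(test = rep@testName, statistic = rep@statistic, df = rep@df,
       p_two_sided = rep@pTwoSided, unit = rep@unit,
       comparisons = rep@comparisons, group_summaries = rep@groupSummaries,
       details = rep@details[!vapply(rep@details, is.null, TRUE)])
}

#' Run the simulate-analyze-report pipeline
#'
#' Orchestrates the full synthetic workflow in dependency order: `simulate`
#' (vessel network, tracks of all three modes, nuclei cloud, rasterized
#' two-channel volume), `track-stats` (per-frame speeds, gates, turns and
#' radial angles), `vessel-dist` (vessel mask, centroid-to-surface distances
#' with edge exclusion, association fraction), `classify` (per-frame on/off
#' labels, persistence, off/on ratio), `distribution` (relative cortical
#' depths and bin counts of final positions) and `report` (mode
#' comparisons). Subsets are allowed when upstream outputs already exist in
#' `outDir`; a missing dependency fails fast naming the file. A run manifest
#' (config snapshot, seeds, per-stage timing, output hashes and row counts)
#' is written to `manifest.json`; deterministic stages reproduce their
#' hashes when re-run with the same seed.
#'
#' @param outDir output directory.
#' @param configPath optional pipeline config JSON (see
#'   [readPipelineConfig()]); ignored when `simulation` / `analysis` are
#'   given directly.
#' @param simulation a [SimulationConfig-class] (default from config file or
#'   package defaults).
#' @param analysis an [AnalysisConfig-class].
#' @param stages subset of
#'   `c("simulate","track-stats","vessel-dist","classify","distribution","report")`
#'   or `"all"`.
#' @param seed optional integer overriding the simulation seed.
#' @param maskThreshold intensity threshold for the vessel mask (default 50,
#'   half the rendered amplitude).
#' @param skeletonize carry the thinning skeleton through `vessel-dist`
#'   (default FALSE: QC-only and slow on full fields).
#' @param verbose print per-stage progress.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(outDir, configPath = NULL, simulation = NULL,
                        analysis = NULL, stages = "all", seed = NULL,
                        maskThreshold = 50, skeletonize = FALSE,
                        verbose = TRUE) {
  if (!is.null(configPath)) {
    cfg <- readPipelineConfig(configPath)
    if (is.null(simulation)) simulation <- cfg$simulation
    if (is.null(analysis)) analysis <- cfg$analysis
  }
  if (is.null(simulation)) simulation <- simulationConfig()
  if (is.null(analysis)) analysis <- analysisConfig()
  if (!is.null(seed)) simulation@seed <- as.integer(seed)
  if (identical(stages, "all")) stages <- pipelineStages
  bad <- setdiff(stages, pipelineStages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- pipelineStages[pipelineStages %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  pth <- function(f) file.path(outDir, f)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("AstroMigrate")),
                   seed = simulation@seed, stages = list(), outputs = list())
  fieldF <- simulation@fieldSizeUm
  defaultFrame <- corticalFrame(radialAxis = c(0, 1),
                                upperBorderUm = -fieldF[2], lowerBorderUm = 0,
                                hemisphere = "right")
  writePipelineConfig(simulation, analysis, pth("config_resolved.json"))
  addOutput <- function(f, rows = NA_integer_) {
    manifest$outputs[[basename(f)]] <<- list(
      path = basename(f), md5 = unname(tools::md5sum(f)), rows = rows)
  }
  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    say("stage %s ...", name)
    fun()
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }

  for (st in stages) {
    if (st == "simulate") runStage(st, function() {
      net <- generateVesselNetwork(simulation)
      trks <- generateTracks(simulation, net)
      nuc <- generateNuclei(simulation)
      writeVesselsCsv(net, pth("vessels.csv"))
      writeTracksCsv(trks, pth("tracks.csv"))
      utils::write.csv(as.data.frame(nuc), pth("nuclei.csv"),
                       row.names = FALSE)
      stack <- rasterizeFrame(net, trks, 1L, simulation)
      writeVolumeStack(stack, outDir, "frame1")
      addOutput(pth("vessels.csv"), nSegments(net))
      addOutput(pth("tracks.csv"),
                sum(vapply(trks, function(x) nrow(samples(x)), 1L)))
      addOutput(pth("nuclei.csv"), nrow(nuc))
      addOutput(pth("frame1_vessel.tif"))
      addOutput(pth("frame1_cell.tif"))
    })
    if (st == "track-stats") runStage(st, function() {
      trks <- readTracksCsv(needFile(pth("tracks.csv"), st, "simulate"))
      rows <- lapply(trks, function(tr) {
        stp <- frameSteps(tr, analysis)
        turn <- rep(NA_real_, nrow(stp))
        gi <- which(stp$gated & !is.na(stp$direction_deg))
        if (length(gi) >= 2L) {
          tc <- directionalChanges(tr, analysis)
          turn[gi[-1]] <- tc
        }
        ang <- rep(NA_real_, nrow(stp))
        if (length(gi))
          ang[gi] <- anglesToRadial(tr, defaultFrame, analysis)
        data.frame(track_id = stp$track_id, t_mid = stp$t_mid,
                   speed_umh = stp$speed_umh, gated = stp$gated,
                   direction_deg = stp$direction_deg, turn_deg = turn,
                   angle_to_radial_deg = ang)
      })
      steps <- do.call(rbind, rows)
      utils::write.csv(steps, pth("frame_steps.csv"), row.names = FALSE)
      mot <- motileFilter(trks, analysis)
      summaries <- lapply(trks, function(tr) {
        ps <- polarSummary(tr, defaultFrame)
        list(track_id = trackId(tr), true_mode = trueMode(tr),
             motile = unname(mot$isMotile[trackId(tr)]),
             net_distance_um = ps$netDistanceUm,
             net_direction_deg = ps$netDirectionDeg)
      })
      jsonlite::write_json(summaries, pth("track_summaries.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      addOutput(pth("frame_steps.csv"), nrow(steps))
      addOutput(pth("track_summaries.json"), length(summaries))
    })
    if (st == "vessel-dist") runStage(st, function() {
      stack <- readVolumeStack(dirname(needFile(pth("frame1_meta.json"), st,
                                                "simulate")), "frame1")
      mask <- buildVesselMask(stack, "vessel", maskThreshold, analysis,
                              skeletonize = skeletonize)
      nuc <- as.matrix(utils::read.csv(needFile(pth("nuclei.csv"), st,
                                                "simulate")))
      # the DAPI reference uses only the central Z window
      zin <- nuc[, 3] >= analysis@zExclusionUm &
        nuc[, 3] <= fieldF[3] - analysis@zExclusionUm
      rec <- nearestVesselDistance(nuc[zin, , drop = FALSE], mask)
      rec <- applyEdgeExclusion(rec, fieldF, analysis)
      utils::write.csv(rec[, c("cell_id", "x", "y", "z", "distance_um",
                               "included", "exclusion_reason")],
                       pth("distances.csv"), row.names = FALSE)
      assoc <- associationFraction(rec, analysis)
      jsonlite::write_json(list(association_fraction = assoc$fraction,
                                n_included = assoc$nIncluded,
                                histogram = assoc$histogram),
                           pth("association.json"), auto_unbox = TRUE,
                           digits = NA)
      addOutput(pth("distances.csv"), nrow(rec))
      addOutput(pth("association.json"))
    })
    if (st == "classify") runStage(st, function() {
      stack <- readVolumeStack(dirname(needFile(pth("frame1_meta.json"), st,
                                                "simulate")), "frame1")
      mask <- buildVesselMask(stack, "vessel", maskThreshold, analysis,
                              skeletonize = FALSE)
      trks <- readTracksCsv(needFile(pth("tracks.csv"), st, "simulate"))
      contacts <- lapply(trks, classifyTrackContacts, masks = mask,
                         config = analysis)
      lab <- do.call(rbind, Map(function(tr, ct)
        cbind(track_id = trackId(tr), ct$labels), trks, contacts))
      utils::write.csv(lab, pth("contact_labels.csv"), row.names = FALSE)
      pers <- Map(function(tr, ct)
        list(track_id = trackId(tr),
             max_distance_um = onVesselPersistence(tr, ct, analysis)),
        trks, contacts)
      ratio <- offOnRatio(trks, contacts, rep("field1", length(trks)),
                          analysis)
      jsonlite::write_json(list(persistence = unname(pers),
                                off_on_ratio = ratio),
                           pth("classification.json"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      addOutput(pth("contact_labels.csv"), nrow(lab))
      addOutput(pth("classification.json"))
    })
    if (st == "distribution") runStage(st, function() {
      trks <- readTracksCsv(needFile(pth("tracks.csv"), st, "simulate"))
      finals <- do.call(rbind, lapply(trks, function(tr) {
        s <- samples(tr)
        data.frame(cell_id = trackId(tr), x = s$x_um[nrow(s)],
                   y = s$y_um[nrow(s)])
      }))
      dep <- relativeDepth(finals, defaultFrame)
      counts <- binDistribution(dep$depth_rel[dep$in_range], analysis)
      utils::write.csv(dep, pth("depths.csv"), row.names = FALSE)
      jsonlite::write_json(list(bin_counts = as.list(counts),
                                n_in_range = sum(dep$in_range),
                                n_out_of_range = sum(!dep$in_range)),
                           pth("distribution.json"), auto_unbox = TRUE,
                           digits = NA)
      addOutput(pth("depths.csv"), nrow(dep))
      addOutput(pth("distribution.json"))
    })
    if (st == "report") runStage(st, function() {
      trks <- readTracksCsv(needFile(pth("tracks.csv"), st, "simulate"))
      modes <- vapply(trks, trueMode, "")
      rep <- list()
      if (all(c("erratic", "radial") %in% modes)) {
        stepsFor <- function(m) do.call(rbind, lapply(trks[modes == m],
                                                      frameSteps,
                                                      config = analysis))
        spd <- compareSpeedDistributions(stepsFor("erratic"),
                                         stepsFor("radial"),
                                         labels = c("erratic", "radial"))
        angFor <- function(m) abs(unlist(lapply(trks[modes == m],
                                                anglesToRadial,
                                                frame = defaultFrame,
                                                config = analysis)))
        ang <- runTest(list(erratic = angFor("erratic"),
                            radial = angFor("radial")),
                       method = "mann_whitney", unit = "frame")
        rep$speed_welch <- reportToList(spd)
        rep$abs_angle_mann_whitney <- reportToList(ang)
      }
      jsonlite::write_json(rep, pth("report.json"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      addOutput(pth("report.json"))
    })
  }
  addOutput(pth("config_resolved.json"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  say("pipeline done: %s", pth("manifest.json"))
  invisible(manifest)
}
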