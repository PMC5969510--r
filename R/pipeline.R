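#' Result of a full dynamic force spectroscopy run
#'
#' Bundles the per-curve results table, the per-speed ensembles, the
#' Bell-Evans fit and the manifest of a [runDFSPipeline()] run.
#'
#' @slot perCurve per-curve results data.frame (see [analyzeCurves()]).
#' @slot ensembles list of [SpeedEnsemble-class].
#' @slot fit the [BellEvansFit-class] (may be absent when fewer than two
#'   speeds had enough events; then a 0-length list slot).
#' @slot manifest named list: full config snapshot, master seed, file
#'   inventory.
#' @export
setClass("DFSRun",
  representation(perCurve = "data.frame", ensembles = "list",
                 fit = "ANY", manifest = "list"))

setMethod("show", "DFSRun", function(object) {
  cat(reportDFS(object), sep = "\n")
})

# Version stamp recorded in manifests.
artifactVersion <- function() as.character(utils::packageVersion("ccDFS"))

#' Run the complete simulate-analyze-fit pipeline
#'
#' For each retract speed of the panel: simulate an ensemble of retract
#' curves ([simulateEnsemble()]), run the per-curve analysis
#' ([analyzeCurves()]), then group accepted events into per-speed
#' ensembles with Gaussian most-probable values
#' ([buildSpeedEnsembles()]) and regress the Bell-Evans model
#' ([fitBellEvans()]). Fully deterministic under the master seed.
#'
#' @param bell a [BellParameters-class], or a construct name understood
#'   by [ccConstruct()].
#' @param speeds retract-speed panel (nm/s); default
#'   [defaultSpeedPanel()].
#' @param nCurvesPerSpeed curves simulated per speed.
#' @param blankFraction fraction of blank curves.
#' @param seed master seed (integer).
#' @param geom a [PullingGeometry-class] template (its `retractSpeed` is
#'   overridden per panel speed).
#' @param model a [WLCModel-class] for the spacers.
#' @param minL,minR2 acceptance thresholds ([filterEvents()]).
#' @param minEvents minimum accepted events per speed for Gaussian fits.
#' @param nBins histogram bins.
#' @param slopeWindow pre-rupture slope window (nm).
#' @param replicateId replicate label.
#' @param outDir optional directory; when given, the per-curve CSV, DFS
#'   result JSON/CSV and manifest are written there (and the raw curves
#'   too when `writeCurves = TRUE`).
#' @param writeCurves write every simulated curve as TSV? (slow for large
#'   panels; default `FALSE`).
#' @return A [DFSRun-class].
#' @examples
#' \donttest{
#' run <- runDFSPipeline("A4B4", speeds = c(200, 800, 3200),
#'                       nCurvesPerSpeed = 60, seed = 7)
#' run@fit
#' }
#' @export
runDFSPipeline <- function(bell, speeds = defaultSpeedPanel(),
                           nCurvesPerSpeed = 350, blankFraction = 0.3,
                           seed = 1, geom = PullingGeometry(),
                           model = WLCModel(), minL = 100, minR2 = 0.95,
                           minEvents = 30L, nBins = 18L, slopeWindow = 5,
                           replicateId = "rep1", outDir = NULL,
                           writeCurves = FALSE) {
  construct <- NA_character_
  if (is.character(bell)) {
    construct <- bell
    bell <- ccConstruct(bell)
  }
  stopifnot(is(bell, "BellParameters"))
  perCurve <- NULL
  curveFiles <- character()
  for (k in seq_along(speeds)) {
    geomK <- initialize(geom, retractSpeed = speeds[k])
    sims <- simulateEnsemble(geomK, model, bell, nCurves = nCurvesPerSpeed,
                             blankFraction = blankFraction,
                             seed = childSeed(seed, 1000L + k),
                             replicateId = replicateId)
    if (!is.null(outDir) && writeCurves)
      curveFiles <- c(curveFiles,
                      basename(writeForceCurves(sims,
                        file.path(outDir, "curves"))))
    res <- analyzeCurves(sims, minL = minL, minR2 = minR2,
                         slopeWindow = slopeWindow, kBT = bell@kBT)
    perCurve <- rbind(perCurve, res)
  }
  ensembles <- buildSpeedEnsembles(perCurve, minEvents = minEvents,
                                   nBins = nBins)
  nFit <- sum(!vapply(ensembles, function(e) e@flagged, logical(1)))
  fit <- if (nFit >= 2L) fitBellEvans(ensembles, kBT = bell@kBT) else NULL
  manifest <- list(
    artifact_version = artifactVersion(),
    master_seed = as.integer(seed),
    construct = construct,
    parameters = list(
      bell = list(koff = bell@koff, deltaX = bell@deltaX, kBT = bell@kBT),
      wlc = list(p = model@p, L = model@L, kBT = model@kBT),
      geometry = list(spacerContourTotal = geom@spacerContourTotal,
                      spacerPersistence = geom@spacerPersistence,
                      cantileverStiffness = geom@cantileverStiffness,
                      noiseSigma = geom@noiseSigma,
                      samplingRate = geom@samplingRate),
      speeds = speeds, nCurvesPerSpeed = nCurvesPerSpeed,
      blankFraction = blankFraction, minL = minL, minR2 = minR2,
      minEvents = as.integer(minEvents), nBins = as.integer(nBins),
      slopeWindow = slopeWindow, replicateId = replicateId),
    files = list(curves = curveFiles, per_curve = character(),
                 dfs_result = character()))
  run <- new("DFSRun", perCurve = perCurve, ensembles = ensembles,
             fit = fit, manifest = manifest)
  if (!is.null(outDir)) run <- writeDFSRun(run, outDir)
  run
}

#' Serialize a pipeline run to disk
#'
#' Writes `per_curve.csv`, `dfs_result.json`, `dfs_result.csv` and
#' `manifest.json` into `dir` and records them in the manifest's file
#' inventory.
#'
#' @param run a [DFSRun-class].
#' @param dir output directory (created if missing).
#' @return The run, with an updated manifest, invisibly.
#' @export
writeDFSRun <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run@perCurve, file.path(dir, "per_curve.csv"),
                   row.names = FALSE)
  res <- dfsResultList(run)
  jsonlite::write_json(res, file.path(dir, "dfs_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
                       null = "null")
  utils::write.csv(res$per_speed, file.path(dir, "dfs_result.csv"),
                   row.names = FALSE)
  run@manifest$files$per_curve <- "per_curve.csv"
  run@manifest$files$dfs_result <- c("dfs_result.json", "dfs_result.csv")
  writeRunManifest(run@manifest, file.path(dir, "manifest.json"))
  invisible(run)
}

# Flat representation of the inference results (JSON payload).
dfsResultList <- function(run) {
  perSpeed <- do.call(rbind, lapply(run@ensembles, function(e) {
    data.frame(retract_speed = e@retractSpeed, n_events = e@nEvents,
               flagged = e@flagged,
               F_star = if (!is.null(e@FStar)) e@FStar@mode else NA_real_,
               F_sd = if (!is.null(e@FStar)) e@FStar@sd else NA_real_,
               r_star = if (!is.null(e@rStar)) e@rStar@mode else NA_real_,
               r_sd_log = if (!is.null(e@rStar)) e@rStar@sd else NA_real_,
               stringsAsFactors = FALSE)
  }))
  fit <- run@fit
  list(
    per_speed = perSpeed,
    bell_evans = if (!is.null(fit)) list(
      koff = fit@koff, deltaX = fit@deltaX, seKoff = fit@seKoff,
      seDeltaX = fit@seDeltaX, nPoints = fit@nPoints, kBT = fit@kBT,
      slope = fit@slope, intercept = fit@intercept) else NULL,
    tallies = as.list(table(run@perCurve$reason)),
    provenance = run@manifest)
}

#' Replay a run from its manifest
#'
#' Re-executes [runDFSPipeline()] with the exact parameter snapshot and
#' master seed stored in a manifest; the numeric outputs are reproduced
#' byte-identically.
#'
#' @param manifest a manifest list (from [readRunManifest()]) or a path
#'   to a manifest JSON file.
#' @param outDir optional output directory for the replayed artifacts.
#' @return A [DFSRun-class].
#' @export
runFromManifest <- function(manifest, outDir = NULL) {
  if (is.character(manifest)) manifest <- readRunManifest(manifest)
  p <- manifest$parameters
  cn <- manifest$construct
  bell <- if (!is.null(cn) && !is.na(cn)) cn
          else BellParameters(p$bell$koff, p$bell$deltaX, p$bell$kBT)
  runDFSPipeline(
    bell = bell,
    speeds = as.numeric(p$speeds),
    nCurvesPerSpeed = p$nCurvesPerSpeed,
    blankFraction = p$blankFraction,
    seed = manifest$master_seed,
    geom = PullingGeometry(
      spacerContourTotal = p$geometry$spacerContourTotal,
      spacerPersistence = p$geometry$spacerPersistence,
      cantileverStiffness = p$geometry$cantileverStiffness,
      noiseSigma = p$geometry$noiseSigma,
      samplingRate = if (is.null(p$geometry$samplingRate))
        NA_real_ else as.numeric(p$geometry$samplingRate)),
    model = WLCModel(p$wlc$p, p$wlc$L, p$wlc$kBT),
    minL = p$minL, minR2 = p$minR2, minEvents = p$minEvents,
    nBins = p$nBins, slopeWindow = p$slopeWindow,
    replicateId = p$replicateId, outDir = outDir)
}

#' Human-readable summary of a pipeline run
#'
#' @param run a [DFSRun-class] or the list read from a `dfs_result.json`.
#' @return Character vector of report lines.
#' @export
reportDFS <- function(run) {
  res <- if (is(run, "DFSRun")) dfsResultList(run) else run
  ps <- res$per_speed
  lines <- c("Dynamic force spectroscopy run", strrep("-", 46),
             sprintf("%10s %8s %10s %12s", "v [nm/s]", "events",
                     "F* [pN]", "r* [pN/s]"))
  for (i in seq_len(nrow(ps))) {
    lines <- c(lines, sprintf("%10g %8d %10s %12s",
      ps$retract_speed[i], as.integer(ps$n_events[i]),
      if (is.na(ps$F_star[i])) "(flagged)" else sprintf("%.1f", ps$F_star[i]),
      if (is.na(ps$r_star[i])) "" else sprintf("%.3g", ps$r_star[i])))
  }
  be <- res$bell_evans
  if (!is.null(be)) {
    lines <- c(lines, strrep("-", 46),
      sprintf("Bell-Evans fit over %d speeds:", be$nPoints),
      sprintf("  koff   = %.3g 1/s (x/ %.3g)", be$koff,
              if (is.null(be$seKoff) || is.na(be$seKoff)) NA else be$seKoff),
      sprintf("  deltaX = %.3g nm (+/- %.2g)", be$deltaX,
              if (is.null(be$seDeltaX) || is.na(be$seDeltaX)) NA
              else be$seDeltaX))
  } else {
    lines <- c(lines, "Bell-Evans fit: not available (too few speeds)")
  }
  tl <- res$tallies
  if (length(tl)) {
    lines <- c(lines, strrep("-", 46), "Filter tallies:")
    for (nm in names(tl))
      lines <- c(lines, sprintf("  %-40s %d", nm, as.integer(tl[[nm]])))
  }
  lines
}
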