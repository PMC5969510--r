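# Mandatory metadata keys of the curve file dialect.
.curveMetaKeys <- c("curve_id", "replicate_id", "retract_speed_nm_s",
                    "sampling_rate_hz", "seed")

#' Write a force curve in the plain-text TSV dialect
#'
#' The dialect is instrument-agnostic and diff-able: '#'-prefixed
#' `key=value` header lines (`curve_id`, `replicate_id`,
#' `retract_speed_nm_s`, `sampling_rate_hz`, `seed`), a column header
#' line, then two tab-separated numeric columns `extension_nm` and
#' `force_pN`. Numbers are written with 17 significant digits so a
#' write-read round trip is value-exact.
#'
#' @param curve a [ForceCurve-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readForceCurves()]
#' @export
writeForceCurve <- function(curve, path) {
  stopifnot(is(curve, "ForceCurve"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# curve_id=%s", curve@curveId),
    sprintf("# replicate_id=%s", curve@replicateId),
    sprintf("# retract_speed_nm_s=%.17g", curve@retractSpeed),
    sprintf("# sampling_rate_hz=%.17g", curve@samplingRate),
    sprintf("# seed=%s", if (is.na(curve@seed)) "NA" else
      format(curve@seed)),
    "extension_nm\tforce_pN"), con)
  writeLines(sprintf("%.17g\t%.17g", curve@extension, curve@force), con)
  invisible(path)
}

#' Write an ensemble of curves to a directory
#'
#' @param curves list of [ForceCurve-class] or of `list(curve =, ...)`
#'   elements.
#' @param dir output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
writeForceCurves <- function(curves, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(curves, function(el) {
    curve <- if (is(el, "ForceCurve")) el else el$curve
    writeForceCurve(curve, file.path(dir, paste0(curve@curveId, ".tsv")))
  }, character(1))
  invisible(paths)
}

# Parse one curve file; stops with an informative message on malformed
# input (line numbers included).
parseCurveFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  isMeta <- startsWith(lines, "#")
  metaLines <- sub("^#\\s*", "", lines[isMeta])
  kv <- regmatches(metaLines, regexpr("=", metaLines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) == 2L) x[2] else NA_character_,
                 character(1))
  meta <- stats::setNames(as.list(trimws(vals)), trimws(keys))
  missingKeys <- setdiff(.curveMetaKeys, names(meta))
  if (length(missingKeys))
    stop(sprintf("missing mandatory metadata: %s",
                 paste(missingKeys, collapse = ", ")))
  body <- which(!isMeta)
  # drop the column header line if present
  if (length(body) && grepl("extension_nm", lines[body[1]], fixed = TRUE))
    body <- body[-1]
  if (length(body) < 2L) stop("fewer than 2 data rows")
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("line %d: expected 2 tab-separated columns", body[bad[1]]))
  ext <- as.numeric(vapply(parts, `[`, character(1), 1))
  frc <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(ext) || anyNA(frc)) {
    bad <- body[which(is.na(ext) | is.na(frc))[1]]
    stop(sprintf("line %d: non-numeric value", bad))
  }
  nonMono <- which(diff(ext) <= 0)
  if (length(nonMono))
    stop(sprintf("line %d: extension not strictly increasing",
                 body[nonMono[1] + 1L]))
  ForceCurve(extension = ext, force = frc,
             retractSpeed = as.numeric(meta$retract_speed_nm_s),
             curveId = meta$curve_id, replicateId = meta$replicate_id,
             seed = suppressWarnings(as.integer(meta$seed)),
             samplingRate = as.numeric(meta$sampling_rate_hz))
}

#' Read force curves from a file or directory
#'
#' Reads every `*.tsv` file of the dialect written by
#' [writeForceCurve()]. Malformed files (missing mandatory metadata,
#' non-numeric rows, non-monotone extension) are skipped with a warning
#' naming the file, the reason and the offending line; the failures are
#' attached as the `"failures"` attribute (a data.frame with columns
#' `file` and `reason`) so callers can tally them.
#'
#' @param path a curve file or a directory of curve files.
#' @return A list of [ForceCurve-class]; empty (with a warning) for an
#'   empty directory.
#' @export
readForceCurves <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.tsv$", full.names = TRUE)
  else path
  if (!length(files)) {
    warning(sprintf("no curve files found in '%s'", path))
    out <- list()
    attr(out, "failures") <- data.frame(file = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE)
    return(out)
  }
  failures <- list()
  curves <- list()
  for (fp in sort(files)) {
    res <- tryCatch(parseCurveFile(fp), error = function(e)
      structure(conditionMessage(e), class = "curveParseError"))
    if (is(res, "curveParseError")) {
      warning(sprintf("skipping '%s': %s", basename(fp), res))
      failures[[length(failures) + 1L]] <-
        data.frame(file = basename(fp), reason = as.character(res),
                   stringsAsFactors = FALSE)
    } else {
      curves[[length(curves) + 1L]] <- res
    }
  }
  attr(curves, "failures") <- if (length(failures))
    do.call(rbind, failures)
  else data.frame(file = character(), reason = character(),
                  stringsAsFactors = FALSE)
  curves
}

#' Write a run manifest
#'
#' The manifest snapshots every parameter of a run (geometry, WLC model,
#' Bell parameters, thresholds, binning, speed panel), the master seed,
#' the artifact version and the per-stage file inventory, so that a run
#' can be replayed to byte-identical numeric outputs (see
#' [runFromManifest()]).
#'
#' @param manifest a named list as produced by [runDFSPipeline()] (field
#'   `manifest`) or assembled by hand.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a run manifest
#' @param path manifest JSON path.
#' @return The manifest as a named list.
#' @export
readRunManifest <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
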