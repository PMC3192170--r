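#' Construct a targeted MS/MS run
#'
#' A `TargetedRun` is one LC-MS/MS injection acquired with an inclusion list:
#' a time-ordered set of product-ion (MS2) scans, each a centroided peak list
#' tagged with the precursor target m/z it was acquired for. Retention times
#' are minutes. Peaks are stored in long form (one row per centroid) and are
#' sorted by m/z within each scan on construction.
#'
#' @param scans data.frame with columns `scan` (unique integer index), `rt`
#'   (minutes, strictly increasing), `precursorMz` (Da/charge).
#' @param peaks data.frame with columns `scan`, `mz`, `intensity`; may be
#'   empty. Every `scan` value must appear in `scans`.
#' @param metadata named list (e.g. `amount` of protein injected, `replicate`
#'   id, `instrument`).
#' @return a `TargetedRun`.
#' @export
targetedRun <- function(scans, peaks = data.frame(scan = integer(),
                                                  mz = numeric(),
                                                  intensity = numeric()),
                        metadata = list()) {
  scans <- scans[order(scans$rt), , drop = FALSE]
  rownames(scans) <- NULL
  if (nrow(peaks) > 0L) {
    peaks <- peaks[order(match(peaks$scan, scans$scan), peaks$mz), ,
                   drop = FALSE]
    rownames(peaks) <- NULL
  }
  new("TargetedRun", scans = scans, peaks = peaks, metadata = metadata)
}

#' Read and write targeted runs (tabular TSV or mzML)
#'
#' The tabular format is a TSV with columns `scan_index`, `rt_min`,
#' `precursor_mz`, `peak_mz`, `intensity` — one row per centroid peak (a scan
#' without peaks contributes one row with empty peak fields). Numeric fields
#' are written with 17 significant digits so that a write/read round trip is
#' bit-exact. mzML is read and written through the \pkg{mzR} package; scans
#' are stored as centroided MS2 spectra with the precursor target recorded as
#' the selected-ion m/z, and retention times are converted between seconds
#' (mzML) and minutes (internal) on the fly. Run metadata is not carried by
#' mzML; supply it via `metadata=`.
#'
#' @param path file path; format inferred from the extension when `format`
#'   is `"auto"` (`.mzML` vs anything else tabular).
#' @param format `"auto"`, `"tabular"` or `"mzML"`.
#' @param metadata named list attached to the returned run.
#' @return `readRun()` returns a [TargetedRun]; `writeRun()` returns `path`
#'   invisibly.
#' @export
readRun <- function(path, format = c("auto", "tabular", "mzML"),
                    metadata = list()) {
  format <- .resolveRunFormat(match.arg(format), path)
  if (format == "tabular") .readRunTabular(path, metadata)
  else .readRunMzml(path, metadata)
}

#' @rdname readRun
#' @param run a [TargetedRun].
#' @export
writeRun <- function(run, path, format = c("auto", "tabular", "mzML")) {
  format <- .resolveRunFormat(match.arg(format), path)
  if (format == "tabular") .writeRunTabular(run, path)
  else .writeRunMzml(run, path)
  invisible(path)
}

.resolveRunFormat <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "tabular"
}

.writeRunTabular <- function(run, path) {
  sc <- scanTable(run)
  pk <- peakTable(run)
  idx <- match(pk$scan, sc$scan)
  lines <- character(0)
  if (nrow(pk) > 0L)
    lines <- sprintf("%d\t%.17g\t%.17g\t%.17g\t%.17g",
                     pk$scan, sc$rt[idx], sc$precursorMz[idx],
                     pk$mz, pk$intensity)
  empty <- setdiff(sc$scan, pk$scan)
  if (length(empty) > 0L) {
    j <- match(empty, sc$scan)
    lines <- c(lines, sprintf("%d\t%.17g\t%.17g\t\t",
                              empty, sc$rt[j], sc$precursorMz[j]))
  }
  # keep rows in scan order (peaks already mz-sorted within scan)
  if (length(lines) > 0L) {
    ord <- order(match(as.integer(sub("\t.*", "", lines)), sc$scan))
    lines <- lines[ord]
  }
  writeLines(c("scan_index\trt_min\tprecursor_mz\tpeak_mz\tintensity", lines),
             path)
}

.readRunTabular <- function(path, metadata = list()) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "numeric", "numeric",
                                   "numeric", "numeric"))
  need <- c("scan_index", "rt_min", "precursor_mz", "peak_mz", "intensity")
  if (!all(need %in% names(tab)))
    stop("malformed tabular run '", path, "': need columns ",
         paste(need, collapse = ", "))
  scanRows <- !duplicated(tab$scan_index)
  scans <- data.frame(scan = tab$scan_index[scanRows],
                      rt = tab$rt_min[scanRows],
                      precursorMz = tab$precursor_mz[scanRows])
  hasPeak <- !is.na(tab$peak_mz)
  peaks <- data.frame(scan = tab$scan_index[hasPeak],
                      mz = tab$peak_mz[hasPeak],
                      intensity = tab$intensity[hasPeak])
  targetedRun(scans, peaks, metadata)
}

.needMzR <- function() {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML support requires the 'mzR' package")
}

.writeRunMzml <- function(run, path) {
  .needMzR()
  sc <- scanTable(run)
  pk <- peakTable(run)
  n <- nrow(sc)
  peakList <- lapply(sc$scan, function(s) {
    rows <- pk$scan == s
    cbind(mz = pk$mz[rows], intensity = pk$intensity[rows])
  })
  counts <- vapply(peakList, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 2L,
    polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(peakList, function(m)
      if (nrow(m)) sum(m[, 2]) else 0, numeric(1)),
    retentionTime = sc$rt * 60,
    basePeakMZ = vapply(peakList, function(m)
      if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(peakList, function(m)
      if (nrow(m)) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = 35, ionisationEnergy = 0,
    lowMZ = vapply(peakList, function(m)
      if (nrow(m)) min(m[, 1]) else 0, numeric(1)),
    highMZ = vapply(peakList, function(m)
      if (nrow(m)) max(m[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = sc$precursorMz,
    precursorCharge = 1L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "",
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = sc$precursorMz,
    isolationWindowLowerOffset = 1.5, isolationWindowUpperOffset = 1.5,
    scanWindowLowerLimit = 0, scanWindowUpperLimit = 2000)
  mzR::writeMSData(peakList, path, header = hdr, outformat = "mzml")
}

.readRunMzml <- function(path, metadata = list()) {
  .needMzR()
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  hdr <- hdr[hdr$msLevel == 2L, , drop = FALSE]
  if (nrow(hdr) == 0L)
    return(targetedRun(data.frame(scan = integer(), rt = numeric(),
                                  precursorMz = numeric()),
                       metadata = metadata))
  scans <- data.frame(scan = hdr$seqNum, rt = hdr$retentionTime / 60,
                      precursorMz = hdr$precursorMZ)
  pl <- mzR::peaks(ms, hdr$seqNum)
  if (is.matrix(pl)) pl <- list(pl)
  peaks <- do.call(rbind, lapply(seq_along(pl), function(i) {
    m <- pl[[i]]
    if (is.null(m) || nrow(m) == 0L)
      return(data.frame(scan = integer(), mz = numeric(),
                        intensity = numeric()))
    data.frame(scan = hdr$seqNum[i], mz = m[, 1], intensity = m[, 2])
  }))
  targetedRun(scans, peaks, metadata)
}
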