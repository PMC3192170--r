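#' Accessors for enrichMS objects
#'
#' Slot access goes through these accessors, never through `@`.
#' `scanTable()` and `peakTable()` return the scan index and centroid peak
#' list of a [TargetedRun]; `runMetadata()` its metadata list; `xicPoints()`
#' the (rt, intensity) points of an [Xic]; `peakArea()` the integrated area of
#' an [IntegratedPeak]; `enrichmentPercent()` and `areaPairs()` the result and
#' the per-fragment labeled/unlabeled areas of a [PeptideEnrichment].
#'
#' @param object an enrichMS S4 object of the matching class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))
#' @rdname accessors
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))
#' @rdname accessors
#' @export
setGeneric("runMetadata", function(object) standardGeneric("runMetadata"))
#' @rdname accessors
#' @export
setGeneric("xicPoints", function(object) standardGeneric("xicPoints"))
#' @rdname accessors
#' @export
setGeneric("peakArea", function(object) standardGeneric("peakArea"))
#' @rdname accessors
#' @export
setGeneric("enrichmentPercent",
           function(object) standardGeneric("enrichmentPercent"))
#' @rdname accessors
#' @export
setGeneric("areaPairs", function(object) standardGeneric("areaPairs"))

#' @rdname accessors
#' @export
setMethod("scanTable", "TargetedRun", function(object) object@scans)
#' @rdname accessors
#' @export
setMethod("peakTable", "TargetedRun", function(object) object@peaks)
#' @rdname accessors
#' @export
setMethod("runMetadata", "TargetedRun", function(object) object@metadata)
#' @rdname accessors
#' @export
setMethod("xicPoints", "Xic", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("peakArea", "IntegratedPeak", function(object) object@area)
#' @rdname accessors
#' @export
setMethod("enrichmentPercent", "PeptideEnrichment",
          function(object) object@percentEnrichment)
#' @rdname accessors
#' @export
setMethod("areaPairs", "PeptideEnrichment", function(object) object@pairs)

setMethod("show", "MassTable", function(object) {
  cat("MassTable:", length(object@residueMasses), "residues;",
      sprintf("proton %.6f, water %.6f, 2H-1H %.6f Da\n",
              object@proton, object@water, object@deuteriumShift))
})

setMethod("show", "LabelSpec", function(object) {
  cat(sprintf("LabelSpec %s: %d deuteriums on '%s' (+%.4f Da per label)\n",
              object@name, object@deuteriumCount, object@targetResidue,
              labelMassShift(object, 1L)))
})

setMethod("show", "TargetedRun", function(object) {
  sc <- scanTable(object)
  cat(sprintf("TargetedRun: %d scans, %d peaks", nrow(sc),
              nrow(peakTable(object))))
  if (nrow(sc) > 0L)
    cat(sprintf(", rt %.2f-%.2f min, %d precursor target(s)",
                min(sc$rt), max(sc$rt), length(unique(sc$precursorMz))))
  cat("\n")
  if (length(object@metadata) > 0L)
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "Xic", function(object) {
  p <- xicPoints(object)
  cat(sprintf("Xic: m/z %.4f +/- %.2f Da, %d points, max intensity %.3g\n",
              object@targetMz, object@tolerance, nrow(p),
              if (nrow(p)) max(p$intensity) else 0))
})

setMethod("show", "IntegratedPeak", function(object) {
  if (!object@found) {
    cat("IntegratedPeak: no peak detected\n")
  } else {
    cat(sprintf("IntegratedPeak: area %.4g over [%.3f, %.3f] min, apex %.3f\n",
                object@area, object@leftBound, object@rightBound,
                object@apexTime))
  }
})

setMethod("show", "PeptideEnrichment", function(object) {
  cat(sprintf("PeptideEnrichment %s: %.4g%% from %d fragment pair(s)\n",
              object@peptide, object@percentEnrichment, nrow(object@pairs)))
})
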