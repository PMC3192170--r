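#' @title Core S4 classes
#' @name enrichMS-classes
#' @description S4 containers for the targeted-enrichment workflow: the mass
#'   basis (`MassTable`), the isotope label (`LabelSpec`), a targeted MS/MS
#'   injection (`TargetedRun`), a product-ion extracted ion chromatogram
#'   (`Xic`), an integrated chromatographic peak (`IntegratedPeak`) and the
#'   per-peptide enrichment result (`PeptideEnrichment`).
#' @keywords internal
NULL

setClass("MassTable",
  representation(residueMasses = "numeric", proton = "numeric",
                 water = "numeric", deuteriumShift = "numeric"),
  validity = function(object) {
    msg <- character()
    missing <- setdiff(STANDARD_RESIDUES, names(object@residueMasses))
    if (length(missing) > 0L)
      msg <- c(msg, paste("missing residues:", paste(missing, collapse = ",")))
    if (any(object@residueMasses <= 0))
      msg <- c(msg, "all residue masses must be > 0")
    if (length(object@proton) != 1L || object@proton <= 0)
      msg <- c(msg, "proton mass must be a positive scalar")
    if (length(object@water) != 1L || object@water <= 0)
      msg <- c(msg, "water mass must be a positive scalar")
    if (length(object@deuteriumShift) != 1L || object@deuteriumShift <= 0)
      msg <- c(msg, "deuterium shift must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

setClass("LabelSpec",
  representation(name = "character", targetResidue = "character",
                 deuteriumCount = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@deuteriumCount %in% c(9L, 10L))
      msg <- c(msg, "deuteriumCount must be 9 or 10")
    if (nchar(object@targetResidue) != 1L)
      msg <- c(msg, "targetResidue must be a single residue code")
    if (length(msg)) msg else TRUE
  })

setClass("TargetedRun",
  representation(scans = "data.frame", peaks = "data.frame",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    sc <- object@scans
    pk <- object@peaks
    need <- c("scan", "rt", "precursorMz")
    if (!all(need %in% names(sc)))
      msg <- c(msg, "scans must have columns scan, rt, precursorMz")
    needp <- c("scan", "mz", "intensity")
    if (!all(needp %in% names(pk)))
      msg <- c(msg, "peaks must have columns scan, mz, intensity")
    if (length(msg) == 0L) {
      if (nrow(sc) > 1L && any(diff(sc$rt) <= 0))
        msg <- c(msg, "scan retention times must be strictly increasing")
      if (any(sc$rt < 0))
        msg <- c(msg, "retention times must be >= 0")
      if (anyDuplicated(sc$scan))
        msg <- c(msg, "scan indices must be unique")
      if (nrow(pk) > 0L) {
        if (any(pk$intensity < 0))
          msg <- c(msg, "peak intensities must be >= 0")
        if (!all(pk$scan %in% sc$scan))
          msg <- c(msg, "every peak must belong to a listed scan")
      }
    }
    if (length(msg)) msg else TRUE
  })

setClass("Xic",
  representation(targetMz = "numeric", tolerance = "numeric",
                 points = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@tolerance <= 0) msg <- c(msg, "tolerance must be > 0")
    if (!all(c("rt", "intensity") %in% names(object@points)))
      msg <- c(msg, "points must have columns rt and intensity")
    else if (nrow(object@points) > 1L && any(diff(object@points$rt) <= 0))
      msg <- c(msg, "XIC times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

setClass("IntegratedPeak",
  representation(area = "numeric", apexTime = "numeric",
                 leftBound = "numeric", rightBound = "numeric",
                 found = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@area < 0) msg <- c(msg, "area must be >= 0")
    if (object@found &&
        !(object@leftBound <= object@apexTime &&
          object@apexTime <= object@rightBound))
      msg <- c(msg, "need leftBound <= apexTime <= rightBound")
    if (length(msg)) msg else TRUE
  })

setClass("PeptideEnrichment",
  representation(peptide = "character", pairs = "data.frame",
                 percentEnrichment = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("series", "ordinal", "unlabeledArea", "labeledArea")
    if (!all(need %in% names(object@pairs)))
      msg <- c(msg, paste("pairs must have columns",
                          paste(need, collapse = ", ")))
    else if (nrow(object@pairs) > 0L &&
             any(object@pairs$unlabeledArea < 0 | object@pairs$labeledArea < 0))
      msg <- c(msg, "areas must be >= 0")
    if (object@percentEnrichment < 0)
      msg <- c(msg, "percentEnrichment must be >= 0")
    if (length(msg)) msg else TRUE
  })
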