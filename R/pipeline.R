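#' Quantify peptide enrichment in a targeted run
#'
#' For every peptide/charge entry of a target list, pairs the unlabeled and
#' labeled species: product-ion XICs are drawn from the scans targeting the
#' matching precursor (the label shift exceeds any realistic isolation
#' window, so the two species never share scans), peaks are detected and
#' integrated by the trapezoidal rule, and percent enrichment is the ratio of
#' summed labeled to summed unlabeled fragment areas. Fragments are
#' quantified only if their intensity in the apex MS/MS scan reaches
#' `minFragmentFraction` of the parent (residual precursor) ion intensity in
#' that scan; weaker or absent fragments are logged with a reason and
#' skipped. Because deuterated and unlabeled species co-elute, the labeled
#' and unlabeled XICs of a fragment are by default integrated over the union
#' of their detected bounds (`sharedBounds = TRUE`); a labeled species with
#' no detectable peak of its own (the usual case at sub-percent enrichment
#' when scans exist, or when labeled scans are absent altogether) contributes
#' its integral over the unlabeled bounds, zero if it has no scans at all.
#'
#' @param run a [TargetedRun].
#' @param targets target list from [buildTargetList()] (or
#'   [readTargetList()]); must contain the unlabeled and one labeled species
#'   per peptide to quantify.
#' @param fragmentTolerance XIC half-window for product ions, Da (default
#'   0.5).
#' @param precursorTolerance precursor-target matching half-window, Da
#'   (default 1.5).
#' @param minFragmentFraction quantifiability floor as a fraction of the
#'   parent-ion intensity (default 0.10, boundary inclusive).
#' @param sharedBounds integrate both species over the union of detected
#'   bounds (default TRUE).
#' @param verbose emit a message for every skipped fragment or peptide.
#' @return a list with `enrichments` (named list of [PeptideEnrichment], one
#'   per quantifiable peptide/charge) and `fragments` (diagnostics data.frame
#'   with one row per candidate fragment: areas, quantifiability and skip
#'   reason).
#' @export
quantifyRun <- function(run, targets, fragmentTolerance = 0.5,
                        precursorTolerance = 1.5, minFragmentFraction = 0.10,
                        sharedBounds = TRUE, verbose = FALSE) {
  keys <- unique(targets[, c("peptide", "charge")])
  enrichments <- list()
  diag <- list()
  note <- function(...) if (verbose) message(...)
  for (i in seq_len(nrow(keys))) {
    pep <- keys$peptide[i]; z <- keys$charge[i]
    sub <- targets[targets$peptide == pep & targets$charge == z, ,
                   drop = FALSE]
    unl <- sub[sub$species == "unlabeled", , drop = FALSE]
    labAll <- sub[sub$species == "labeled", , drop = FALSE]
    if (nrow(unl) == 0L) next
    if (nrow(labAll) > 0L) {
      kmax <- max(labAll$labelCount)
      lab <- labAll[labAll$labelCount == kmax, , drop = FALSE]
    } else lab <- labAll
    precU <- unl$precursorMz[1]
    precL <- if (nrow(lab) > 0L) lab$precursorMz[1] else NA_real_

    # parent-ion chromatogram locates the elution apex and the reference
    # intensity for the relative-abundance floor
    parentXic <- extractProductXic(run, precU, precU, fragmentTolerance,
                                   precursorTolerance)
    parentPk <- if (nrow(xicPoints(parentXic)) >= 3L) detectPeak(parentXic)
                else list(found = FALSE)
    if (!parentPk$found) {
      note("peptide ", pep, " (+", z, "): no unlabeled parent signal; skipped")
      diag[[length(diag) + 1L]] <- data.frame(
        peptide = pep, charge = z, series = NA, ordinal = NA,
        unlabeledArea = NA_real_, labeledArea = NA_real_,
        quantifiable = FALSE, reason = "no unlabeled parent signal")
      next
    }
    scU <- scanTable(run)
    selU <- which(abs(scU$precursorMz - precU) <= precursorTolerance)
    apexScan <- scU$scan[selU[which.min(abs(scU$rt[selU] -
                                              parentPk$apexTime))]]
    pk <- peakTable(run)
    apexPeaks <- pk[pk$scan == apexScan, , drop = FALSE]
    scanIntensity <- function(mz) {
      sum(apexPeaks$intensity[abs(apexPeaks$mz - mz) <= fragmentTolerance])
    }
    parentIntensity <- scanIntensity(precU)
    if (parentIntensity <= 0) parentIntensity <- parentPk$apexIntensity

    rows <- list()
    for (j in seq_len(nrow(unl))) {
      ser <- unl$fragmentSeries[j]; ord <- unl$fragmentOrdinal[j]
      mzU <- unl$fragmentMz[j]
      labRow <- if (nrow(lab) > 0L)
        lab[lab$fragmentSeries == ser & lab$fragmentOrdinal == ord, ,
            drop = FALSE] else lab
      fragInt <- scanIntensity(mzU)
      kept <- length(selectQuantifiableFragments(
        c(f = fragInt), parentIntensity, minFragmentFraction)) == 1L
      if (!kept) {
        reason <- if (fragInt <= 0) "no fragment signal"
                  else sprintf("below %.0f%% of parent ion",
                               100 * minFragmentFraction)
        note("fragment ", ser, ord, " of ", pep, ": ", reason, "; skipped")
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, charge = z, series = ser, ordinal = ord,
          unlabeledArea = NA_real_, labeledArea = NA_real_,
          quantifiable = FALSE, reason = reason)
        next
      }
      xicU <- extractProductXic(run, precU, mzU, fragmentTolerance,
                                precursorTolerance)
      pkU <- if (nrow(xicPoints(xicU)) >= 3L) detectPeak(xicU)
             else list(found = FALSE)
      if (!pkU$found) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, charge = z, series = ser, ordinal = ord,
          unlabeledArea = NA_real_, labeledArea = NA_real_,
          quantifiable = FALSE, reason = "no unlabeled XIC peak")
        next
      }
      areaL <- 0
      haveLabeledScans <- !is.na(precL) && nrow(labRow) == 1L &&
        any(abs(scanTable(run)$precursorMz - precL) <= precursorTolerance)
      if (haveLabeledScans) {
        xicL <- extractProductXic(run, precL, labRow$fragmentMz[1],
                                  fragmentTolerance, precursorTolerance)
        pkL <- if (nrow(xicPoints(xicL)) >= 3L) detectPeak(xicL)
               else list(found = FALSE)
        bndU <- pkU; bndL <- if (pkL$found) pkL else pkU
        if (sharedBounds) {
          # co-eluting species: integrate both over the union of bounds
          un <- list(found = TRUE, left = min(bndU$left, bndL$left),
                     right = max(bndU$right, bndL$right),
                     apexTime = pkU$apexTime)
          bndU <- un; bndL <- un
        }
        areaU <- peakArea(integratePeak(xicU, bndU))
        areaL <- peakArea(integratePeak(xicL, bndL))
      } else {
        if (!is.na(precL))
          note("peptide ", pep, ": no scans for labeled precursor ",
               sprintf("%.3f", precL), "; labeled area set to 0")
        areaU <- peakArea(integratePeak(xicU, pkU))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, charge = z, series = ser, ordinal = ord,
        unlabeledArea = areaU, labeledArea = areaL,
        quantifiable = TRUE, reason = "")
    }
    dg <- do.call(rbind, rows)
    diag[[length(diag) + 1L]] <- dg
    ok <- dg[dg$quantifiable, , drop = FALSE]
    if (nrow(ok) > 0L && sum(ok$unlabeledArea) > 0) {
      pe <- computeEnrichment(
        data.frame(series = ok$series, ordinal = ok$ordinal,
                   unlabeledArea = ok$unlabeledArea,
                   labeledArea = ok$labeledArea), peptide = pep)
      enrichments[[paste0(pep, "/+", z)]] <- pe
    } else {
      warning("no quantifiable fragments for peptide ", pep, " (+", z, ")")
    }
  }
  list(enrichments = enrichments,
       fragments = if (length(diag)) do.call(rbind, diag) else
         data.frame())
}

#' @rdname quantifyRun
#' @param ... passed on to `quantifyRun()`.
#' @return `quantifyEnrichment()` returns the percent enrichment of the
#'   single peptide in `targets` as a number.
#' @export
quantifyEnrichment <- function(run, targets, ...) {
  res <- quantifyRun(run, targets, ...)
  if (length(res$enrichments) == 0L) return(NA_real_)
  enrichmentPercent(res$enrichments[[1L]])
}

#' Per-fragment signal-linearity table across an amount series
#'
#' Quantifies each run, then regresses every fragment's unlabeled and labeled
#' peak area on the injected amount with [linearityRegression()] — the
#' validation that decides whether a peptide's fragment signals grow
#' proportionally with the amount of protein analyzed (slope through the
#' origin, high R-squared).
#'
#' @param runs list of [TargetedRun]s (e.g. [simulateDilutionSeries()]).
#' @param targets target list as in [quantifyRun()].
#' @param amounts injected amounts; taken from each run's `metadata$amount`
#'   when `NULL`.
#' @param ... passed to [quantifyRun()].
#' @return data.frame with one row per (peptide, fragment, species):
#'   `slope`, `intercept`, `rSquared`, `interceptP`, `n`.
#' @export
linearityTable <- function(runs, targets, amounts = NULL, ...) {
  if (is.null(amounts))
    amounts <- vapply(runs, function(r) as.numeric(runMetadata(r)$amount),
                      numeric(1))
  stopifnot(length(amounts) == length(runs))
  frames <- lapply(seq_along(runs), function(i) {
    fr <- quantifyRun(runs[[i]], targets, ...)$fragments
    fr <- fr[fr$quantifiable, , drop = FALSE]
    if (nrow(fr) > 0L) fr$amount <- amounts[i]
    fr
  })
  all <- do.call(rbind, frames)
  if (is.null(all) || nrow(all) == 0L) return(data.frame())
  keys <- unique(all[, c("peptide", "series", "ordinal")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- all[all$peptide == keys$peptide[i] &
                 all$series == keys$series[i] &
                 all$ordinal == keys$ordinal[i], , drop = FALSE]
    for (species in c("unlabeled", "labeled")) {
      y <- if (species == "unlabeled") sub$unlabeledArea else sub$labeledArea
      if (length(y) < 3L || all(y == 0)) next
      fit <- linearityRegression(sub$amount, y)
      out[[length(out) + 1L]] <- data.frame(
        peptide = keys$peptide[i], series = keys$series[i],
        ordinal = keys$ordinal[i], species = species,
        slope = fit$slope, intercept = fit$intercept,
        rSquared = fit$rSquared, interceptP = fit$interceptP, n = fit$n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
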