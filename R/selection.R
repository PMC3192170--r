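#' Peptide candidacy criteria for enrichment measurement
#'
#' A peptide qualifies for targeted enrichment measurement only if it: contains
#' the label's target residue (leucine); ranks among the most intense peptides
#' in the survey scan (top 10 by default); is assigned to the target protein
#' with probability above 0.95; maps uniquely to that protein; carries no
#' missed cleavage; and contains no methionine (whose variable oxidation would
#' split the signal). `selectionCriteria()` bundles the thresholds;
#' `selectCandidatePeptides()` applies them all, preserving record order.
#'
#' @param minProbability records must have probability strictly greater than
#'   this (default 0.95).
#' @param maxIntensityRank keep records with intensity rank at or below this
#'   (default 10); ranks are taken per run from the supplied records, never
#'   recomputed from raw data.
#' @param requireLeucine,forbidMissedCleavage,forbidMethionine,requireUniqueProtein
#'   logical switches for the remaining rules.
#' @return `selectionCriteria()` returns a list of class
#'   `"selectionCriteria"`.
#' @export
selectionCriteria <- function(minProbability = 0.95, maxIntensityRank = 10L,
                              requireLeucine = TRUE,
                              forbidMissedCleavage = TRUE,
                              forbidMethionine = TRUE,
                              requireUniqueProtein = TRUE) {
  if (minProbability < 0 || minProbability > 1)
    stop("minProbability must be in [0, 1]")
  if (maxIntensityRank < 1) stop("maxIntensityRank must be >= 1")
  structure(list(minProbability = minProbability,
                 maxIntensityRank = as.integer(maxIntensityRank),
                 requireLeucine = requireLeucine,
                 forbidMissedCleavage = forbidMissedCleavage,
                 forbidMethionine = forbidMethionine,
                 requireUniqueProtein = requireUniqueProtein),
            class = "selectionCriteria")
}

#' @rdname selectionCriteria
#' @param records data.frame of identification records with columns
#'   `peptideSequence`, `proteins` (semicolon-separated identifiers),
#'   `probability` (fraction), `intensityRank`, `missedCleavages`; see
#'   [readIdentifications()].
#' @param criteria a `selectionCriteria` object.
#' @param targetProtein identifier the peptide must be uniquely assigned to.
#' @return `selectCandidatePeptides()` returns the subset of `records`
#'   passing every criterion (possibly empty), in the original order.
#' @export
selectCandidatePeptides <- function(records, criteria = selectionCriteria(),
                                    targetProtein) {
  if (nrow(records) == 0L) stop("records must be non-empty")
  keep <- rep(TRUE, nrow(records))
  if (criteria$requireLeucine)
    keep <- keep & grepl("L", records$peptideSequence, fixed = TRUE)
  keep <- keep & records$intensityRank <= criteria$maxIntensityRank
  keep <- keep & records$probability > criteria$minProbability
  if (criteria$forbidMissedCleavage)
    keep <- keep & records$missedCleavages == 0L
  if (criteria$forbidMethionine)
    keep <- keep & !grepl("M", records$peptideSequence, fixed = TRUE)
  if (criteria$requireUniqueProtein) {
    prots <- strsplit(records$proteins, ";", fixed = TRUE)
    keep <- keep & vapply(prots, function(p) {
      p <- trimws(p)
      length(p) == 1L && p == targetProtein
    }, logical(1))
  } else {
    keep <- keep & vapply(strsplit(records$proteins, ";", fixed = TRUE),
                          function(p) targetProtein %in% trimws(p), logical(1))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read identification records from CSV/TSV
#'
#' Expects columns `peptideSequence`, `proteins` (semicolon-separated),
#' `probability`, `intensityRank`, `missedCleavages`. Probabilities may be
#' given as percentages; any value above 1 is divided by 100.
#'
#' @param path CSV or TSV file (delimiter chosen by extension; `.tsv`/`.txt`
#'   read as tab-separated).
#' @return data.frame of identification records.
#' @export
readIdentifications <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  rec <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("peptideSequence", "proteins", "probability", "intensityRank",
            "missedCleavages")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L)
    stop("identification file missing column(s): ", paste(miss, collapse = ", "))
  pct <- !is.na(rec$probability) & rec$probability > 1
  rec$probability[pct] <- rec$probability[pct] / 100
  rec
}

#' Fragment quantifiability rule (relative-abundance floor)
#'
#' Fragment ions whose intensity falls below a fraction of the parent
#' (precursor) ion intensity in the MS/MS scan are too weak to quantify and
#' are excluded. The boundary is inclusive: a fragment at exactly
#' `minFraction * parentIntensity` is kept.
#'
#' @param fragmentIntensities named numeric vector of fragment intensities
#'   (names identify the fragments, e.g. `"y6"`).
#' @param parentIntensity parent-ion intensity in the same scan; must be > 0.
#' @param minFraction abundance floor as a fraction of the parent (default
#'   0.10).
#' @return the kept subset of `fragmentIntensities` (names preserved).
#' @examples
#' selectQuantifiableFragments(c(y6 = 200, b8 = 50), parentIntensity = 1000)
#' @export
selectQuantifiableFragments <- function(fragmentIntensities, parentIntensity,
                                        minFraction = 0.10) {
  if (length(parentIntensity) != 1L || is.na(parentIntensity) ||
      parentIntensity <= 0)
    stop("parentIntensity must be a positive scalar")
  fragmentIntensities[fragmentIntensities >= minFraction * parentIntensity]
}
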