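#' Build a precursor target (inclusion) list with fragment-ion ladders
#'
#' For each peptide and charge state the list carries one unlabeled entry plus
#' one labeled entry per label count 1..`min(maxLabels, leucineCount)` (a
#' peptide without the label's target residue yields no labeled entries). Each
#' entry expands to its full b/y fragment ladder at +1 fragment charge. For a
#' labeled species with k labels, a fragment's label count is
#' `min(k, target residues in the fragment span)` — the targeted-monitoring
#' convention that the mass-shifted fragment species is the one quantified.
#' Entries are ordered by precursor m/z.
#'
#' @param peptides character vector of peptide sequences, or a data.frame with
#'   a `sequence` column as returned by [digestProtein()].
#' @param label a `LabelSpec`.
#' @param charges integer vector of precursor charge states.
#' @param maxLabels maximum simultaneous labels per peptide (default 1: only
#'   the singly labeled, nominal "+9 Da" species is targeted).
#' @param massTable a `MassTable`.
#' @return data.frame with columns `peptide`, `species`
#'   (`"unlabeled"`/`"labeled"`), `labelCount`, `charge`, `precursorMz`,
#'   `fragmentSeries`, `fragmentOrdinal`, `fragmentLabelCount`, `fragmentMz`;
#'   one row per fragment ion.
#' @examples
#' tl <- buildTargetList("IPVGPETLGR", d9Leucine())
#' unique(tl[, c("species", "precursorMz")])
#' @export
buildTargetList <- function(peptides, label = d9Leucine(), charges = 1L,
                            maxLabels = 1L, massTable = defaultMassTable()) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  if (length(peptides) == 0L) stop("peptides must be non-empty")
  entries <- list()
  for (pep in unique(peptides)) {
    rv <- .residueVector(pep, massTable)
    nres <- length(rv)
    nLeu <- sum(strsplit(pep, "", fixed = TRUE)[[1]] == label@targetResidue)
    for (z in charges) {
      for (k in 0:min(maxLabels, nLeu)) {
        precMz <- (sum(rv) + massTable@water +
                     labelMassShift(label, k, massTable) +
                     z * massTable@proton) / z
        ords <- seq_len(nres - 1L)
        frag <- data.frame(
          peptide = pep,
          species = if (k == 0L) "unlabeled" else "labeled",
          labelCount = k, charge = as.integer(z), precursorMz = precMz,
          fragmentSeries = rep(c("b", "y"), each = nres - 1L),
          fragmentOrdinal = rep(ords, 2L),
          stringsAsFactors = FALSE)
        frag$fragmentLabelCount <- vapply(seq_len(nrow(frag)), function(i) {
          min(k, .labelsInSpan(pep, frag$fragmentSeries[i],
                               frag$fragmentOrdinal[i], label))
        }, integer(1))
        frag$fragmentMz <- vapply(seq_len(nrow(frag)), function(i) {
          fragmentMz(pep, frag$fragmentSeries[i], frag$fragmentOrdinal[i],
                     charge = 1L, labelCount = frag$fragmentLabelCount[i],
                     label = label, massTable = massTable)
        }, numeric(1))
        entries[[length(entries) + 1L]] <- frag
      }
    }
  }
  out <- do.call(rbind, entries)
  # order entries by precursor m/z, fragments within an entry by series/ordinal
  out <- out[order(out$precursorMz, out$fragmentSeries, out$fragmentOrdinal), ]
  rownames(out) <- NULL
  out
}

#' Write / read a target list as CSV
#'
#' Columns mirror [buildTargetList()]; m/z values are written with six
#' decimals.
#'
#' @param targets data.frame from [buildTargetList()].
#' @param path output CSV path.
#' @export
writeTargetList <- function(targets, path) {
  out <- targets
  out$precursorMz <- sprintf("%.6f", out$precursorMz)
  out$fragmentMz <- sprintf("%.6f", out$fragmentMz)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTargetList
#' @export
readTargetList <- function(path) {
  tl <- read.csv(path, stringsAsFactors = FALSE)
  tl$precursorMz <- as.numeric(tl$precursorMz)
  tl$fragmentMz <- as.numeric(tl$fragmentMz)
  tl
}
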