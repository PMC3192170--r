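#' In-silico tryptic digestion
#'
#' Cleaves a protein C-terminal of lysine (K) or arginine (R) except when the
#' next residue is proline (the Keil rule), returning every peptide carrying
#' up to `maxMissed` missed cleavage sites. Zero-missed-cleavage peptides tile
#' the protein exactly; coordinates are 1-based inclusive positions in the
#' parent protein.
#'
#' @param proteinSequence single amino-acid string (standard 20 residue codes
#'   only; B/Z/X are rejected, not guessed).
#' @param maxMissed maximum number of missed tryptic cleavages (>= 0).
#' @param massTable a `MassTable`; used only to validate residue codes.
#' @return a data.frame with one row per peptide and columns `sequence`,
#'   `start`, `end`, `missedCleavages`, `leucineCount`, ordered by start
#'   position then missed-cleavage count.
#' @examples
#' digestProtein("GIRVALTGK")
#' digestProtein("AKPLR")  # K before P is not cleaved
#' @export
digestProtein <- function(proteinSequence, maxMissed = 0L,
                          massTable = defaultMassTable()) {
  .checkSequence(proteinSequence, massTable)
  if (maxMissed < 0) stop("maxMissed must be >= 0")
  res <- strsplit(proteinSequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  # cleavage points: after position i when res[i] is K/R and res[i+1] != P
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut == n | res[pmin(cut + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut, n))  # segment boundaries (positions after which)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nseg <- length(starts)
  out <- vector("list", nseg * (as.integer(maxMissed) + 1L))
  k <- 0L
  for (i in seq_len(nseg)) {
    for (m in 0:maxMissed) {
      j <- i + m
      if (j > nseg) break
      k <- k + 1L
      s <- starts[i]; e <- ends[j]
      pep <- substr(proteinSequence, s, e)
      out[[k]] <- data.frame(
        sequence = pep, start = s, end = e, missedCleavages = m,
        leucineCount = sum(res[s:e] == "L"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector of sequences (single- and multi-record FASTA).
#'
#' @param path path to a FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
readFastaProteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}
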