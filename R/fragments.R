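#' Monoisotopic peptide and fragment-ion m/z
#'
#' `monoisotopicMH()` returns the singly protonated monoisotopic peptide mass
#' MH+ = sum of residue masses + water + proton, plus `labelCount` times the
#' per-label deuterium shift. `fragmentMz()` returns b/y product-ion m/z at a
#' given charge: b_k covers the N-terminal k residues (sum + z protons, over
#' z); y_k the C-terminal k residues (sum + water + z protons, over z). Label
#' shifts apply only when the labeled residue(s) fall in the fragment span;
#' `labelCount` may not exceed the number of label target residues in the
#' span. Values are exact; rounding happens only at presentation (the printed
#' one-decimal convention is round-half-away-from-zero, see
#' [roundHalfAway()]).
#'
#' @param sequence peptide amino-acid string.
#' @param labelCount number of incorporated labels (>= 0).
#' @param label a `LabelSpec` (default d9-leucine).
#' @param massTable a `MassTable`.
#' @return m/z in Da (per charge for `fragmentMz`).
#' @examples
#' monoisotopicMH("IPVGPETLGR")              # 1038.594 -> printed 1038.6
#' fragmentMz("IPVGPETLGR", "y", 6)          # 672.368  -> printed 672.4
#' fragmentMz("IPVGPETLGR", "y", 6, labelCount = 1)  # +9.0565 (d9)
#' @export
monoisotopicMH <- function(sequence, labelCount = 0L, label = d9Leucine(),
                           massTable = defaultMassTable()) {
  rv <- .residueVector(sequence, massTable)
  .checkLabelCount(sequence, labelCount, label)
  sum(rv) + massTable@water + massTable@proton +
    labelMassShift(label, labelCount, massTable)
}

.checkLabelCount <- function(span, labelCount, label) {
  if (labelCount < 0) stop("labelCount must be >= 0")
  avail <- sum(strsplit(span, "", fixed = TRUE)[[1]] == label@targetResidue)
  if (labelCount > avail)
    stop("labelCount (", labelCount, ") exceeds available '",
         label@targetResidue, "' residues (", avail, ") in ", span)
  invisible(avail)
}

#' @rdname monoisotopicMH
#' @param series `"b"` or `"y"`.
#' @param ordinal fragment ordinal, 1 to `nchar(sequence) - 1`.
#' @param charge positive integer charge state.
#' @export
fragmentMz <- function(sequence, series = c("b", "y"), ordinal, charge = 1L,
                       labelCount = 0L, label = d9Leucine(),
                       massTable = defaultMassTable()) {
  series <- match.arg(series)
  rv <- .residueVector(sequence, massTable)
  n <- length(rv)
  if (ordinal < 1L || ordinal > n - 1L)
    stop("ordinal must be between 1 and ", n - 1L, " for ", sequence)
  if (charge < 1L) stop("charge must be >= 1")
  span <- if (series == "b") substr(sequence, 1L, ordinal)
          else substr(sequence, n - ordinal + 1L, n)
  .checkLabelCount(span, labelCount, label)
  neutral <- if (series == "b") sum(rv[seq_len(ordinal)])
             else sum(rv[(n - ordinal + 1L):n]) + massTable@water
  (neutral + charge * massTable@proton +
     labelMassShift(label, labelCount, massTable)) / charge
}

# Label target residues within the b_k / y_k span of a peptide.
.labelsInSpan <- function(sequence, series, ordinal, label) {
  n <- nchar(sequence)
  span <- if (series == "b") substr(sequence, 1L, ordinal)
          else substr(sequence, n - ordinal + 1L, n)
  sum(strsplit(span, "", fixed = TRUE)[[1]] == label@targetResidue)
}
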