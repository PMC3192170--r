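#' Monoisotopic residue-mass table and physical constants
#'
#' A `MassTable` holds the monoisotopic residue masses of the 20 standard
#' amino acids together with the three constants every m/z computation in the
#' package rests on: the proton mass (1.007276 Da), the mass of water
#' (18.010565 Da) added to every intact peptide and y ion, and the
#' deuterium-protium mass difference (1.006277 Da) that drives the label
#' shift. The default table ships as a plain-text file under
#' `inst/extdata/monoisotopic_residue_masses.tsv` and can be overridden with
#' [readMassTable()].
#'
#' @return `defaultMassTable()` returns a `MassTable` object.
#' @examples
#' mt <- defaultMassTable()
#' residueMasses(mt)[["G"]]
#' @export
defaultMassTable <- function() {
  path <- system.file("extdata", "monoisotopic_residue_masses.tsv",
                      package = "enrichMS", mustWork = TRUE)
  readMassTable(path)
}

#' @describeIn defaultMassTable Read a residue-mass table from a two-column
#'   TSV (`residue`, `mass`); all 20 standard residues must be present with
#'   positive masses.
#' @param path path to a TSV file with columns `residue` and `mass`.
#' @param proton,water,deuteriumShift physical constants in Da; the defaults
#'   are the CODATA-derived values used throughout the package.
#' @export
readMassTable <- function(path, proton = 1.007276, water = 18.010565,
                          deuteriumShift = 1.006277) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "mass") %in% names(tab)))
    stop("mass table must have columns 'residue' and 'mass'")
  masses <- setNames(as.numeric(tab$mass), tab$residue)
  new("MassTable", residueMasses = masses, proton = proton, water = water,
      deuteriumShift = deuteriumShift)
}

#' @describeIn defaultMassTable Accessor for the named vector of residue
#'   masses.
#' @param x a `MassTable`.
#' @export
residueMasses <- function(x) x@residueMasses

STANDARD_RESIDUES <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                       "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")

# Residue masses of a sequence, erroring on nonstandard codes (B, Z, X, ...).
.residueVector <- function(sequence, massTable) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), names(residueMasses(massTable)))
  if (length(bad) > 0L)
    stop("invalid sequence: nonstandard residue code(s) ",
         paste(bad, collapse = ", "), " in '", sequence, "'")
  unname(residueMasses(massTable)[res])
}

.checkSequence <- function(sequence, massTable = defaultMassTable()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  invisible(.residueVector(sequence, massTable))
}

#' Round half away from zero
#'
#' The convention used when comparing computed m/z values with printed
#' one-decimal values (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
roundHalfAway <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
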