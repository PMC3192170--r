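#' Deuterated-leucine label specifications
#'
#' The workflow labels proteins in vivo with deuterated leucine. d10-leucine
#' (all ten non-exchangeable hydrogens replaced) is the infused/synthesized
#' form; transamination in vivo exchanges the alpha-carbon deuterium, so the
#' label incorporated into protein is d9-leucine. Each incorporated label
#' shifts the mass of any leucine-containing species by
#' `deuteriumCount * 1.006277` Da (the 2H-1H mass difference): +9.0565 Da for
#' d9, +10.0628 Da for d10, nominally "+9" / "+10" Da.
#'
#' @param name `"d9-leucine"` or `"d10-leucine"` (also accepts `"d9"`/`"d10"`).
#' @return a `LabelSpec` object.
#' @examples
#' labelMassShift(d9Leucine(), 1)   # 9.0565 Da
#' labelMassShift(d10Leucine(), 1)  # 10.0628 Da
#' @export
labelSpec <- function(name = c("d9-leucine", "d10-leucine", "d9", "d10")) {
  name <- match.arg(name)
  n <- if (name %in% c("d9-leucine", "d9")) 9L else 10L
  new("LabelSpec", name = paste0("d", n, "-leucine"), targetResidue = "L",
      deuteriumCount = n)
}

#' @rdname labelSpec
#' @export
d9Leucine <- function() labelSpec("d9-leucine")

#' @rdname labelSpec
#' @export
d10Leucine <- function() labelSpec("d10-leucine")

#' @rdname labelSpec
#' @param label a `LabelSpec`.
#' @param nLabels number of incorporated labels (>= 0).
#' @param massTable a `MassTable` supplying the 2H-1H mass difference.
#' @return `labelMassShift()` returns the total mass shift in Da.
#' @export
labelMassShift <- function(label, nLabels = 1L, massTable = defaultMassTable()) {
  stopifnot(is(label, "LabelSpec"))
  if (any(nLabels < 0)) stop("nLabels must be >= 0")
  nLabels * label@deuteriumCount * massTable@deuteriumShift
}
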