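test_that("mass table carries all standard residues and fixed constants", {
  mt <- defaultMassTable()
  expect_true(all(standardResidues %in% names(residueMasses(mt))))
  expect_true(all(residueMasses(mt) > 0))
  expect_equal(mt@proton, 1.007276)
  expect_equal(mt@water, 18.010565)
  expect_equal(mt@deuteriumShift, 1.006277)
  expect_equal(residueMasses(mt)[["L"]], residueMasses(mt)[["I"]])
})

test_that("tryptic digestion cleaves after K/R with the Keil rule", {
  d <- digestProtein("GIRVALTGK")
  expect_equal(d$sequence, c("GIR", "VALTGK"))
  expect_equal(d$start, c(1L, 4L))
  expect_equal(d$end, c(3L, 9L))
  expect_equal(d$missedCleavages, c(0L, 0L))

  # K before P is not a cleavage site
  expect_equal(digestProtein("AKPLR")$sequence, "AKPLR")

  # embedded target peptide emitted with zero missed cleavages
  prot <- paste0("MAAKIPVGPETLGRALSK")
  d2 <- digestProtein(prot)
  hit <- d2[d2$sequence == "IPVGPETLGR", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$missedCleavages, 0L)
  expect_equal(hit$leucineCount, 1L)
  expect_equal(substr(prot, hit$start, hit$end), "IPVGPETLGR")
})

test_that("digestion handles missed cleavages and rejects bad input", {
  d <- digestProtein("GIRVALTGKAAR", maxMissed = 2)
  expect_setequal(d$sequence[d$missedCleavages == 0L],
                  c("GIR", "VALTGK", "AAR"))
  expect_setequal(d$sequence[d$missedCleavages == 1L],
                  c("GIRVALTGK", "VALTGKAAR"))
  expect_equal(d$sequence[d$missedCleavages == 2L], "GIRVALTGKAAR")
  expect_error(digestProtein("PEPTIDEX1"), "invalid sequence")
  expect_error(digestProtein("PEPTIDEB"), "invalid sequence")
})

test_that("zero-missed-cleavage peptides tile the protein exactly", {
  set.seed(42)
  for (prot in randomPeptides(25, 20, 60)) {
    d <- digestProtein(prot)
    d <- d[order(d$start), ]
    expect_equal(paste(d$sequence, collapse = ""), prot)
    expect_equal(d$end - d$start + 1L, nchar(d$sequence))
  }
})

test_that("monoisotopic MH+ reproduces printed peptide masses", {
  expect_equal(roundHalfAway(monoisotopicMH("IPVGPETLGR")), 1038.6)
  expect_equal(roundHalfAway(monoisotopicMH("LVLEVAQHLGESTVR")), 1650.9)
  expect_equal(roundHalfAway(monoisotopicMH("VALTGLTVAEYFR")), 1439.8)
  # single glycine: 57.021464 + water + proton
  expect_equal(round(monoisotopicMH("G"), 3), 76.039)
  expect_error(monoisotopicMH("IPVGPETLGR", labelCount = 2),
               "exceeds available")
})

test_that("fragment m/z reproduces printed b/y values", {
  expect_equal(roundHalfAway(fragmentMz("IPVGPETLGR", "y", 6)), 672.4)
  expect_equal(roundHalfAway(fragmentMz("IPVGPETLGR", "y", 7)), 729.4)
  expect_equal(roundHalfAway(fragmentMz("IPVGPETLGR", "y", 8)), 828.5)
  expect_equal(roundHalfAway(fragmentMz("LVLEVAQHLGESTVR", "b", 8)), 890.5)
  expect_equal(roundHalfAway(fragmentMz("LVLEVAQHLGESTVR", "b", 9)), 1003.6)
  expect_equal(roundHalfAway(fragmentMz("LVLEVAQHLGESTVR", "b", 11)), 1189.7)
  expect_equal(roundHalfAway(fragmentMz("VALTGLTVAEYFR", "b", 8)), 755.5)
  expect_equal(roundHalfAway(fragmentMz("VALTGLTVAEYFR", "b", 9)), 826.5)
  expect_equal(roundHalfAway(fragmentMz("VALTGLTVAEYFR", "b", 10)), 955.5)
  expect_equal(roundHalfAway(fragmentMz("VALTGLTVAEYFR", "b", 11)), 1118.6)
  expect_error(fragmentMz("IPVGPETLGR", "y", 10), "ordinal")
  expect_error(fragmentMz("IPVGPETLGR", "y", 0), "ordinal")
})

test_that("label shift is exact per deuterium and additive on fragments", {
  expect_equal(labelMassShift(d9Leucine(), 1), 9.056493, tolerance = 1e-9)
  expect_equal(labelMassShift(d10Leucine(), 1), 10.06277, tolerance = 1e-9)
  expect_equal(labelMassShift(d9Leucine(), 0), 0)
  expect_equal(round(labelMassShift(d9Leucine(), 1)), 9)
  expect_equal(round(labelMassShift(d10Leucine(), 1)), 10)

  y6u <- fragmentMz("IPVGPETLGR", "y", 6)
  y6l <- fragmentMz("IPVGPETLGR", "y", 6, labelCount = 1)
  expect_equal(y6l - y6u, 9 * 1.006277, tolerance = 1e-12)
  # labelCount above the leucines in the span errors
  expect_error(fragmentMz("IPVGPETLGR", "y", 2, labelCount = 1),
               "exceeds available")
})

test_that("b/y complementarity holds on target and random peptides", {
  checkComplementarity <- function(pep) {
    mt <- defaultMassTable()
    mh <- monoisotopicMH(pep)
    n <- nchar(pep)
    for (k in seq_len(n - 1L)) {
      b <- fragmentMz(pep, "b", k)
      y <- fragmentMz(pep, "y", n - k)
      expect_equal(b + y, mh + mt@proton, tolerance = 1e-6 / (mh + 1))
    }
  }
  for (pep in referencePeptides) checkComplementarity(pep)
  set.seed(7)
  for (pep in randomPeptides(100)) checkComplementarity(pep)
})

test_that("target list pairs labeled and unlabeled species correctly", {
  tl <- buildTargetList("IPVGPETLGR", d9Leucine(), charges = 1L,
                        maxLabels = 1L)
  prec <- unique(tl[, c("species", "precursorMz")])
  expect_equal(nrow(prec), 2L)
  u <- prec$precursorMz[prec$species == "unlabeled"]
  l <- prec$precursorMz[prec$species == "labeled"]
  expect_equal(round(u, 2), 1038.59)
  expect_equal(round(l, 2), 1047.65)
  expect_equal(l - u, labelMassShift(d9Leucine(), 1), tolerance = 1e-12)
  # full b/y ladder per species
  expect_equal(nrow(tl), 2L * 2L * 9L)
  expect_true(!is.unsorted(tl$precursorMz))

  # leucine-free peptide: unlabeled entry only
  tl2 <- buildTargetList("GGSGGK", d9Leucine())
  expect_equal(unique(tl2$species), "unlabeled")

  # three leucines, maxLabels = 3: labeled entries at +1/+2/+3 shifts
  tl3 <- buildTargetList("LVLEVAQHLGESTVR", d9Leucine(), maxLabels = 3L)
  labs <- unique(tl3[tl3$species == "labeled", c("labelCount", "precursorMz")])
  u3 <- unique(tl3$precursorMz[tl3$species == "unlabeled"])
  expect_equal(sort(labs$labelCount), 1:3)
  expect_equal(sort(labs$precursorMz - u3),
               (1:3) * labelMassShift(d9Leucine(), 1), tolerance = 1e-12)
})

test_that("target list survives a CSV round trip at 6-decimal precision", {
  tl <- buildTargetList(referencePeptides, d9Leucine())
  f <- tempfile(fileext = ".csv")
  writeTargetList(tl, f)
  back <- readTargetList(f)
  expect_equal(back$peptide, tl$peptide)
  expect_equal(back$precursorMz, tl$precursorMz, tolerance = 1e-6)
  expect_equal(back$fragmentMz, tl$fragmentMz, tolerance = 1e-6)
})

test_that("FASTA proteins are read and digestible", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|ATP5B test", "MAAKIPVGPETLGRALSK",
               ">sp|P2|OTHER", "GGSGGKAAR"), f)
  prots <- readFastaProteins(f)
  expect_length(prots, 2L)
  expect_true("IPVGPETLGR" %in% digestProtein(prots[[1]])$sequence)
})
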