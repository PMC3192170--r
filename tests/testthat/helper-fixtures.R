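# Shared fixtures, built in code at test time.

# the three validated target-protein peptides and their printed m/z values
referencePeptides <- c("LVLEVAQHLGESTVR", "IPVGPETLGR", "VALTGLTVAEYFR")

# an Xic sampling a Gaussian profile (amplitude A, center c, width s)
gaussianXic <- function(A = 1e5, center = 10, sigma = 0.2, interval = 0.01,
                        halfSigmas = 5, mz = 672.4) {
  rt <- seq(center - halfSigmas * sigma, center + halfSigmas * sigma,
            by = interval)
  new("Xic", targetMz = mz, tolerance = 0.5,
      points = data.frame(rt = rt,
                          intensity = A * exp(-(rt - center)^2 /
                                                (2 * sigma^2))))
}

xicFromPoints <- function(rt, intensity, mz = 500, tol = 0.5) {
  new("Xic", targetMz = mz, tolerance = tol,
      points = data.frame(rt = rt, intensity = intensity))
}

# random peptide sequences over the 20 standard residues
standardResidues <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                      "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
randomPeptides <- function(n, minLen = 6, maxLen = 20) {
  vapply(seq_len(n), function(i) {
    len <- sample(minLen:maxLen, 1L)
    paste(sample(standardResidues, len, replace = TRUE), collapse = "")
  }, character(1))
}

# independent OLS oracle: closed-form normal equations, no lm()
olsOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  yhat <- a + b * x
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  se_a <- sqrt(rss / (n - 2) * (1 / n + mean(x)^2 / (sxx - sx^2 / n)))
  list(slope = b, intercept = a, rSquared = 1 - rss / tss,
       interceptP = 2 * stats::pt(-abs(a / se_a), df = n - 2))
}

# small identification-record table mirroring a search/validation export
exampleRecords <- function() {
  data.frame(
    peptideSequence = c("IPVGPETLGR", "LMDEK", "IPVGPETLGR", "GGSGGK",
                        "LVLEVAQHLGESTVR", "VALTGLTVAEYFR", "LLSTYK"),
    proteins = c("ATP5B", "ATP5B", "ATP5B", "ATP5B", "ATP5B", "ATP5B",
                 "ATP5B;ALBU"),
    probability = c(0.99, 0.99, 0.90, 0.99, 0.99, 0.97, 0.99),
    intensityRank = c(3L, 2L, 4L, 1L, 5L, 6L, 7L),
    missedCleavages = c(0L, 0L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}
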