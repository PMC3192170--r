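#' Configuration for the synthetic targeted-run simulator
#'
#' The simulator emulates an inclusion-list LC-MS/MS acquisition for one
#' peptide: targeted MS/MS scans alternate between the unlabeled and the
#' labeled precursor across a single-Gaussian elution window, and every scan
#' carries a residual precursor (parent) peak plus the configured fragment
#' peaks. A fragment peak's intensity is
#' `baseIntensity * amountScale * exp(-(t - center)^2 / (2 sigma^2))`,
#' multiplied by `trueEnrichment` for the labeled species (labeled and
#' unlabeled species co-elute exactly). Optional noise is multiplicative
#' lognormal (unit mean, coefficient of variation `noiseCv`) per peak, an
#' additive `baseline`, and Gaussian m/z jitter.
#'
#' Defaults reproduce the study conditions the validation experiments assume:
#' the IPVGPETLGR peptide with a d9-leucine label at true enrichment 0.482%,
#' its y6-y8 fragments at 25-50% of the parent intensity, a 0.15-min elution
#' sigma sampled every 0.02 min over +/- 4 sigma.
#'
#' @param peptide peptide sequence.
#' @param label a `LabelSpec`.
#' @param trueEnrichment labeled/unlabeled abundance ratio (fraction, not
#'   percent).
#' @param elutionCenter,elutionSigma Gaussian elution apex and width, minutes.
#' @param scanInterval time between successive scans of the same precursor,
#'   minutes.
#' @param fragments data.frame with columns `series`, `ordinal`,
#'   `baseIntensity` listing the fragment peaks each scan contains.
#' @param parentBaseIntensity residual precursor-peak base intensity.
#' @param amountScale multiplies every intensity; proportional to the amount
#'   of protein injected.
#' @param mzJitterSd per-peak m/z jitter SD in Da (0 = none).
#' @param noiseCv multiplicative intensity noise CV (0 = noise-free).
#' @param baseline additive intensity baseline per peak.
#' @param labelCount labels on the targeted labeled species (default 1, the
#'   nominal "+9 Da" species).
#' @param charge precursor charge state.
#' @param windowSigmas half-width of the simulated elution window in sigmas.
#' @param seed integer RNG seed; identical configs give identical runs.
#' @return a list of class `"simConfig"`.
#' @export
simConfig <- function(peptide = "IPVGPETLGR", label = d9Leucine(),
                      trueEnrichment = 0.00482,
                      elutionCenter = 15, elutionSigma = 0.15,
                      scanInterval = 0.02,
                      fragments = data.frame(
                        series = "y", ordinal = 6:8,
                        baseIntensity = c(5e5, 3.5e5, 2.5e5)),
                      parentBaseIntensity = 1e6, amountScale = 1,
                      mzJitterSd = 0, noiseCv = 0, baseline = 0,
                      labelCount = 1L, charge = 1L, windowSigmas = 4,
                      seed = 1L) {
  stopifnot(trueEnrichment >= 0, elutionSigma > 0, scanInterval > 0,
            amountScale > 0, noiseCv >= 0, baseline >= 0, mzJitterSd >= 0)
  .checkSequence(peptide)
  structure(list(peptide = peptide, label = label,
                 trueEnrichment = trueEnrichment,
                 elutionCenter = elutionCenter, elutionSigma = elutionSigma,
                 scanInterval = scanInterval, fragments = fragments,
                 parentBaseIntensity = parentBaseIntensity,
                 amountScale = amountScale, mzJitterSd = mzJitterSd,
                 noiseCv = noiseCv, baseline = baseline,
                 labelCount = as.integer(labelCount),
                 charge = as.integer(charge), windowSigmas = windowSigmas,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate one targeted MS/MS run
#'
#' @param config a [simConfig()].
#' @return a [TargetedRun] whose metadata records the ground truth
#'   (`trueEnrichment`, `amount`, `seed`).
#' @examples
#' run <- simulateRun(simConfig(trueEnrichment = 0.005, seed = 7))
#' run
#' @export
simulateRun <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  mt <- defaultMassTable()
  pep <- config$peptide
  lab <- config$label
  k <- config$labelCount
  .checkLabelCount(pep, k, lab)
  rvSum <- sum(.residueVector(pep, mt))
  z <- config$charge
  precU <- (rvSum + mt@water + z * mt@proton) / z
  precL <- precU + labelMassShift(lab, k, mt) / z
  fr <- config$fragments
  fragU <- vapply(seq_len(nrow(fr)), function(i)
    fragmentMz(pep, fr$series[i], fr$ordinal[i], 1L, 0L, lab, mt), numeric(1))
  fragLabels <- vapply(seq_len(nrow(fr)), function(i)
    min(k, .labelsInSpan(pep, fr$series[i], fr$ordinal[i], lab)), integer(1))
  fragL <- fragU + labelMassShift(lab, fragLabels, mt)

  half <- config$windowSigmas * config$elutionSigma
  tU <- seq(config$elutionCenter - half, config$elutionCenter + half,
            by = config$scanInterval)
  tL <- tU + config$scanInterval / 2  # interleaved inclusion-list cadence
  times <- c(tU, tL)
  species <- rep(c("unlabeled", "labeled"), c(length(tU), length(tL)))
  ord <- order(times)
  times <- times[ord]; species <- species[ord]

  gauss <- exp(-(times - config$elutionCenter)^2 /
                 (2 * config$elutionSigma^2))
  enr <- ifelse(species == "labeled", config$trueEnrichment, 1)
  nScan <- length(times)
  nFrag <- nrow(fr)
  # per scan: parent peak + fragment peaks
  scanIdx <- rep(seq_len(nScan), each = nFrag + 1L)
  baseInt <- rep(c(config$parentBaseIntensity, fr$baseIntensity), nScan)
  mz0 <- unlist(lapply(seq_len(nScan), function(i) {
    if (species[i] == "unlabeled") c(precU, fragU) else c(precL, fragL)
  }))
  inten <- baseInt * config$amountScale * gauss[scanIdx] * enr[scanIdx]
  if (config$noiseCv > 0) {
    s <- sqrt(log(1 + config$noiseCv^2))
    inten <- inten * rlnorm(length(inten), meanlog = -s^2 / 2, sdlog = s)
  }
  if (config$baseline > 0) inten <- inten + config$baseline
  if (config$mzJitterSd > 0)
    mz0 <- mz0 + rnorm(length(mz0), sd = config$mzJitterSd)

  scans <- data.frame(scan = seq_len(nScan), rt = times,
                      precursorMz = ifelse(species == "unlabeled",
                                           precU, precL))
  peaks <- data.frame(scan = scanIdx, mz = mz0, intensity = inten)
  targetedRun(scans, peaks,
              metadata = list(peptide = pep, label = lab@name,
                              trueEnrichment = config$trueEnrichment,
                              amount = config$amountScale,
                              seed = config$seed))
}

#' Simulate an injection-amount (dilution) series
#'
#' One run per injected amount, all other parameters shared; intensities
#' scale proportionally with amount. Per-run seeds are the base seed plus the
#' run index, so a series is reproducible from a single integer.
#'
#' @param config a [simConfig()]; its `amountScale` is overridden per run.
#' @param amounts positive amounts (mg of protein injected). The default is
#'   the seven-point series 0.2-2.3 mg used for the signal-linearity
#'   validation.
#' @return list of [TargetedRun]s (one per amount).
#' @export
simulateDilutionSeries <- function(config,
                                   amounts = c(0.2, 0.3, 0.4, 0.5, 0.8,
                                               1.1, 2.3)) {
  stopifnot(all(amounts > 0))
  lapply(seq_along(amounts), function(i) {
    cfg <- config
    cfg$amountScale <- amounts[i]
    cfg$seed <- config$seed + i - 1L
    run <- simulateRun(cfg)
    run@metadata$amount <- amounts[i]
    run
  })
}

#' Simulate a labeled/unlabeled synthetic-peptide mixture series
#'
#' One run per molar ratio, with true enrichment `labeled / unlabeled`; the
#' default label is d10-leucine, the form used to synthesize labeled peptide
#' standards. The default eight ratios are log-spaced to span measured
#' enrichments of 0.009% to 8.185%.
#'
#' @param ratios data.frame with columns `labeled` and `unlabeled` (molar
#'   amounts, >= 3 rows), e.g. [defaultMixtureRatios()].
#' @param config base [simConfig()]; its `trueEnrichment`, `label` and seed
#'   are overridden per run.
#' @return list of [TargetedRun]s (one per ratio).
#' @export
simulateMixtureSeries <- function(ratios = defaultMixtureRatios(),
                                  config = simConfig(label = d10Leucine())) {
  if (nrow(ratios) < 3L) stop("need at least 3 mixture ratios")
  if (any(ratios$unlabeled <= 0)) stop("unlabeled amounts must be > 0")
  lapply(seq_len(nrow(ratios)), function(i) {
    cfg <- config
    cfg$trueEnrichment <- ratios$labeled[i] / ratios$unlabeled[i]
    cfg$seed <- config$seed + i - 1L
    run <- simulateRun(cfg)
    run@metadata$labeledAmount <- ratios$labeled[i]
    run@metadata$unlabeledAmount <- ratios$unlabeled[i]
    run
  })
}

#' @rdname simulateMixtureSeries
#' @param from,to,n span and length of the log-spaced enrichment-fraction
#'   series.
#' @export
defaultMixtureRatios <- function(from = 9e-5, to = 0.08185, n = 8L) {
  data.frame(labeled = exp(seq(log(from), log(to), length.out = n)),
             unlabeled = 1)
}
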