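---
title: "Measuring deuterated-leucine peptide enrichment from targeted MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring deuterated-leucine peptide enrichment from targeted MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichMS)
```

## The measurement problem

Protein synthesis rates are measured by infusing a stable-isotope-labeled
amino acid and following its incorporation into protein. For a low-abundance
protein such as the mitochondrial ATP synthase beta subunit in skeletal
muscle, the labeled fraction after an hours-long infusion is well below one
percent, far beneath what survey-scan (data-dependent) acquisition detects.
The approach implemented here quantifies that enrichment at the
tryptic-peptide level with targeted MS/MS: the instrument is given an
inclusion list of precursor m/z values for both the unlabeled peptide and its
deuterium-shifted labeled counterpart, and enrichment is read from the ratio
of product-ion (fragment) chromatographic peak areas,

$$E\,(\%) \;=\; 100 \times
  \frac{\sum_f A_f^{\mathrm{labeled}}}{\sum_f A_f^{\mathrm{unlabeled}}},$$

summed over the quantifiable fragment ions $f$ of the peptide. The area-sum
ratio is used rather than the mean of per-fragment ratios; per-fragment
ratios are kept as diagnostics in the result object.

The label is deuterated leucine. d10-leucine is infused (or used to
synthesize peptide standards); transamination in vivo exchanges the
alpha-carbon deuterium, so the residue incorporated into protein carries nine
deuteriums. Each label shifts any species containing it by
$n_{\mathrm D}\times(m_{^2\mathrm H}-m_{^1\mathrm H}) =
n_{\mathrm D}\times 1.006277$ Da: 9.0565 Da (d9) or 10.0628 Da (d10),
nominally "+9"/"+10" Da. The shift is carried exactly internally; rounding
happens only at presentation, using round-half-away-from-zero at one decimal
to match how printed m/z values are reported.

## Mass chemistry

Fragment m/z values follow the standard b/y ladder on monoisotopic residue
masses: $b_k$ covers the N-terminal $k$ residues
($\sum_{1..k} m_i + z\,m_p$, over $z$), $y_k$ the C-terminal $k$ residues
($\sum m_i + m_{\mathrm{H_2O}} + z\,m_p$, over $z$), with
$m_p = 1.007276$ Da and $m_{\mathrm{H_2O}} = 18.010565$ Da. Fragment charge
is fixed at +1, the state the assay monitors. Two identities are enforced by
tests and make good spot checks: $b_k + y_{N-k} = \mathrm{MH}^+ + m_p$ for
every cleavage position, and labeled minus unlabeled m/z equals the label
count times the per-label shift exactly.

```{r chem}
monoisotopicMH("IPVGPETLGR")           # 1038.6 printed
fragmentMz("IPVGPETLGR", "y", 6)       # 672.4 printed
fragmentMz("IPVGPETLGR", "y", 6, labelCount = 1)  # +9.0565
```

Digestion uses trypsin specificity with the Keil rule (cleave after K/R, not
before P); the plain "digestion with trypsin" convention leaves the
proline exception open, and the standard rule is adopted and documented
here. Nonstandard residue codes (B, Z, X) are rejected rather than guessed.
The residue-mass table ships as a plain-text file and can be replaced via
`readMassTable()`.

The target list (`buildTargetList()`) carries, per peptide and charge, the
unlabeled precursor plus one labeled precursor per label count
$1..\min(\texttt{maxLabels}, n_{\mathrm{Leu}})$, each with its full b/y
ladder. `maxLabels` defaults to 1: the assay quantifies the singly labeled
(+9 Da) species, and whether inclusion lists should also carry
multiply-labeled precursors is left configurable because sub-percent
precursor enrichment makes doubly labeled molecules vanishingly rare
(probability $\sim E^2$). For a labeled species with $k$ labels, a
fragment's label count is $\min(k, \text{target residues in its span})$ —
the targeted-monitoring convention that the mass-shifted fragment is the
species quantified.

## Peptide candidacy and fragment quantifiability

Identification records (a search-engine/validation export: sequence, protein
assignment, probability, intensity rank, missed cleavages) are filtered by
`selectCandidatePeptides()`. A peptide qualifies only if it contains leucine,
ranks in the top 10 by MS signal, is assigned with probability above 0.95,
maps uniquely to the target protein, has no missed cleavage, and contains no
methionine (variable oxidation would split its signal). Intensity ranks are
taken per run from the supplied records — the package never recomputes them
from raw data, and per-run ranking is an assumption worth noting when
records span several runs. Assignment probabilities are consumed, never
recomputed.

At the spectrum level, a fragment is quantifiable only if its intensity in
the apex MS/MS scan reaches 10% of the parent (residual precursor) ion
intensity. The boundary is inclusive — the exclusion rule is stated as
"below 10%", so exactly 10% is kept.

## XIC extraction, peak detection and integration

`extractProductXic()` selects scans whose precursor target lies within
±1.5 Da of the requested precursor (a typical targeted isolation width; the
10 ppm figure associated with this assay applies to database-search
precursor tolerance, not scan selection) and sums centroid intensities
within ±0.5 Da of the fragment m/z per scan, boundaries inclusive. Scans
with no matching peak contribute zero, so the XIC always has one point per
contributing scan.

Labeled and unlabeled XICs are never drawn from the same scans: the +9/+10 Da
precursor separation exceeds any realistic isolation window, so each species
has its own scan population on the inclusion list.

Peak bounds are our own choice (vendor software used for the original
measurements does not document its algorithm): the apex is the global
maximum, and bounds extend outward until intensity falls below 1% of the
apex or a local minimum below 5% of the apex intervenes, clipped to the XIC
range. An all-zero XIC yields a flagged no-peak result rather than an error.
Integration is the trapezoidal rule on raw points — no smoothing — so the
area is exactly linear in intensity and testable against closed forms (a
sampled Gaussian of amplitude $A$ and width $\sigma$ integrates to
$A\sigma\sqrt{2\pi}$ within a fraction of a percent at the default
sampling). Because the deuterated and unlabeled species co-elute, the two
XICs of a fragment are integrated over the union of their detected bounds
by default (`sharedBounds = TRUE`); this mainly protects the labeled trace,
whose peak at sub-percent enrichment can sit near the detection floor. A
labeled channel with scans but no detectable peak is integrated over the
unlabeled bounds; with no scans at all it contributes zero area, with a
logged message.

## Validation statistics

Three statistics qualify a peptide for enrichment measurement:

* **Signal linearity** (`linearityTable()` / `linearityRegression()`): OLS of
  each fragment's peak area on the amount of protein injected, reporting
  $R^2$ and a two-sided t-test of the intercept against zero at
  $\alpha = 0.05$ (no multiple-testing correction, matching how the
  validation is reported). A peptide is acceptable when $R^2 \ge 0.99$ and no
  intercept differs from zero.
* **Reproducibility** (`replicateSummary()`): mean, sample SD ($n-1$) and
  CV $= 100\,s/\bar x$ across replicate injections.
* **Measured vs predicted** (`measuredVsPredicted()`): OLS of measured
  enrichment on the enrichment predicted from gravimetric mixtures of
  labeled and unlabeled synthetic peptide
  (`predictedEnrichmentFromMixture()`, the molar ratio in percent); an
  unbiased assay gives slope 1 through the origin.

An exact fit (zero residual variance) would make the intercept t statistic
undefined; it is flagged (`exactFit`), with intercept p-value 1 when the
intercept is numerically zero and 0 otherwise.

Enrichment values are carried in percent throughout, the unit in which the
assay is reported.

## The simulator: what it emulates and what it does not

`simulateRun()` emulates an inclusion-list acquisition for one peptide:
unlabeled and labeled precursor scans alternate at a fixed cadence across a
single-Gaussian elution profile, each scan carrying a residual precursor
peak and the configured fragment peaks. Labeled intensities are the
unlabeled ones times the true enrichment; the two species co-elute exactly
(deuterium retention-time effects are ignored — a real d9 species elutes
slightly earlier, a second-order effect for ratio measurements with shared
bounds). Noise is multiplicative lognormal with unit mean and configurable
CV per peak, plus an optional additive baseline and Gaussian m/z jitter;
the instrument noise of the original measurements is uncharacterized, so
these parameters are exposed rather than fixed. Chimeric spectra, dynamic
exclusion, survey scans and isotope envelopes are not simulated — the assay
quantifies monoisotopic species only.

Defaults are the validated study conditions: peptide IPVGPETLGR with a
d9-leucine label at true enrichment 0.482% (the replicate-experiment mean
for that peptide), y6–y8 fragments at 25–50% of the parent intensity, a
0.15 min elution sigma sampled every 0.02 min over ±4σ — about 120 scans
per run, enough that trapezoidal error is negligible against the 0.1%
recovery tolerance. The dilution series uses the seven amounts
0.2–2.3 mg; the mixture series uses eight log-spaced molar ratios spanning
measured enrichments 0.009%–8.185% (the original eight ratios are not
printed; the span is matched and the spacing is this package's choice).
Seeding is one integer; series derive per-run seeds as `seed + index`.

Passing these simulations shows the pipeline arithmetic is faithful —
extraction, pairing, integration and ratio recover a known truth under the
stated noise — not that real chromatography (tailing peaks, interferences,
isobaric co-selection, ion-suppression nonlinearity) behaves this way. The
in-vivo reference values (mean enrichments of 0.564%/0.482%/0.566% with CVs
of 4.15%/2.6%/8.98% across the three peptides) depend on the original
rat-muscle runs and cannot be recomputed from simulations; they are covered
only by the property-based recovery tests.

## Numerical and design notes

* Test problem sizes: the noisy-recovery check uses 50 seeded runs at 5%
  noise; the linearity experiment 100 seeded seven-run series; the
  complementarity property 100 random peptides — sizes chosen so the whole
  suite runs in about a minute while Monte-Carlo margins stay wide.
* The relative-abundance floor, both m/z window boundaries, and the
  detected-bounds clip are all inclusive; ties in the apex search resolve to
  the earliest scan (`which.max`).
* `quantifyRun()` warns (absent row, not failure) when a peptide has no
  quantifiable fragments, and logs every skipped fragment with its reason.
* Tabular run files serialize numerics with 17 significant digits, making
  the write/read round trip bit-exact; mzML I/O goes through mzR with
  retention times converted between seconds and minutes at the boundary.
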