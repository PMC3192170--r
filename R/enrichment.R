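#' Percent enrichment from fragment peak-area pairs
#'
#' Peptide enrichment is the ratio of summed labeled to summed unlabeled
#' fragment peak areas, expressed in percent:
#' `100 * sum(labeledArea) / sum(unlabeledArea)`. The area-sum ratio (not the
#' mean of per-fragment ratios) is used; per-fragment ratios are carried in
#' the pairs table as diagnostics.
#'
#' @param pairs data.frame with columns `series`, `ordinal`, `unlabeledArea`,
#'   `labeledArea` (one row per quantified fragment ion).
#' @param peptide peptide sequence attached to the result.
#' @return a [PeptideEnrichment].
#' @examples
#' pr <- data.frame(series = "y", ordinal = 6:8,
#'                  unlabeledArea = c(1000, 2000, 3000),
#'                  labeledArea = c(10, 20, 30))
#' enrichmentPercent(computeEnrichment(pr))  # 1%
#' @export
computeEnrichment <- function(pairs, peptide = NA_character_) {
  if (nrow(pairs) < 1L) stop("need at least one fragment area pair")
  totalU <- sum(pairs$unlabeledArea)
  if (totalU <= 0)
    stop("undefined enrichment: total unlabeled area is zero")
  pairs$fragmentRatio <- ifelse(pairs$unlabeledArea > 0,
                                pairs$labeledArea / pairs$unlabeledArea, NA)
  new("PeptideEnrichment", peptide = peptide, pairs = pairs,
      percentEnrichment = 100 * sum(pairs$labeledArea) / totalU)
}

#' Replicate summary: mean, SD and coefficient of variation
#'
#' @param values numeric vector of replicate percent-enrichment values
#'   (length >= 2, positive mean).
#' @return a list with `values`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator) and `cv` (percent, `100 * sd / mean`).
#' @examples
#' replicateSummary(c(2, 4, 6))$cv  # 50
#' @export
replicateSummary <- function(values) {
  if (length(values) < 2L) stop("need at least 2 replicate values")
  m <- mean(values)
  if (m <= 0) stop("replicate mean must be > 0 for a CV")
  s <- sd(values)
  list(values = values, n = length(values), mean = m, sd = s,
       cv = 100 * s / m)
}

#' Ordinary least-squares linearity check with intercept test
#'
#' Fits `y = a + b x` by OLS and reports the slope, intercept, R-squared and
#' the two-sided t-test p-value for the null hypothesis that the intercept is
#' zero. An exact fit (zero residual variance, within machine tolerance) is
#' flagged rather than producing an undefined t statistic: its intercept
#' p-value is 1 when the intercept is numerically zero and 0 otherwise.
#'
#' @param x predictor (e.g. amount of protein injected, in mg).
#' @param y response (e.g. fragment peak area).
#' @return a list with `slope`, `intercept`, `rSquared`, `interceptP`, `n`,
#'   `exactFit`.
#' @export
linearityRegression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for inference")
  if (diff(range(x)) == 0) stop("degenerate x: all values equal")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  scale2 <- max(mean(y^2), .Machine$double.eps)
  exact <- rss <= 1e-20 * n * scale2
  if (exact) {
    pInt <- if (abs(cf[[1]]) <= sqrt(.Machine$double.eps) * sqrt(scale2))
      1 else 0
  } else {
    sm <- summary(fit)
    pInt <- sm$coefficients["(Intercept)", "Pr(>|t|)"]
  }
  list(slope = unname(cf[[2]]), intercept = unname(cf[[1]]),
       rSquared = min(max(r2, 0), 1), interceptP = pInt, n = n,
       exactFit = exact)
}

#' Predicted enrichment of a labeled/unlabeled peptide mixture
#'
#' The predicted percent enrichment of a gravimetric mixture is the molar
#' ratio of labeled to unlabeled peptide, in percent.
#'
#' @param labeledAmount,unlabeledAmount molar amounts (any common unit);
#'   `unlabeledAmount` must be > 0.
#' @return percent enrichment, `100 * labeledAmount / unlabeledAmount`.
#' @export
predictedEnrichmentFromMixture <- function(labeledAmount, unlabeledAmount) {
  if (any(unlabeledAmount <= 0)) stop("unlabeledAmount must be > 0")
  if (any(labeledAmount < 0)) stop("labeledAmount must be >= 0")
  100 * labeledAmount / unlabeledAmount
}

#' Measured-versus-predicted enrichment regression
#'
#' OLS of measured percent enrichment on predicted percent enrichment across
#' a mixture series; an assay with no proportional or constant bias gives
#' slope 1, intercept 0.
#'
#' @param measured,predicted equal-length numeric vectors of percent
#'   enrichment (n >= 3).
#' @return as [linearityRegression()].
#' @export
measuredVsPredicted <- function(measured, predicted) {
  linearityRegression(predicted, measured)
}
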