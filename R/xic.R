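#' Extract a product-ion ion chromatogram
#'
#' Over the scans whose precursor target lies within `precursorTolerance` of
#' `precursorTarget`, sums the centroid intensities within
#' `fragmentMz +/- tolerance` per scan (both windows inclusive at the
#' boundary). Scans in the precursor selection with no matching peak
#' contribute an intensity of 0, so the XIC has one point per contributing
#' scan. The default 0.5 Da fragment window matches ion-trap product-ion mass
#' accuracy; the 1.5 Da precursor window reflects a typical targeted
#' isolation width.
#'
#' @param run a [TargetedRun].
#' @param precursorTarget precursor target m/z (Da/charge).
#' @param fragmentMz product-ion m/z to extract (Da/charge).
#' @param tolerance fragment m/z half-window in Da (default 0.5).
#' @param precursorTolerance precursor-target half-window in Da (default 1.5).
#' @return an [Xic].
#' @export
extractProductXic <- function(run, precursorTarget, fragmentMz,
                              tolerance = 0.5, precursorTolerance = 1.5) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  sc <- scanTable(run)
  pk <- peakTable(run)
  sel <- which(abs(sc$precursorMz - precursorTarget) <= precursorTolerance)
  inten <- numeric(length(sel))
  if (length(sel) > 0L && nrow(pk) > 0L) {
    hit <- pk[abs(pk$mz - fragmentMz) <= tolerance, , drop = FALSE]
    if (nrow(hit) > 0L) {
      sums <- tapply(hit$intensity, hit$scan, sum)
      m <- match(sc$scan[sel], as.numeric(names(sums)))
      inten <- ifelse(is.na(m), 0, sums[m])
    }
  }
  new("Xic", targetMz = fragmentMz, tolerance = tolerance,
      points = data.frame(rt = sc$rt[sel], intensity = unname(inten)))
}

#' Detect the chromatographic peak in an XIC
#'
#' The apex is the global intensity maximum. Bounds extend outward from the
#' apex until the intensity falls below `boundaryFraction` of the apex
#' (default 1%) or a local minimum below `minimumFraction` of the apex
#' (default 5%) is reached, clipped to the XIC range. An all-zero XIC yields a
#' no-peak result (`found = FALSE`), not an error.
#'
#' @param xic an [Xic] with at least 3 points.
#' @param boundaryFraction fraction of apex intensity below which the peak is
#'   considered ended.
#' @param minimumFraction local minima below this fraction of the apex also
#'   terminate the peak (valley between partially resolved peaks).
#' @return a list with elements `found`, `left`, `right`, `apexTime`,
#'   `apexIntensity` (times in minutes).
#' @export
detectPeak <- function(xic, boundaryFraction = 0.01, minimumFraction = 0.05) {
  p <- xicPoints(xic)
  if (nrow(p) < 3L) stop("XIC must have at least 3 points")
  y <- p$intensity
  if (all(y == 0))
    return(list(found = FALSE, left = NA_real_, right = NA_real_,
                apexTime = NA_real_, apexIntensity = 0))
  a <- which.max(y)
  apex <- y[a]
  lo <- boundaryFraction * apex
  valley <- minimumFraction * apex
  isStop <- function(i, dir) {
    if (y[i] < lo) return(TRUE)
    # local minimum deep enough to split partially resolved peaks
    prv <- i - dir; nxt <- i + dir
    nxt >= 1L && nxt <= length(y) && y[i] < valley &&
      y[i] <= y[prv] && y[i] <= y[nxt]
  }
  l <- a
  while (l > 1L && !isStop(l - 1L, -1L)) l <- l - 1L
  r <- a
  while (r < length(y) && !isStop(r + 1L, 1L)) r <- r + 1L
  list(found = TRUE, left = p$rt[l], right = p$rt[r],
       apexTime = p$rt[a], apexIntensity = apex)
}

#' Integrate an XIC peak by the trapezoidal rule
#'
#' Integrates intensity versus retention time over `[left, right]` with the
#' trapezoidal rule on the raw XIC points (no smoothing). When `bounds` is a
#' no-peak result the returned peak has zero area and `found = FALSE`.
#'
#' @param xic an [Xic].
#' @param bounds result of [detectPeak()], or a list with `left` and `right`
#'   times in minutes.
#' @return an [IntegratedPeak].
#' @export
integratePeak <- function(xic, bounds = detectPeak(xic)) {
  if (isFALSE(bounds$found))
    return(new("IntegratedPeak", area = 0, apexTime = NA_real_,
               leftBound = NA_real_, rightBound = NA_real_, found = FALSE))
  if (bounds$left > bounds$right) stop("inverted integration bounds")
  p <- xicPoints(xic)
  inb <- p$rt >= bounds$left & p$rt <= bounds$right
  if (sum(inb) < 2L)
    return(new("IntegratedPeak", area = 0,
               apexTime = bounds$apexTime %||% NA_real_,
               leftBound = bounds$left, rightBound = bounds$right,
               found = TRUE))
  area <- pracma::trapz(p$rt[inb], p$intensity[inb])
  apex <- bounds$apexTime
  if (is.null(apex) || is.na(apex)) {
    w <- which(inb)[which.max(p$intensity[inb])]
    apex <- p$rt[w]
  }
  new("IntegratedPeak", area = max(area, 0), apexTime = apex,
      leftBound = bounds$left, rightBound = bounds$right, found = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
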