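makeRun <- function() {
  scans <- data.frame(scan = 1:3, rt = c(10.00, 10.02, 10.04),
                      precursorMz = c(1038.59, 1047.65, 1038.59))
  peaks <- data.frame(scan = c(1L, 1L, 2L, 3L),
                      mz = c(672.37, 729.41, 681.42, 672.87),
                      intensity = c(300, 200, 5, 150))
  targetedRun(scans, peaks, metadata = list(replicate = 1L))
}

test_that("run validity enforces scan ordering and peak sanity", {
  run <- makeRun()
  expect_s4_class(run, "TargetedRun")
  # the constructor normalizes scan order; coincident times are rejected
  reordered <- targetedRun(data.frame(scan = 1:2, rt = c(2, 1),
                                      precursorMz = 500))
  expect_equal(scanTable(reordered)$rt, c(1, 2))
  expect_error(targetedRun(data.frame(scan = 1:2, rt = c(1, 1),
                                      precursorMz = 500)),
               "strictly increasing")
  expect_error(targetedRun(data.frame(scan = 1L, rt = 1, precursorMz = 500),
                           data.frame(scan = 1L, mz = 100, intensity = -1)),
               ">= 0")
  expect_error(targetedRun(data.frame(scan = 1L, rt = 1, precursorMz = 500),
                           data.frame(scan = 2L, mz = 100, intensity = 1)),
               "listed scan")
  # empty run is valid
  empty <- targetedRun(data.frame(scan = integer(), rt = numeric(),
                                  precursorMz = numeric()))
  expect_equal(nrow(scanTable(empty)), 0L)
})

test_that("tabular run format round-trips bit-exactly", {
  run <- makeRun()
  # irrational-ish values exercise full-precision serialization
  run@peaks$intensity <- run@peaks$intensity * pi
  run@scans$rt <- run@scans$rt + exp(1) * 1e-6
  f <- tempfile(fileext = ".tsv")
  writeRun(run, f)
  back <- readRun(f)
  expect_identical(scanTable(back)$rt, scanTable(run)$rt)
  expect_identical(scanTable(back)$precursorMz, scanTable(run)$precursorMz)
  expect_identical(peakTable(back)$mz, peakTable(run)$mz)
  expect_identical(peakTable(back)$intensity, peakTable(run)$intensity)

  # a scan with no peaks survives the round trip
  scans <- data.frame(scan = 1:2, rt = c(1, 2), precursorMz = 500)
  peaks <- data.frame(scan = 2L, mz = 100.5, intensity = 10)
  f2 <- tempfile(fileext = ".tsv")
  writeRun(targetedRun(scans, peaks), f2)
  back2 <- readRun(f2)
  expect_equal(nrow(scanTable(back2)), 2L)
  expect_equal(nrow(peakTable(back2)), 1L)
})

test_that("mzML round trip preserves scans, peaks and precursor targets", {
  run <- makeRun()
  f <- tempfile(fileext = ".mzML")
  writeRun(run, f)
  back <- readRun(f)
  expect_equal(nrow(scanTable(back)), 3L)
  expect_equal(scanTable(back)$rt, scanTable(run)$rt, tolerance = 1e-6)
  expect_equal(scanTable(back)$precursorMz, scanTable(run)$precursorMz,
               tolerance = 1e-6)
  expect_equal(peakTable(back)$mz, peakTable(run)$mz, tolerance = 1e-5)
  expect_equal(peakTable(back)$intensity, peakTable(run)$intensity,
               tolerance = 1e-5)
})

test_that("XIC extraction sums in-window peaks with inclusive boundaries", {
  run <- makeRun()
  # fragment at 672.37 captured when querying 672.4 +/- 0.5 (and the
  # 672.87 peak in scan 3 sits inside the same window)
  xic <- extractProductXic(run, 1038.59, 672.4)
  expect_equal(xicPoints(xic)$intensity, c(300, 150))
  # query far away: all-zero XIC, one point per matching scan
  xic0 <- extractProductXic(run, 1038.59, 500.0)
  expect_equal(xicPoints(xic0)$intensity, c(0, 0))
  # peak exactly at the tolerance boundary is included
  scans <- data.frame(scan = 1L, rt = 1, precursorMz = 800)
  peaks <- data.frame(scan = 1L, mz = 600.5, intensity = 42)
  xicB <- extractProductXic(targetedRun(scans, peaks), 800, 600.0)
  expect_equal(xicPoints(xicB)$intensity, 42)
})

test_that("XIC scales linearly with intensity and grows with tolerance", {
  run <- makeRun()
  xic1 <- extractProductXic(run, 1038.59, 672.4)
  run2 <- makeRun()
  run2@peaks$intensity <- run2@peaks$intensity * 3
  xic3 <- extractProductXic(run2, 1038.59, 672.4)
  expect_equal(xicPoints(xic3)$intensity, 3 * xicPoints(xic1)$intensity)
  # widening the tolerance never decreases any point
  narrow <- extractProductXic(run, 1038.59, 672.4, tolerance = 0.1)
  wide <- extractProductXic(run, 1038.59, 672.4, tolerance = 2)
  expect_true(all(xicPoints(wide)$intensity >=
                    xicPoints(narrow)$intensity))
})

test_that("peak detection finds the apex and sensible bounds", {
  xic <- gaussianXic(center = 10, sigma = 0.2)
  pk <- detectPeak(xic)
  expect_true(pk$found)
  expect_equal(pk$apexTime, 10, tolerance = 0.011)
  expect_true(pk$left <= 10 - 2 * 0.2 && pk$right >= 10 + 2 * 0.2)

  # monotone ramp: bounds are the XIC extremes
  ramp <- xicFromPoints(1:10, seq(10, 100, by = 10))
  pkR <- detectPeak(ramp)
  expect_equal(c(pkR$left, pkR$right), c(1, 10))

  # all-zero: flagged no-peak, not an error
  flat <- xicFromPoints(1:5, rep(0, 5))
  expect_false(detectPeak(flat)$found)
  expect_equal(peakArea(integratePeak(flat)), 0)

  # a deep valley between two peaks terminates the bounds
  y <- c(1, 50, 100, 50, 1, 0.5, 1, 60, 120, 60, 1)
  two <- xicFromPoints(seq_along(y), y)
  pk2 <- detectPeak(two)
  expect_equal(pk2$apexTime, 9)
  expect_true(pk2$left >= 6)
})

test_that("trapezoidal integration matches the Gaussian closed form", {
  A <- 2e5; sigma <- 0.15
  xic <- gaussianXic(A = A, sigma = sigma, interval = 0.005, halfSigmas = 6)
  pk <- integratePeak(xic, list(found = TRUE, left = min(xicPoints(xic)$rt),
                                right = max(xicPoints(xic)$rt),
                                apexTime = 10))
  expect_equal(peakArea(pk), A * sigma * sqrt(2 * pi), tolerance = 0.01)
  # with detected bounds the area is still within 1%
  pk2 <- integratePeak(xic, detectPeak(xic))
  expect_equal(peakArea(pk2), A * sigma * sqrt(2 * pi), tolerance = 0.01)
})

test_that("integration is linear and rejects inverted bounds", {
  xic <- gaussianXic()
  a1 <- peakArea(integratePeak(xic))
  xic2 <- xic
  xic2@points$intensity <- xic2@points$intensity * 2
  expect_equal(peakArea(integratePeak(xic2)), 2 * a1)
  expect_error(integratePeak(xic, list(found = TRUE, left = 11, right = 9)),
               "inverted")
})

test_that("trapezoid matches a brute-force Riemann sum on random profiles", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    rt <- sort(runif(n, 0, 10))
    rt <- rt + seq_len(n) * 1e-6  # enforce strict increase
    y <- runif(n, 0, 100)
    xic <- xicFromPoints(rt, y)
    got <- peakArea(integratePeak(xic, list(found = TRUE, left = min(rt),
                                            right = max(rt),
                                            apexTime = rt[which.max(y)])))
    # fine midpoint Riemann sum on the piecewise-linear interpolant
    grid <- seq(min(rt), max(rt), length.out = 20001)
    mid <- (grid[-1] + grid[-length(grid)]) / 2
    ref <- sum(approx(rt, y, xout = mid)$y * diff(grid))
    expect_equal(got, ref, tolerance = 0.005)
  }
})
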