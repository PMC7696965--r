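# Savitzky-Golay, baseline correction, resampling, normalization, averaging

test_that("Savitzky-Golay is exact on polynomials up to its order", {
  w <- seq(600, 1900)
  cfg <- preprocess_config(sg_window = 11, sg_order = 3)
  # constant
  s <- raman_spectrum(w, rep(2.5, length(w)))
  expect_equal(savitzky_golay_smooth(s, cfg)$intensity, s$intensity,
               tolerance = 1e-12)
  # exact cubic (scaled to avoid huge magnitudes), interior points
  y <- (w / 1000)^3
  sm <- savitzky_golay_smooth(raman_spectrum(w, y), cfg)$intensity
  interior <- 6:(length(w) - 5)
  expect_equal(sm[interior], y[interior], tolerance = 1e-10)
})

test_that("SG output matches an explicit local least-squares oracle", {
  set.seed(1)
  w <- seq_len(200) + 499
  y <- rnorm(200)
  cfg <- preprocess_config(sg_window = 11, sg_order = 3)
  sm <- savitzky_golay_smooth(raman_spectrum(w, y), cfg)$intensity
  # oracle: at each interior point fit a cubic to the 11-point window with
  # lm() and evaluate at the center
  for (i in c(6, 50, 123, 195)) {
    win <- (i - 5):(i + 5)
    fit <- lm(y[win] ~ poly(win, 3, raw = TRUE))
    expect_equal(sm[i], unname(predict(fit)[6]), tolerance = 1e-8)
  }
})

test_that("SG noise attenuation equals the kernel's sum of squared weights", {
  set.seed(2)
  n <- 20000
  y <- rnorm(n)
  cfg <- preprocess_config(sg_window = 11, sg_order = 3)
  sm <- savitzky_golay_smooth(raman_spectrum(seq_len(n), y), cfg)$intensity
  # kernel via explicit least squares, independent of the implementation
  A <- outer(-5:5, 0:3, "^")
  k <- (solve(t(A) %*% A) %*% t(A))[1, ]
  expect_equal(var(sm), sum(k^2) * var(y), tolerance = 0.05)
})

test_that("SG rejects non-uniform grids and short spectra", {
  w <- c(seq(600, 1000), seq(1001.5, 1900, by = 1.5))
  expect_error(savitzky_golay_smooth(raman_spectrum(w, seq_along(w))),
               class = "oralfusion_nonuniform_grid")
  expect_error(savitzky_golay_smooth(raman_spectrum(1:8, rnorm(8))),
               class = "oralfusion_invalid_spec")
})

test_that("baseline correction recovers polynomial backgrounds", {
  w <- seq(600, 1900)
  cfg <- preprocess_config()
  # all-zero spectrum stays zero
  z <- baseline_correct(raman_spectrum(w, rep(0, length(w))), cfg)
  expect_equal(z$intensity, rep(0, length(w)), tolerance = 1e-10)
  # pure degree-2 polynomial is removed almost completely
  u <- (w - 1250) / 650
  y <- 4 + 2 * u - 3 * u^2
  corr <- baseline_correct(raman_spectrum(w, y), cfg)$intensity
  expect_lt(max(abs(corr)), 1e-6 * diff(range(y)))
  # order must be below the number of points
  expect_error(
    baseline_correct(raman_spectrum(700:704, rep(1, 5)),
                     preprocess_config(baseline_poly_order = 6)),
    class = "oralfusion_invalid_spec")
})

test_that("baseline correction preserves an injected peak apex within 5%", {
  w <- seq(600, 1900)
  u <- (w - 1250) / 650
  peak_height <- 1.7
  peak <- peak_height * exp(-(w - 1339)^2 / (2 * 3.4^2))
  y <- (5 - u + 0.6 * u^2) + peak
  corr <- baseline_correct(raman_spectrum(w, y))$intensity
  apex <- corr[match(1339, w)]
  expect_lt(abs(apex - peak_height) / peak_height, 0.05)
})

test_that("crop_and_resample lands on the canonical 1101-point grid", {
  cfg <- preprocess_config()
  # identity on the canonical grid
  w <- seq(700, 1800)
  s <- raman_spectrum(w, sin(w / 100))
  out <- crop_and_resample(s, cfg)
  expect_equal(out$wavenumber, as.numeric(w))
  expect_equal(out$intensity, s$intensity)
  # half-step grid resamples to 1101 points
  w2 <- seq(650, 1850, by = 0.5)
  out2 <- crop_and_resample(raman_spectrum(w2, rep(1, length(w2))), cfg)
  expect_length(out2$intensity, 1101)
  # linear ramp interpolates exactly
  w3 <- seq(600, 1900, by = 2.5)
  ramp <- crop_and_resample(raman_spectrum(w3, 3 * w3 - 7), cfg)
  expect_equal(ramp$intensity, 3 * ramp$wavenumber - 7, tolerance = 1e-9)
  # missing coverage is reported with the missing range
  expect_error(crop_and_resample(raman_spectrum(seq(900, 1900), rep(1, 1001)),
                                 cfg),
               "700.0-900.0", class = "oralfusion_coverage")
})

test_that("normalization modes satisfy their defining identities", {
  w <- seq(700, 1800)
  y <- 2 + sin(w / 50)
  s <- raman_spectrum(w, y)
  mm <- normalize_spectrum(s, mode = "minmax")$intensity
  expect_equal(range(mm), c(0, 1))
  un <- normalize_spectrum(raman_spectrum(1:2, c(3, 4)), mode = "unit_norm")
  expect_equal(un$intensity, c(0.6, 0.8))
  # unit-height rectangle of width w integrates to 1 after unit_area
  rect <- raman_spectrum(seq(0, 10), rep(1, 11))
  ua <- normalize_spectrum(rect, mode = "unit_area")$intensity
  expect_equal(ua, rep(1 / 10, 11))
  expect_error(normalize_spectrum(raman_spectrum(1:5, rep(1, 5)),
                                  mode = "minmax"),
               class = "oralfusion_degenerate_input")
})

test_that("replicate averaging is the pointwise mean with renormalization", {
  w <- seq(700, 1800)
  y <- exp(-(w - 1004)^2 / 50) + 0.1
  reps <- lapply(1:5, function(i) raman_spectrum(w, y, "P01", "tumor", i))
  avg <- average_replicates(reps)
  expect_equal(avg$intensity,
               normalize_spectrum(reps[[1]])$intensity, tolerance = 1e-12)
  # raw mean of a 0-vector-ish and a 2-vector is the 1-vector
  a <- raman_spectrum(1:4, c(0, 0, 0, 1e-9), "P01", "tumor", 1)
  b <- raman_spectrum(1:4, rep(2, 4), "P01", "tumor", 2)
  m <- average_replicates(list(a, b), renormalize = FALSE)
  expect_equal(m$intensity, c(1, 1, 1, 1 + 5e-10))
  # mixed samples are refused
  expect_error(average_replicates(list(
    raman_spectrum(1:4, 1:4, "P01", "tumor"),
    raman_spectrum(1:4, 1:4, "P02", "tumor"))),
    class = "oralfusion_mixed_replicates")
})

test_that("a 35-patient cohort preprocesses to exactly 70 averaged spectra", {
  co <- generate_cohort(cohort_spec(n_patients = 35, seed = 6))
  fm <- preprocess_cohort(co)
  expect_equal(dim(fm$values), c(70, 1101))
  expect_equal(as.vector(table(fm$labels)), c(35, 35))
  # every averaged spectrum is minmax-normalized
  expect_equal(unname(apply(fm$values, 1, min)), rep(0, 70))
  expect_equal(unname(apply(fm$values, 1, max)), rep(1, 70))
})

test_that("the preprocessing chain is near-idempotent on normalized spectra", {
  co <- tiny_cohort(n_patients = 1, seed = 9)
  cfg <- preprocess_config()
  s <- co$spectra[[1]]
  chain <- function(x) {
    x <- savitzky_golay_smooth(x, cfg)
    x <- baseline_correct(x, cfg)
    x <- crop_and_resample(x, cfg)
    normalize_spectrum(x, cfg)
  }
  once <- chain(s)
  twice <- chain(once)
  # smoothing/normalization are stable; only baseline re-estimation moves
  # the curve, and it is bounded by a few percent of the unit range
  expect_lt(max(abs(twice$intensity - once$intensity)), 0.05)
})
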