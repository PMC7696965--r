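# synthetic cohort generator: counts, determinism, signal model

test_that("cohort counts follow the paired design exactly", {
  co <- generate_cohort(cohort_spec(n_patients = 35, replicates_per_sample = 5,
                                    seed = 1))
  expect_length(co$spectra, 350)
  expect_length(co$images, 35)
  expect_equal(nrow(co$manifest), 350)
  samples <- unique(co$manifest[, c("patient_id", "tissue_class")])
  expect_equal(nrow(samples), 70)
  expect_equal(as.vector(table(samples$tissue_class)), c(35, 35))
  # every image carries exactly one tumor and one normal ROI
  for (img in co$images[1:3])
    expect_setequal(img$rois$class, c("normal", "tumor"))

  minimal <- generate_cohort(cohort_spec(1, 1, seed = 5))
  expect_length(minimal$spectra, 2)
  expect_length(minimal$images, 1)
})

test_that("identical specs give bit-identical cohorts, regardless of caller RNG", {
  spec <- cohort_spec(n_patients = 4, seed = 7)
  set.seed(101); a <- generate_cohort(spec)
  set.seed(999); b <- generate_cohort(spec)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # and the generator must not disturb the caller's stream invisibly:
  # a different seed gives a different cohort
  c2 <- generate_cohort(cohort_spec(n_patients = 4, seed = 8))
  expect_false(identical(a$spectra[[1]]$intensity, c2$spectra[[1]]$intensity))
})

test_that("patient child streams make cohorts stable under subsetting", {
  big <- generate_cohort(cohort_spec(n_patients = 5, seed = 3))
  small <- generate_cohort(cohort_spec(n_patients = 2, seed = 3))
  expect_identical(small$spectra[[1]]$intensity, big$spectra[[1]]$intensity)
  expect_identical(small$images[[2]]$pixels, big$images[[2]]$pixels)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_patients = 0), class = "oralfusion_invalid_spec")
  expect_error(cohort_spec(replicates_per_sample = -1),
               class = "oralfusion_invalid_spec")
  eff <- effect_params()
  eff$peak_centers[1] <- 100  # outside the acquisition grid
  expect_error(synth_raman_spectrum("tumor", eff),
               class = "oralfusion_invalid_spec")
})

test_that("null effect makes tumor and normal spectra identical", {
  eff <- quiet_effect()
  eff$tumor_amplitude_ratio[] <- 1
  s_n <- synth_raman_spectrum("normal", eff)
  s_t <- synth_raman_spectrum("tumor", eff)
  expect_equal(s_n$intensity, s_t$intensity)
})

test_that("tumor peak height follows the closed-form signal model", {
  # single band at 1004 cm^-1, ratio 2, no noise: the tumor intensity at the
  # apex equals baseline + 2 x the normal peak height
  eff <- quiet_effect()
  eff$peak_centers <- 1004
  eff$normal_amplitude <- 1.3
  eff$tumor_amplitude_ratio <- 2
  s_n <- synth_raman_spectrum("normal", eff)
  s_t <- synth_raman_spectrum("tumor", eff)
  i <- match(1004, s_n$wavenumber)
  u <- (1004 - 1250) / 650
  baseline_at_1004 <- sum(eff$baseline_poly_coeffs * u^(0:2))
  expect_equal(s_n$intensity[i], baseline_at_1004 + 1.3, tolerance = 1e-12)
  expect_equal(s_t$intensity[i], baseline_at_1004 + 2 * 1.3, tolerance = 1e-12)
})

test_that("mean tumor-minus-normal intensity at 1656 is positive under defaults", {
  eff <- effect_params()
  i <- match(1656, default_grid <- seq(600, 1900))
  set.seed(31)
  d <- replicate(300, {
    synth_raman_spectrum("tumor", eff)$intensity[i] -
      synth_raman_spectrum("normal", eff)$intensity[i]
  })
  # analytic expectation: (ratio - 1) x amplitude at 1656 (plus tiny
  # neighbouring-band overlap); Monte-Carlo mean within 4 SE
  expected <- (1.5 - 1) * 0.95
  expect_gt(mean(d), 0)
  expect_lt(abs(mean(d) - expected), 4 * sd(d) / sqrt(length(d)) + 0.01)
})

test_that("ROI intensity drop is exact pixel arithmetic when noise is off", {
  eff <- quiet_effect()
  eff$roi_intensity_drop <- 0.5
  img <- synth_velscope_image(eff, bg_sd = 0, roi_sd = 0)
  stats <- lapply(seq_len(2), function(i)
    roi_raw_stats(img, roi_mask(img, img$rois[i, ])))
  expect_equal(stats[[2]]$mean, 0.5 * stats[[1]]$mean, tolerance = 1e-12)
  expect_equal(stats[[1]]$sd, 0)
})

test_that("null ROI effect gives equal tumor/normal pixel statistics", {
  eff <- quiet_effect()
  eff$roi_intensity_drop <- 0
  eff$roi_heterogeneity_gain <- 1
  img <- synth_velscope_image(eff, bg_sd = 0, roi_sd = 0)
  s <- quantify_image(img)
  expect_equal(s$norm_intensity[1], s$norm_intensity[2], tolerance = 1e-12)
})

test_that("artifact injection strictly increases the whole-image mean", {
  eff <- quiet_effect()
  set.seed(11); plain <- synth_velscope_image(eff)
  set.seed(11); teeth <- synth_velscope_image(eff, artifacts = TRUE)
  expect_gt(mean(teeth$pixels[, , 2]), mean(plain$pixels[, , 2]))
})

test_that("ROI geometry is validated", {
  eff <- effect_params()
  expect_error(synth_velscope_image(eff, width = 60L, height = 60L,
                                    roi_radius = 20),
               class = "oralfusion_invalid_spec")
  expect_error(synth_velscope_image(eff, roi_radius = 1),
               class = "oralfusion_invalid_spec")
})

test_that("expected tumor ROI mean decreases as the intensity drop grows", {
  mean_tumor <- function(drop, seeds) {
    mean(sapply(seeds, function(s) {
      eff <- effect_params()
      eff$roi_intensity_drop <- drop
      co <- generate_cohort(cohort_spec(1, 1, seed = s, effect = eff),
                            modalities = "velscope")
      img <- co$images[[1]]
      roi_raw_stats(img, roi_mask(img, img$rois[2, ]))$mean
    }))
  }
  seeds <- 1:100
  m <- sapply(c(0.1, 0.35, 0.6), mean_tumor, seeds = seeds)
  expect_true(all(diff(m) < 0))
})
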