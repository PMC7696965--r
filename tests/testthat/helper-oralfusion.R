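# shared fixture builders -- everything is generated in code at test time

# tiny cohort used by most structural tests
tiny_cohort <- function(n_patients = 3, seed = 42, effect = effect_params(),
                        modalities = c("raman", "velscope")) {
  generate_cohort(cohort_spec(n_patients = n_patients, seed = seed,
                              effect = effect),
                  modalities = modalities)
}

# noiseless effect: deterministic spectra and images
quiet_effect <- function() {
  eff <- effect_params()
  eff$noise_sd <- 0
  eff$sample_factor_sd <- 0
  eff$peak_jitter_sd <- 0
  eff$roi_drop_sd <- 0
  eff$roi_gain_log_sd <- 0
  eff
}

# two-class Gaussian toy data with controllable separation
toy_gaussian <- function(n_per_class = 20, p = 2, sep = 3, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    X <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p),
               matrix(rnorm(n_per_class * p, mean = sep), n_per_class, p))
    list(X = X, labels = factor(rep(c("normal", "tumor"),
                                    each = n_per_class)))
  })
}
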