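# shared fixtures: small, fast synthetic scenes built in code

# deterministic forward-model-only scene: no noise, no scatter, no
# per-location nuisance -- spectra are exact functions of SOC
quiet_params <- function(...) {
  args <- list(n_locations = 12, rng_seed = 42L,
               scatter_slope_sd = 0, scatter_offset_sd = 0,
               sample_nuisance_sd = 0, field_extra_noise_sd = 0,
               field_tilt_sd = 0, field_location_tilt_sd = 0,
               field_structured_sd = 0,
               moisture_darkening = 0, soc_moisture_attenuation = 0,
               moisture_band_shift = 0, moisture_band_broadening = 0)
  do.call(scene_params, utils::modifyList(args, list(...)))
}

quiet_highres <- function(...) {
  device_profile("highres", 350, 2500, 1, noise_sd = 0,
                 n_lab_replicates = 1, n_field_replicates = 1, ...)
}

# small realistic scene for pipeline tests (noise on, fewer replicates)
small_scene <- function(n = 20, seed = 7L) {
  simulate_scene(scene_params(n_locations = n, rng_seed = seed),
                 devices = list(
                   highres = device_profile("highres", 350, 2500, 1,
                                            splice_points = c(1000, 1800),
                                            splice_offsets = c(0.02, -0.01),
                                            noise_sd = 0.002,
                                            n_lab_replicates = 6,
                                            n_field_replicates = 5),
                   lowres = device_profile("lowres", 350, 2200, 5,
                                           dead_bands = list(c(1000, 1100)),
                                           noise_sd = 0.004,
                                           segment_nuisance_sd = 0.004,
                                           n_lab_replicates = 6,
                                           n_field_replicates = 5)))
}

digest_folds <- function(folds) paste(as.vector(folds), collapse = ",")

# random spectrum_set on a plain grid
random_set <- function(n = 5, wl = seq(400, 700, by = 2), seed = 1) {
  set.seed(seed)
  spectrum_set(wl, matrix(runif(n * length(wl), 0.2, 0.8), n))
}
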