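# Shared configuration of the analysis workflow: one master seed drives
# the scene, the CV subdivisions and every tuning step, so each numbered
# script can regenerate upstream state deterministically.

library(socspec)

STUDY_SEED <- 1L
PARAMS <- scene_params(rng_seed = STUDY_SEED)
DEVICES <- list(highres = device_highres(), lowres = device_lowres())
SCHEME <- cv_scheme(seed = STUDY_SEED)
METHODS <- c("SG", "SGCR", "gapDer", "MSC")
A_MAX <- 20

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

study_scene <- function() simulate_scene(PARAMS, DEVICES)

study_datasets <- function(scene = study_scene()) {
  base <- assemble_datasets(scene)
  out <- list()
  for (bn in names(base)) for (me in METHODS)
    out[[paste(bn, me, sep = "_")]] <- preprocess_spectra(base[[bn]], me)
  out
}

samples_for <- function(set, scene) {
  scene$samples[match(set$meta$sample_id, scene$samples$sample_id), ]
}
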