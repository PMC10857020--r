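#!/usr/bin/env Rscript
# Simulate the two-device lab/field sampling campaign: 50 locations with
# SOC 14-25 g kg-1, 18 lab replicates per sample on both instruments,
# 15 site-specific field spectra on the 1 nm device, and a georeferenced
# on-the-go stream from the 5 nm device.  Writes the raw spectra and the
# sample table under results/data/.

source("analysis/config.R")

dir.create(file.path(RESULTS, "data"), recursive = TRUE, showWarnings = FALSE)
scene <- study_scene()

cat(sprintf("Simulated %d locations: SOC mean %.1f g/kg, range %.1f-%.1f\n",
            nrow(scene$samples), mean(scene$samples$soc),
            min(scene$samples$soc), max(scene$samples$soc)))
cat(sprintf("Moisture at acquisition: %.0f-%.0f%% volumetric\n",
            min(scene$truth$moisture), max(scene$truth$moisture)))

write.csv(scene$samples, file.path(RESULTS, "data", "samples.csv"),
          row.names = FALSE)
write_spectra(scene$lab_highres, file.path(RESULTS, "data", "lab_highres.csv"))
write_spectra(scene$lab_lowres, file.path(RESULTS, "data", "lab_lowres.csv"))
write_spectra(scene$field_highres,
              file.path(RESULTS, "data", "field_highres.csv"))
write_spectra(scene$stream_lowres,
              file.path(RESULTS, "data", "stream_lowres.csv"), "long")
jsonlite::write_json(scene$truth[c("soc", "moisture", "band_centers", "seed")],
                     file.path(RESULTS, "data", "truth.json"),
                     auto_unbox = TRUE, digits = NA)
cat("Raw spectra written to", file.path(RESULTS, "data"), "\n")
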