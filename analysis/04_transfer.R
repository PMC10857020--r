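#!/usr/bin/env Rscript
# Tune the three lab-to-field corrections (per-wavelength linear
# transformation, piecewise direct standardization with ncomp 1-10 x
# window 1-20, external parameter orthogonalization with 1-10
# components) on each of the 8 field variants, using the same nested CV
# subdivisions as the uncorrected models.  The full PDS grid makes this
# the long stage (roughly 10-15 minutes on one CPU).  Writes corrected
# metrics and the selected-parameter table under results/.

source("analysis/config.R")

scene <- study_scene()
datasets <- study_datasets(scene)

rows <- list(); prows <- list(); sel_rows <- list()
for (dev in c("highres", "lowres")) for (me in METHODS) {
  fvn <- paste(dev, "field", me, sep = "_")
  lvn <- paste(dev, "lab", me, sep = "_")
  for (tmth in c("LT", "PDS", "EPO")) {
    tt <- tune_transfer(datasets[[fvn]], datasets[[lvn]],
                        samples_for(datasets[[fvn]], scene),
                        method = tmth, scheme = SCHEME, A_max = A_MAX)
    s <- summarize_cv(tt$predictions)$summary
    key <- paste(fvn, tmth, sep = "_")
    rows[[key]] <- data.frame(
      variant = fvn, correction = tmth,
      rmse_median = s$median[s$metric == "rmse"],
      r2_median = s$median[s$metric == "r2"],
      rpd_median = s$median[s$metric == "rpd"])
    pm <- tt$params_mode; pm$device <- dev; pm$preprocess <- me
    prows[[key]] <- pm
    sel_rows[[key]] <- cbind(variant = fvn, tt$selection)
    cat(sprintf("%-22s %-3s RMSE %.2f  R2 %.2f\n", fvn, tmth,
                rows[[key]]$rmse_median, rows[[key]]$r2_median))
  }
}

write.csv(do.call(rbind, rows), file.path(RESULTS, "transfer_metrics.csv"),
          row.names = FALSE)
sel <- do.call(function(...) rbind(...), lapply(sel_rows, function(x) {
  x[setdiff(c("variant", "repetition", "fold", "method", "plsr_ncomp",
              "inner_rmse", "pds_w", "pds_ncomp", "epo_c"),
            names(x))] <- NA
  x[, c("variant", "repetition", "fold", "method", "plsr_ncomp",
        "inner_rmse", "pds_w", "pds_ncomp", "epo_c")]
}))
write.csv(sel, file.path(RESULTS, "transfer_selections.csv"),
          row.names = FALSE)
params_tab <- socspec:::merge_params_table(prows)
write.csv(params_tab, file.path(RESULTS, "transfer_parameters.csv"),
          row.names = FALSE)
cat("\nSelected transfer parameters (mode across the 25 models):\n")
print(params_tab)
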