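#' Assemble per-location averaged datasets from a simulated scene
#'
#' Applies the fixed data-preparation order to each device/condition
#' combination: splice correction (high-resolution device), trimming to the
#' common 400-2200 nm modelling range, robust replicate outlier removal,
#' and replicate averaging. For the on-the-go stream, outlier removal runs
#' on the whole stream before the 10 nearest spectra are selected around
#' each sampling point (maximum radius 3 m) and averaged.
#'
#' @param scene output of [simulate_scene()].
#' @param range modelling range in nm.
#' @param k_nearest stream spectra averaged per location.
#' @param max_radius_m stream selection radius in metres.
#' @return Named list of averaged [spectrum_set()]s: `highres_lab`,
#'   `highres_field`, `lowres_lab`, `lowres_field`.
#' @export
assemble_datasets <- function(scene, range = c(400, 2200), k_nearest = 10,
                              max_radius_m = 3) {
  splices <- c(1000, 1800)
  prep_point <- function(s, splice) {
    if (splice) s <- splice_correct(s, splices)
    s <- trim_range(s, range[1], range[2])
    s <- remove_outliers(s)$spectra
    average_replicates(s)
  }
  stream <- trim_range(scene$stream_lowres, range[1], range[2])
  stream_grouped <- stream
  stream_grouped$meta$sample_id <- "stream"
  stream_grouped$meta$replicate_id <- as.character(seq_len(nrow(stream$meta)))
  keep_ids <- remove_outliers(stream_grouped)$spectra$meta$replicate_id
  stream_clean <- subset_spectra(stream, as.integer(keep_ids))
  near <- suppressWarnings(
    select_nearest_stream(stream_clean, scene$samples, k = k_nearest,
                          max_radius_m = max_radius_m))
  list(highres_lab = prep_point(scene$lab_highres, splice = TRUE),
       highres_field = prep_point(scene$field_highres, splice = TRUE),
       lowres_lab = prep_point(scene$lab_lowres, splice = FALSE),
       lowres_field = average_replicates(near))
}

#' Run the full study replica on a synthetic scene
#'
#' Generates the scene, prepares the dataset variants (devices x
#' lab/field x preprocessing methods), evaluates each with spatially
#' grouped nested cross-validation, tunes the requested lab-to-field
#' corrections on every field variant, and computes wavelength-importance
#' profiles, peaks, and peak-match tables against the reference variant
#' (high-resolution lab MSC by default).
#'
#' @param params a [scene_params()].
#' @param devices list with `highres` and `lowres` [device_profile()]s.
#' @param scheme a [cv_scheme()].
#' @param methods preprocessing methods to include.
#' @param transfer_methods corrections to tune on field variants (empty
#'   vector skips correction).
#' @param A_max largest PLS component count in the tuning grid.
#' @param pds_ncomp,pds_w,epo_c transfer tuning grids.
#' @param reference_variant variant whose VIP peaks anchor the match
#'   tables.
#' @param verbose print stage progress.
#' @return A list with `scene`, `datasets`, `cv` (per variant: predictions
#'   + summary), `metrics_table`, `transfer` (per field variant x method),
#'   `transfer_metrics_table`, `params_table`, `profiles`, `peaks`,
#'   `match_tables`.
#' @export
run_study <- function(params = scene_params(),
                      devices = list(highres = device_highres(),
                                     lowres = device_lowres()),
                      scheme = cv_scheme(),
                      methods = c("SG", "SGCR", "gapDer", "MSC"),
                      transfer_methods = c("LT", "PDS", "EPO"),
                      A_max = 20, pds_ncomp = 1:10, pds_w = 1:20,
                      epo_c = 1:10,
                      reference_variant = "highres_lab_MSC",
                      verbose = TRUE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  say("simulating scene (", params$n_locations, " locations)")
  scene <- simulate_scene(params, devices)
  base <- assemble_datasets(scene)

  say("preprocessing ", 4 * length(methods), " dataset variants")
  datasets <- list()
  for (bn in names(base)) for (me in methods)
    datasets[[paste(bn, me, sep = "_")]] <- preprocess_spectra(base[[bn]], me)

  align_samples <- function(set) {
    j <- match(set$meta$sample_id, scene$samples$sample_id)
    scene$samples[j, ]
  }

  say("nested cross-validation on ", length(datasets), " variants")
  cv <- list()
  for (vn in names(datasets)) {
    set <- datasets[[vn]]
    cv[[vn]] <- nested_cv(set$reflectance, align_samples(set), scheme,
                          A_max = A_max, wavelengths = set$wavelengths)
    cv[[vn]]$summary <- summarize_cv(cv[[vn]]$predictions)
  }
  metrics_table <- do.call(rbind, lapply(names(cv), function(vn) {
    s <- cv[[vn]]$summary$summary
    data.frame(variant = vn,
               rmse_median = s$median[s$metric == "rmse"],
               r2_median = s$median[s$metric == "r2"],
               rpd_median = s$median[s$metric == "rpd"],
               ccc_median = s$median[s$metric == "ccc"],
               ncomp_median = median(cv[[vn]]$predictions$ncomp))
  }))

  transfer <- list(); trows <- list(); prows <- list()
  for (dev in c("highres", "lowres")) for (me in methods) {
    fvn <- paste(dev, "field", me, sep = "_")
    lvn <- paste(dev, "lab", me, sep = "_")
    if (!fvn %in% names(datasets)) next
    for (tm in transfer_methods) {
      say("tuning ", tm, " on ", fvn)
      tt <- tune_transfer(datasets[[fvn]], datasets[[lvn]],
                          align_samples(datasets[[fvn]]), method = tm,
                          scheme = scheme, A_max = A_max,
                          pds_ncomp = pds_ncomp, pds_w = pds_w,
                          epo_c = epo_c)
      tt$summary <- summarize_cv(tt$predictions)
      key <- paste(fvn, tm, sep = "_")
      transfer[[key]] <- tt
      s <- tt$summary$summary
      trows[[key]] <- data.frame(
        variant = fvn, correction = tm,
        rmse_median = s$median[s$metric == "rmse"],
        r2_median = s$median[s$metric == "r2"],
        rpd_median = s$median[s$metric == "rpd"])
      pm <- tt$params_mode
      pm$device <- dev; pm$preprocess <- me
      prows[[key]] <- pm
    }
  }
  transfer_metrics_table <- if (length(trows)) do.call(rbind, trows) else NULL
  params_table <- if (length(prows)) merge_params_table(prows) else NULL

  say("wavelength importance")
  profiles <- lapply(cv, function(x) median_profiles(x$models))
  peaks <- lapply(profiles, profile_peaks)
  match_tables <- NULL
  if (reference_variant %in% names(peaks)) {
    tol <- ifelse(grepl("^lowres", names(peaks)), 20, 10)
    names(tol) <- names(peaks)
    others <- setdiff(names(peaks), reference_variant)
    match_tables <- list(
      vip = match_peaks(peaks[[reference_variant]]$vip_peaks,
                        lapply(peaks[others], `[[`, "vip_peaks"),
                        tol[others]),
      rc = match_peaks(peaks[[reference_variant]]$rc_peaks,
                       lapply(peaks[others], `[[`, "rc_peaks"),
                       tol[others]))
  }

  list(scene = scene, datasets = datasets, cv = cv,
       metrics_table = metrics_table, transfer = transfer,
       transfer_metrics_table = transfer_metrics_table,
       params_table = params_table, profiles = profiles, peaks = peaks,
       match_tables = match_tables)
}

# shape the per-method transfer selections like a per-device parameter
# table (rows: preprocessing method; columns: PDS ncomp/w, EPO ncomp)
merge_params_table <- function(prows) {
  df <- do.call(rbind, lapply(prows, function(p) {
    data.frame(device = p$device, preprocess = p$preprocess,
               method = p$method,
               pds_ncomp = if ("pds_ncomp" %in% names(p)) p$pds_ncomp else NA,
               pds_w = if ("pds_w" %in% names(p)) p$pds_w else NA,
               epo_c = if ("epo_c" %in% names(p)) p$epo_c else NA)
  }))
  rownames(df) <- NULL
  out <- unique(df[, c("device", "preprocess")])
  out$pds_ncomp <- out$pds_w <- out$epo_c <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- df$device == out$device[i] & df$preprocess == out$preprocess[i]
    pd <- df[sel & df$method == "PDS", ]
    ep <- df[sel & df$method == "EPO", ]
    if (nrow(pd)) { out$pds_ncomp[i] <- pd$pds_ncomp; out$pds_w[i] <- pd$pds_w }
    if (nrow(ep)) out$epo_c[i] <- ep$epo_c
  }
  rownames(out) <- NULL
  out
}
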