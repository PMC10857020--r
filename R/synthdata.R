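#' Spectrometer device profile
#'
#' Describes the output grid and noise of one instrument. The high-resolution
#' profile emulates a 1 nm full-range point spectrometer whose three internal
#' sensors meet at 1000 and 1800 nm (producing additive reflectance steps);
#' the low-resolution profile emulates a two-segment 5 nm instrument whose
#' sensors leave a noisy dead band at 1000-1100 nm and which additionally
#' records an on-the-go stream in the field.
#'
#' @param name device label, `"highres"` or `"lowres"`.
#' @param wavelength_start,wavelength_end grid limits in nm.
#' @param resolution output grid step in nm.
#' @param dead_bands list of `c(lo, hi)` nm intervals reported as missing.
#' @param splice_points nm positions where additive inter-sensor offsets are
#'   injected.
#' @param splice_offsets additive reflectance step applied from each splice
#'   point onward (same length as `splice_points`).
#' @param noise_sd instrument noise standard deviation, reflectance units.
#' @param segment_nuisance_sd amplitude of per-sample inter-sensor
#'   calibration error: each sensor segment (delimited by dead bands) gets
#'   a random offset and in-segment tilt per sample, constant across that
#'   sample's replicates. Zero for a well-spliced single-train instrument;
#'   positive for a multi-sensor instrument whose segments respond
#'   slightly differently to each sample presentation.
#' @param n_lab_replicates,n_field_replicates replicate spectra per sample.
#' @return A list of class `device_profile`.
#' @export
device_profile <- function(name, wavelength_start, wavelength_end, resolution,
                           dead_bands = list(), splice_points = numeric(0),
                           splice_offsets = numeric(0), noise_sd = 0.002,
                           segment_nuisance_sd = 0,
                           n_lab_replicates = 18, n_field_replicates = 15) {
  if (wavelength_start >= wavelength_end) stop("wavelength_start must be < wavelength_end")
  if (resolution <= 0) stop("resolution must be > 0")
  rng <- c(wavelength_start, wavelength_end)
  for (db in dead_bands)
    if (db[1] < rng[1] || db[2] > rng[2] || db[1] > db[2])
      stop("dead band outside wavelength range")
  if (any(splice_points <= rng[1] | splice_points >= rng[2]))
    stop("splice points must be interior to the wavelength range")
  if (length(splice_offsets) != length(splice_points))
    stop("one splice offset per splice point required")
  structure(list(name = name, wavelength_start = wavelength_start,
                 wavelength_end = wavelength_end, resolution = resolution,
                 dead_bands = dead_bands, splice_points = splice_points,
                 splice_offsets = splice_offsets, noise_sd = noise_sd,
                 segment_nuisance_sd = segment_nuisance_sd,
                 n_lab_replicates = n_lab_replicates,
                 n_field_replicates = n_field_replicates),
            class = "device_profile")
}

#' @rdname device_profile
#' @export
device_highres <- function() {
  device_profile("highres", 350, 2500, 1,
                 splice_points = c(1000, 1800),
                 splice_offsets = c(0.02, -0.01),
                 noise_sd = 0.002, n_lab_replicates = 18,
                 n_field_replicates = 15)
}

#' @rdname device_profile
#' @export
device_lowres <- function() {
  device_profile("lowres", 350, 2200, 5,
                 dead_bands = list(c(1000, 1100)),
                 noise_sd = 0.004, segment_nuisance_sd = 0.004,
                 n_lab_replicates = 18, n_field_replicates = 15)
}

#' Synthetic scene parameters
#'
#' Defines the SOC distribution, the SOC-linked absorption bands, the scatter
#' and noise regime, and the field moisture disturbance of a simulated
#' sampling campaign: 50 locations with SOC averaging 19.6 g kg-1 over a
#' 14-25 g kg-1 range, and volumetric field moisture between 15 and 25%.
#' Band centers sit at wavelengths commonly reported as SOC-relevant
#' (560, 1330, 1412, 1720, 2008 nm); band widths are Gaussian standard
#' deviations in nm; band gains are reflectance depth per (g kg-1) of SOC.
#'
#' @param n_locations number of sampling locations.
#' @param soc_mean,soc_sd mean and standard deviation of SOC in g kg-1. The
#'   standard deviation is a package default (2.5) chosen to fill the stated
#'   range; it is a configuration value, not a reported one.
#' @param soc_range truncation interval in g kg-1.
#' @param band_centers,band_widths,band_gains SOC absorption bands.
#' @param moisture_range volumetric moisture interval in percent.
#' @param moisture_band_centers,moisture_band_widths,moisture_gain water
#'   absorption bands; depth = gain x relative strength x moisture(%).
#' @param moisture_band_rel relative strengths of the water bands; the
#'   1900 nm combination band is substantially stronger than the 1400 nm
#'   first overtone.
#' @param moisture_band_shift nm of water-band center displacement per
#'   percent moisture away from 20% (hydrogen-bonding state changes the
#'   band position as soils wet up).
#' @param moisture_band_broadening fractional water-band width increase per
#'   percent moisture away from 20%. Together with the shift this makes
#'   the moisture effect a curved manifold rather than a fixed direction,
#'   which is what distinguishes a subspace-removal correction from what a
#'   linear regression can absorb on its own.
#' @param moisture_darkening fractional albedo loss per percent moisture
#'   (wet soil is darker across the whole range).
#' @param soc_moisture_attenuation fractional reduction of the SOC band
#'   depth per percent moisture (water masks the organic absorption
#'   features, so the SOC signal itself is weaker in moist field spectra).
#' @param scatter_slope_sd,scatter_offset_sd per-replicate multiplicative and
#'   additive scatter.
#' @param sample_nuisance_sd amplitude (reflectance units) of the smooth
#'   per-location spectral nuisance: each location carries a random sum of
#'   broad Gaussian bumps emulating SOC-unrelated soil variation
#'   (mineralogy, texture, iron oxides). Unlike replicate scatter it does
#'   not average out, so it is what limits laboratory model accuracy.
#' @param sample_nuisance_bumps number of bumps per location.
#' @param field_extra_noise_sd extra instrument noise under field conditions.
#' @param field_tilt_sd per-spectrum random baseline tilt amplitude (field).
#' @param field_location_tilt_sd amplitude of the per-location structured
#'   field baseline distortion (offset, slope and curvature from surface
#'   roughness and illumination of that spot); unlike the per-spectrum
#'   tilt this does not average out over replicates, but it spans a
#'   low-dimensional subspace a lab-based correction can remove.
#' @param field_structured_sd,field_structured_dim amplitude and dimension
#'   of the band-like per-location field disturbance: each location draws
#'   random coefficients on `field_structured_dim` fixed broad Gaussian
#'   bumps spread over the spectral range (patchy moisture films, surface
#'   condition). It is constant across a location's replicates, so it
#'   degrades field models; because it spans a fixed subspace, a paired
#'   lab/field correction can identify and remove it.
#' @param stream_disturbance_mult multiplier on scatter, tilt and noise for
#'   the on-the-go stream, reflecting varying soil contact of a moving
#'   below-ground sensor relative to site-specific measurements.
#' @param field_size_m side lengths of the rectangular field in metres.
#' @param rng_seed master integer seed; all sub-streams derive from it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_locations = 50, soc_mean = 19.6, soc_sd = 2.5,
                         soc_range = c(14, 25),
                         band_centers = c(560, 1330, 1412, 1720, 2008),
                         band_widths = c(55, 28, 24, 35, 45),
                         band_gains = c(0.0012, 0.0009, 0.0011, 0.0008, 0.0010),
                         moisture_range = c(15, 25),
                         moisture_band_centers = c(1400, 1900),
                         moisture_band_widths = c(30, 45),
                         moisture_gain = 0.012,
                         moisture_band_rel = c(0.5, 1),
                         moisture_band_shift = 2.5,
                         moisture_band_broadening = 0.025,
                         moisture_darkening = 0.004,
                         soc_moisture_attenuation = 0.002,
                         scatter_slope_sd = 0.015,
                         scatter_offset_sd = 0.008,
                         sample_nuisance_sd = 0.004,
                         sample_nuisance_bumps = 6,
                         field_extra_noise_sd = 0.005,
                         field_tilt_sd = 0.01,
                         field_location_tilt_sd = 0.012,
                         field_structured_sd = 0.01,
                         field_structured_dim = 8,
                         stream_disturbance_mult = 2,
                         field_size_m = c(200, 130),
                         rng_seed = 1L) {
  if (n_locations < 2) stop("n_locations must be >= 2")
  if (soc_range[1] >= soc_range[2]) stop("degenerate soc_range")
  if (soc_range[1] <= 0) stop("soc_range must be positive")
  if (length(band_centers) != length(band_widths) ||
      length(band_centers) != length(band_gains))
    stop("band_centers, band_widths and band_gains must have equal length")
  if (any(band_widths <= 0)) stop("band widths must be positive")
  if (any(band_gains < 0)) stop("band gains must be non-negative")
  if (moisture_range[1] < 0 || moisture_range[2] > 100 ||
      moisture_range[1] > moisture_range[2])
    stop("moisture_range must lie within [0, 100]")
  structure(as.list(environment()), class = "scene_params")
}

# deterministic sub-seed derivation from the master seed: stream ids keep
# independent draws reproducible regardless of call order
subseed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Draw per-location SOC values
#'
#' Truncated-normal SOC: normal with `soc_mean`/`soc_sd` restricted to
#' `soc_range` (exact inverse-CDF truncation, so no value falls outside the
#' range). Deterministic given `params$rng_seed`.
#'
#' @param params a [scene_params()].
#' @return Numeric vector of SOC values in g kg-1, length `n_locations`.
#' @export
generate_soc <- function(params) {
  if (params$n_locations < 2) stop("n_locations must be >= 2")
  if (params$soc_range[1] >= params$soc_range[2]) stop("degenerate soc_range")
  set.seed(subseed(params$rng_seed, 1))
  if (params$soc_sd == 0) return(rep(params$soc_mean, params$n_locations))
  plo <- pnorm(params$soc_range[1], params$soc_mean, params$soc_sd)
  phi <- pnorm(params$soc_range[2], params$soc_mean, params$soc_sd)
  u <- runif(params$n_locations, plo, phi)
  qnorm(u, params$soc_mean, params$soc_sd)
}

#' @rdname generate_soc
#' @return For `generate_coordinates`: a two-column matrix of planar
#'   coordinates (m) uniform over the field rectangle.
#' @export
generate_coordinates <- function(params) {
  set.seed(subseed(params$rng_seed, 2))
  cbind(x_m = runif(params$n_locations, 0, params$field_size_m[1]),
        y_m = runif(params$n_locations, 0, params$field_size_m[2]))
}

#' Noiseless forward model
#'
#' Deterministic reflectance as a function of SOC: a smooth low-order
#' polynomial baseline decreasing toward the NIR minus one Gaussian
#' absorption per SOC band, depth `gain_k * SOC`. Moisture (if nonzero)
#' adds water absorptions at the moisture band centers, depth
#' `moisture_gain * moisture`.
#'
#' @param soc scalar SOC in g kg-1.
#' @param wavelengths nm grid.
#' @param params a [scene_params()].
#' @param moisture volumetric moisture in percent (default 0 = air-dry).
#' @return Numeric reflectance vector.
#' @export
noiseless_spectrum <- function(soc, wavelengths, params, moisture = 0) {
  u <- (wavelengths - 350) / 2150
  r <- 0.55 - 0.12 * u - 0.08 * u^2
  soc_depth <- soc * max(0, 1 - params$soc_moisture_attenuation * moisture)
  for (k in seq_along(params$band_centers)) {
    r <- r - params$band_gains[k] * soc_depth *
      exp(-(wavelengths - params$band_centers[k])^2 /
            (2 * params$band_widths[k]^2))
  }
  if (moisture > 0) {
    dm <- moisture - 20
    for (k in seq_along(params$moisture_band_centers)) {
      ctr <- params$moisture_band_centers[k] + params$moisture_band_shift * dm
      wid <- params$moisture_band_widths[k] *
        max(0.2, 1 + params$moisture_band_broadening * dm)
      r <- r - params$moisture_gain * params$moisture_band_rel[k] * moisture *
        exp(-(wavelengths - ctr)^2 / (2 * wid^2))
    }
    r <- r * max(0, 1 - params$moisture_darkening * moisture)
  }
  r
}

# per-location smooth nuisance spectra: bump parameters are drawn from a
# device-independent stream (the same soil looks the same to both
# instruments); evaluated on whatever grid the caller supplies
location_nuisance <- function(params, n_loc, wavelengths) {
  if (params$sample_nuisance_sd == 0 || params$sample_nuisance_bumps == 0)
    return(matrix(0, n_loc, length(wavelengths)))
  set.seed(subseed(params$rng_seed, 5))
  K <- params$sample_nuisance_bumps
  amp <- matrix(rnorm(n_loc * K, 0, params$sample_nuisance_sd), n_loc, K)
  ctr <- matrix(runif(n_loc * K, 350, 2500), n_loc, K)
  wid <- matrix(runif(n_loc * K, 40, 250), n_loc, K)
  out <- matrix(0, n_loc, length(wavelengths))
  for (k in seq_len(K))
    out <- out + amp[, k] *
      exp(-outer(ctr[, k], wavelengths, "-")^2 / (2 * wid[, k]^2))
  out
}

master_grid <- function(device) {
  seq(device$wavelength_start, device$wavelength_end, by = 1)
}

# fixed smooth basis of the structured field disturbance: broad Gaussian
# bumps evenly spaced over the spectral range, unit peak amplitude
field_disturbance_basis <- function(wl, dim, width = 60) {
  centers <- seq(450, 2150, length.out = dim)
  t(vapply(centers, function(ctr) exp(-(wl - ctr)^2 / (2 * width^2)),
           numeric(length(wl))))
}

# sensor segments of a device on the master grid (split at dead bands)
device_segment_id <- function(wl, device) {
  seg <- rep(1L, length(wl))
  for (db in device$dead_bands) seg <- seg + as.integer(wl > db[2])
  seg
}

# per-unit, per-sensor-segment offset + in-segment tilt (consumes the
# current RNG stream); units are locations for lab data, single scans for
# the on-the-go stream
segment_nuisance <- function(n_units, wl, device) {
  sd <- device$segment_nuisance_sd
  out <- matrix(0, n_units, length(wl))
  if (sd == 0) return(out)
  seg <- device_segment_id(wl, device)
  for (sg in unique(seg)) {
    cols <- which(seg == sg)
    u <- (wl[cols] - mean(range(wl[cols]))) / (diff(range(wl[cols])) / 2)
    off <- rnorm(n_units, 0, sd)
    tlt <- rnorm(n_units, 0, sd)
    out[, cols] <- out[, cols] + off + outer(tlt, u)
  }
  out
}

# block-mean resample from the 1 nm master grid to the device grid, then
# drop dead-band wavelengths
resample_to_device <- function(wl_master, refl, device) {
  grid <- seq(device$wavelength_start, device$wavelength_end,
              by = device$resolution)
  if (device$resolution == 1 && length(grid) == length(wl_master)) {
    out <- refl
  } else {
    half <- device$resolution / 2
    out <- matrix(NA_real_, nrow(refl), length(grid))
    for (j in seq_along(grid)) {
      idx <- which(wl_master >= grid[j] - half & wl_master < grid[j] + half)
      out[, j] <- rowMeans(refl[, idx, drop = FALSE])
    }
  }
  keep <- rep(TRUE, length(grid))
  for (db in device$dead_bands) keep <- keep & !(grid >= db[1] & grid <= db[2])
  list(wavelengths = grid[keep], reflectance = out[, keep, drop = FALSE])
}

apply_scatter_noise <- function(refl, wl, params, noise_sd,
                                n_rep_per_sample) {
  n <- nrow(refl)
  slope <- rnorm(n, 1, params$scatter_slope_sd)
  offset <- rnorm(n, 0, params$scatter_offset_sd)
  refl <- refl * slope + offset
  if (noise_sd > 0)
    refl <- refl + matrix(rnorm(n * ncol(refl), 0, noise_sd), n)
  refl
}

clip01 <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)

#' Generate laboratory replicate spectra
#'
#' Builds replicate lab spectra for each location on the device's output
#' grid: noiseless forward model, per-replicate multiplicative/additive
#' scatter, instrument noise, additive inter-sensor steps from each splice
#' point onward, block resampling to the device resolution, dead bands
#' dropped, reflectance clipped to (0, 1).
#'
#' @param soc per-location SOC vector (g kg-1).
#' @param device a [device_profile()].
#' @param params a [scene_params()].
#' @param coords optional two-column coordinate matrix (m) per location.
#' @param n_replicates replicate count (default the device's lab count).
#' @param stream_id integer offset separating this call's random stream.
#' @return A [spectrum_set()] with `n_replicates` spectra per location.
#' @export
generate_lab_spectra <- function(soc, device, params, coords = NULL,
                                 n_replicates = device$n_lab_replicates,
                                 stream_id = 10L) {
  if (any(params$band_widths <= 0) || any(params$band_gains < 0))
    stop("negative band widths/gains")
  wl <- master_grid(device)
  for (ctr in params$band_centers)
    if (ctr < wl[1] || ctr > wl[length(wl)])
      stop("device grid does not cover band center ", ctr)
  n_loc <- length(soc)
  base <- t(vapply(soc, noiseless_spectrum, numeric(length(wl)),
                   wavelengths = wl, params = params))
  base <- base + location_nuisance(params, n_loc, wl)
  set.seed(subseed(params$rng_seed, stream_id))
  base <- base + segment_nuisance(n_loc, wl, device)
  refl <- base[rep(seq_len(n_loc), each = n_replicates), , drop = FALSE]
  refl <- apply_scatter_noise(refl, wl, params, device$noise_sd, n_replicates)
  for (k in seq_along(device$splice_points))
    refl[, wl >= device$splice_points[k]] <-
      refl[, wl >= device$splice_points[k]] + device$splice_offsets[k]
  rs <- resample_to_device(wl, refl, device)
  meta <- data.frame(
    sample_id = rep(sprintf("S%02d", seq_len(n_loc)), each = n_replicates),
    replicate_id = as.character(rep(seq_len(n_replicates), n_loc)),
    device = device$name, condition = "lab", stringsAsFactors = FALSE)
  if (!is.null(coords)) {
    meta$x_m <- rep(coords[, 1], each = n_replicates)
    meta$y_m <- rep(coords[, 2], each = n_replicates)
  }
  spectrum_set(rs$wavelengths, clip01(rs$reflectance), meta)
}

#' Disturb laboratory spectra into field conditions
#'
#' Adds to each spectrum: moisture-proportional water absorption bands
#' (default centers 1400 and 1900 nm), a random per-spectrum baseline tilt,
#' and extra field noise. The field replicate count of the device is
#' honored by keeping the first `n_field_replicates` replicates per sample.
#' With zero moisture, zero tilt and zero extra noise the retained spectra
#' are returned unchanged.
#'
#' @param lab a [spectrum_set()] of lab spectra.
#' @param moisture per-location volumetric moisture (%), in sample order.
#' @param device the [device_profile()] that produced `lab`.
#' @param params a [scene_params()].
#' @param soc per-location SOC (g kg-1); needed for the moisture-SOC
#'   interaction terms of the forward model. Defaults to the scene mean.
#' @param stream_id integer offset separating this call's random stream.
#' @return A [spectrum_set()] of field spectra.
#' @export
apply_field_disturbance <- function(lab, moisture, device, params,
                                    soc = NULL, stream_id = 20L) {
  if (any(moisture < 0 | moisture > 100)) stop("moisture outside [0, 100]")
  set.seed(subseed(params$rng_seed, stream_id))
  ids <- unique(lab$meta$sample_id)
  if (length(moisture) != length(ids))
    stop("need one moisture value per sample")
  if (is.null(soc)) soc <- rep(params$soc_mean, length(ids))
  keep <- unlist(lapply(ids, function(s) {
    idx <- which(lab$meta$sample_id == s)
    idx[seq_len(min(device$n_field_replicates, length(idx)))]
  }))
  out <- subset_spectra(lab, keep)
  wl <- out$wavelengths
  # per-location moisture disturbance = forward model wet minus dry
  delta <- matrix(0, length(ids), length(wl))
  for (i in seq_along(ids))
    delta[i, ] <- noiseless_spectrum(soc[i], wl, params, moisture[i]) -
      noiseless_spectrum(soc[i], wl, params, 0)
  if (params$field_location_tilt_sd > 0) {
    u <- (wl - mean(range(wl))) / (diff(range(wl)) / 2)
    B <- rbind(1, u, 2 * u^2 - 1)
    cf <- matrix(rnorm(3 * length(ids), 0, params$field_location_tilt_sd), ncol = 3)
    delta <- delta + cf %*% B
  }
  if (params$field_structured_sd > 0) {
    Bs <- field_disturbance_basis(wl, params$field_structured_dim)
    cf <- matrix(rnorm(params$field_structured_dim * length(ids), 0,
                       params$field_structured_sd),
                 ncol = params$field_structured_dim)
    delta <- delta + cf %*% Bs
  }
  rownames(delta) <- ids
  refl <- out$reflectance + delta[out$meta$sample_id, , drop = FALSE]
  dimnames(refl) <- NULL
  n <- nrow(refl)
  if (params$field_tilt_sd > 0) {
    tilt <- rnorm(n, 0, params$field_tilt_sd)
    uu <- (wl - mean(range(wl))) / (diff(range(wl)) / 2)
    refl <- refl + outer(tilt, uu)
  }
  if (params$field_extra_noise_sd > 0)
    refl <- refl + matrix(rnorm(n * length(wl), 0, params$field_extra_noise_sd), n)
  disturbed <- params$field_tilt_sd > 0 || params$field_extra_noise_sd > 0 ||
    any(moisture > 0)
  out$reflectance <- if (disturbed) clip01(refl) else refl
  out$meta$condition <- "field"
  out
}

#' Generate an on-the-go field stream for the low-resolution device
#'
#' Emits georeferenced single-scan field spectra around every sampling
#' location: `n_per_location` spectra at planar positions jittered uniformly
#' within `radius_m` of the location, each built from that location's SOC and
#' moisture with field disturbance and single-scan noise.
#'
#' @param soc,moisture per-location values.
#' @param coords two-column coordinate matrix (m).
#' @param device a [device_profile()] (the low-resolution profile).
#' @param params a [scene_params()].
#' @param n_per_location stream spectra emitted near each location.
#' @param radius_m maximum planar jitter radius in metres.
#' @param stream_id integer offset separating this call's random stream.
#' @return A [spectrum_set()] whose metadata carries stream coordinates; the
#'   `sample_id` column is a running stream record id (location assignment is
#'   the job of [select_nearest_stream()]).
#' @export
generate_stream <- function(soc, moisture, coords, device, params,
                            n_per_location = 12, radius_m = 3,
                            stream_id = 30L) {
  wl_master <- master_grid(device)
  n_loc <- length(soc)
  nuis <- location_nuisance(params, n_loc, wl_master)
  mlt <- params$stream_disturbance_mult
  pm <- params
  pm$scatter_slope_sd <- params$scatter_slope_sd * mlt
  pm$scatter_offset_sd <- params$scatter_offset_sd * mlt
  set.seed(subseed(params$rng_seed, stream_id))
  n_tot <- n_loc * n_per_location
  base <- matrix(NA_real_, n_tot, length(wl_master))
  xs <- ys <- numeric(n_tot)
  loc_tilt <- matrix(0, n_loc, length(wl_master))
  if (params$field_location_tilt_sd > 0) {
    u <- (wl_master - mean(range(wl_master))) / (diff(range(wl_master)) / 2)
    B <- rbind(1, u, 2 * u^2 - 1)
    cf <- matrix(rnorm(3 * n_loc, 0, params$field_location_tilt_sd), ncol = 3)
    loc_tilt <- cf %*% B
  }
  if (params$field_structured_sd > 0) {
    Bs <- field_disturbance_basis(wl_master, params$field_structured_dim)
    cf <- matrix(rnorm(params$field_structured_dim * n_loc, 0,
                       params$field_structured_sd),
                 ncol = params$field_structured_dim)
    loc_tilt <- loc_tilt + cf %*% Bs
  }
  row <- 1
  for (i in seq_len(n_loc)) {
    sp <- noiseless_spectrum(soc[i], wl_master, params,
                             moisture = moisture[i]) + nuis[i, ] + loc_tilt[i, ]
    for (r in seq_len(n_per_location)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- radius_m * sqrt(runif(1))
      xs[row] <- coords[i, 1] + rad * cos(ang)
      ys[row] <- coords[i, 2] + rad * sin(ang)
      base[row, ] <- sp
      row <- row + 1
    }
  }
  base <- base + segment_nuisance(n_tot, wl_master, device)
  refl <- apply_scatter_noise(base, wl_master, pm,
                              (device$noise_sd + params$field_extra_noise_sd) * mlt, 1)
  if (params$field_tilt_sd > 0) {
    tilt <- rnorm(n_tot, 0, params$field_tilt_sd * mlt)
    uu <- (wl_master - mean(range(wl_master))) / (diff(range(wl_master)) / 2)
    refl <- refl + outer(tilt, uu)
  }
  rs <- resample_to_device(wl_master, refl, device)
  meta <- data.frame(sample_id = sprintf("R%05d", seq_len(n_tot)),
                     replicate_id = "1", device = device$name,
                     condition = "field", x_m = xs, y_m = ys,
                     stringsAsFactors = FALSE)
  spectrum_set(rs$wavelengths, clip01(rs$reflectance), meta)
}

#' Simulate a complete two-device lab/field scene
#'
#' One call builds everything the study replica needs: the sample table,
#' lab replicate spectra for both devices, point field spectra for the
#' high-resolution device, an on-the-go stream for the low-resolution
#' device, and the generating truth (SOC, moisture, coordinates, seed).
#'
#' @param params a [scene_params()].
#' @param devices list with elements `highres` and `lowres`
#'   ([device_profile()] objects).
#' @return A list with elements `samples` ([sample_table()]), `lab_highres`,
#'   `lab_lowres`, `field_highres` ([spectrum_set()]s), `stream_lowres`
#'   (georeferenced on-the-go [spectrum_set()]), and `truth`.
#' @export
simulate_scene <- function(params = scene_params(),
                           devices = list(highres = device_highres(),
                                          lowres = device_lowres())) {
  soc <- generate_soc(params)
  coords <- generate_coordinates(params)
  set.seed(subseed(params$rng_seed, 3))
  moisture <- runif(params$n_locations, params$moisture_range[1],
                    params$moisture_range[2])
  samples <- sample_table(sprintf("S%02d", seq_along(soc)), soc,
                          coords[, 1], coords[, 2])
  lab_hr <- generate_lab_spectra(soc, devices$highres, params, coords,
                                 stream_id = 10L)
  lab_lr <- generate_lab_spectra(soc, devices$lowres, params, coords,
                                 stream_id = 11L)
  field_hr <- apply_field_disturbance(lab_hr, moisture, devices$highres,
                                      params, soc = soc, stream_id = 20L)
  stream_lr <- generate_stream(soc, moisture, coords, devices$lowres, params,
                               stream_id = 30L)
  truth <- list(soc = soc, moisture = moisture, coords = coords,
                band_centers = params$band_centers, seed = params$rng_seed)
  list(samples = samples, lab_highres = lab_hr, lab_lowres = lab_lr,
       field_highres = field_hr, stream_lowres = stream_lr, truth = truth)
}
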