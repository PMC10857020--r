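test_that("SOC generator respects mean, truncation and determinism", {
  p <- scene_params(rng_seed = 11L)
  soc <- generate_soc(p)
  expect_length(soc, 50)
  expect_gt(mean(soc), 18)
  expect_lt(mean(soc), 21)
  expect_identical(soc, generate_soc(p))

  # degenerate spread collapses to the mean
  p0 <- scene_params(soc_sd = 0)
  expect_true(all(generate_soc(p0) == 19.6))

  # truncation is exact, not just probable: brute-force large sample
  pb <- scene_params(n_locations = 1e5, rng_seed = 3L)
  sb <- generate_soc(pb)
  expect_gte(min(sb), 14)
  expect_lte(max(sb), 25)

  expect_error(generate_soc(scene_params(soc_range = c(14, 14))),
               "degenerate")
})

test_that("noiseless lab spectra are exact deterministic functions of SOC", {
  p <- quiet_params()
  dev <- quiet_highres()
  soc <- c(15, 20, 20, 24)
  s <- generate_lab_spectra(soc, dev, p)
  expect_equal(nrow(s$reflectance), 4)
  # equal SOC -> identical spectra
  expect_equal(s$reflectance[2, ], s$reflectance[3, ])
  # regeneration is bit-identical
  s2 <- generate_lab_spectra(soc, dev, p)
  expect_identical(s$reflectance, s2$reflectance)
  # reflectance strictly inside (0, 1)
  expect_true(all(s$reflectance > 0 & s$reflectance < 1))
})

test_that("continuum-removed noiseless spectra dip at the true band centers", {
  p <- quiet_params()
  s <- generate_lab_spectra(20, quiet_highres(), p)
  cr <- continuum_removal(s)
  for (ctr in p$band_centers) {
    win <- which(abs(cr$wavelengths - ctr) <= 60)
    lmin <- cr$wavelengths[win][which.min(cr$reflectance[1, win])]
    expect_lte(abs(lmin - ctr), 5)
  }
})

test_that("raising a band gain strictly deepens that band's feature", {
  p1 <- quiet_params()
  p2 <- quiet_params()
  p2$band_gains[3] <- p2$band_gains[3] * 2
  s1 <- continuum_removal(generate_lab_spectra(20, quiet_highres(), p1))
  s2 <- continuum_removal(generate_lab_spectra(20, quiet_highres(), p2))
  at <- which.min(abs(s1$wavelengths - p1$band_centers[3]))
  expect_lt(s2$reflectance[1, at], s1$reflectance[1, at])
})

test_that("low-resolution output equals block-resampled high-resolution output", {
  p <- quiet_params()
  d1 <- quiet_highres()
  d5 <- device_profile("lowres", 350, 2500, 5, noise_sd = 0,
                       n_lab_replicates = 1)
  s1 <- generate_lab_spectra(20, d1, p)
  s5 <- generate_lab_spectra(20, d5, p)
  half <- 2.5
  manual <- vapply(s5$wavelengths, function(g) {
    mean(s1$reflectance[1, s1$wavelengths >= g - half & s1$wavelengths < g + half])
  }, 0)
  expect_equal(s5$reflectance[1, ], manual, tolerance = 1e-12)
})

test_that("zero disturbance leaves field spectra equal to lab spectra", {
  p <- quiet_params(moisture_range = c(0, 0))
  dev <- quiet_highres()
  lab <- generate_lab_spectra(c(16, 20, 23), dev, p)
  fld <- apply_field_disturbance(lab, rep(0, 3), dev, p)
  expect_equal(fld$reflectance, lab$reflectance)
  expect_true(all(fld$meta$condition == "field"))
  expect_error(apply_field_disturbance(lab, c(0, 150, 0), dev, p),
               "moisture")
})

test_that("lab-field difference peaks at the water bands", {
  p <- quiet_params()
  dev <- quiet_highres()
  soc <- c(16, 20, 23)
  lab <- generate_lab_spectra(soc, dev, p)
  fld <- apply_field_disturbance(lab, c(18, 20, 22), dev, p, soc = soc)
  d <- colMeans(abs(lab$reflectance - fld$reflectance))
  peak_wl <- lab$wavelengths[which.max(d)]
  expect_true(min(abs(peak_wl - c(1400, 1900))) <= 20)
})

test_that("noiseless lab-field difference has the rank of the disturbance", {
  # two disturbance modes: water absorption scaling and per-location tilt
  p <- quiet_params(field_tilt_sd = 0.01)
  dev <- quiet_highres()
  soc <- seq(15, 24, length.out = 8)
  lab <- generate_lab_spectra(soc, dev, p)
  fld <- apply_field_disturbance(lab, runif(8, 15, 25), dev, p, soc = soc)
  D <- lab$reflectance - fld$reflectance
  D <- sweep(D, 2, colMeans(D))
  sv <- svd(D)$d
  expect_lte(sum(sv > 1e-8 * sv[1]), 3)  # modes + 1
})

test_that("the on-the-go stream surrounds each location within the jitter radius", {
  p <- quiet_params()
  coords <- cbind(seq(0, 110, by = 10), rep(0, 12))
  soc <- rep(20, 12)
  st <- generate_stream(soc, rep(20, 12), coords, device_lowres(), p,
                        n_per_location = 11, radius_m = 3)
  expect_equal(nrow(st$reflectance), 12 * 11)
  d <- sqrt((st$meta$x_m - rep(coords[, 1], each = 11))^2 +
              (st$meta$y_m - rep(coords[, 2], each = 11))^2)
  expect_true(all(d <= 3 + 1e-9))
})

test_that("generator rejects invalid scenes", {
  expect_error(scene_params(n_locations = 1), "n_locations")
  expect_error(scene_params(band_widths = c(1, 2)), "equal length")
  expect_error(scene_params(moisture_range = c(-5, 20)), "moisture_range")
  expect_error(generate_lab_spectra(20, quiet_highres(),
                                    quiet_params(band_centers = 3000,
                                                 band_widths = 10,
                                                 band_gains = 1e-3)),
               "band center")
})
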