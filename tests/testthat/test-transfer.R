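make_pair <- function(n = 15, p = 40, seed = 1, transform = NULL,
                      smooth = FALSE) {
  set.seed(seed)
  wl <- seq(500, 500 + 2 * (p - 1), by = 2)
  lab <- if (smooth) {
    # rank-1 smooth spectra: every window is perfectly collinear
    outer(runif(n, 0.8, 1.2), 0.5 - 0.1 * exp(-(wl - 550)^2 / (2 * 30^2)))
  } else matrix(runif(n * p, 0.3, 0.7), n)
  field <- if (is.null(transform)) lab else transform(lab)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n))
  list(lab = spectrum_set(wl, lab, meta),
       field = spectrum_set(wl, field, meta))
}

test_that("linear transformation inverts exact per-wavelength affine maps", {
  pr <- make_pair()
  m <- fit_lt(pr$field, pr$lab)
  expect_equal(m$slope, rep(1, 40), tolerance = 1e-10)
  expect_equal(m$intercept, rep(0, 40), tolerance = 1e-10)

  pr2 <- make_pair(transform = function(lab) 2 * lab + 0.1)
  m2 <- fit_lt(pr2$field, pr2$lab)
  corrected <- apply_transfer(m2, pr2$field)
  expect_equal(corrected$reflectance, pr2$lab$reflectance, tolerance = 1e-10)

  # closed-form two-variable OLS oracle per wavelength
  pr3 <- make_pair(seed = 3, transform = function(lab)
    lab * 1.2 + matrix(rnorm(length(lab), 0, 0.01), nrow(lab)))
  m3 <- fit_lt(pr3$field, pr3$lab)
  for (j in c(1, 17, 40)) {
    fit <- lm(pr3$lab$reflectance[, j] ~ pr3$field$reflectance[, j])
    expect_equal(m3$intercept[j], unname(coef(fit)[1]), tolerance = 1e-8)
    expect_equal(m3$slope[j], unname(coef(fit)[2]), tolerance = 1e-8)
  }
})

test_that("PDS learns the identity and keeps an exactly banded transform", {
  pr <- make_pair(seed = 5, smooth = TRUE)
  m <- fit_pds(pr$field, pr$lab, w = 1, ncomp = 1)
  corrected <- apply_transfer(m, pr$field)
  expect_lt(max(abs(corrected$reflectance - pr$lab$reflectance)), 1e-8)

  # entries outside |i - j| <= w are structurally zero (band storage)
  expect_equal(dim(m$band), c(40L, 3L))

  # w = 0 reduces to a univariate map equal to per-wavelength LT slopes
  pr2 <- make_pair(seed = 6, transform = function(lab)
    sweep(lab, 2, runif(ncol(lab), 0.8, 1.2), "*"))
  m0 <- fit_pds(pr2$field, pr2$lab, w = 0, ncomp = 1)
  lt <- fit_lt(pr2$field, pr2$lab)
  expect_equal(drop(m0$band), lt$slope, tolerance = 1e-8)
  expect_equal(m0$intercept, lt$intercept, tolerance = 1e-8)
})

test_that("EPO removes an exact low-rank disturbance", {
  set.seed(8)
  pr <- make_pair(seed = 8)
  # field = lab -> zero difference, the projection is the identity
  expect_warning(m <- fit_epo(pr$field, pr$lab, c = 1), "rank")
  P <- epo_projection(m)
  expect_equal(P, diag(40))
  expect_equal(apply_transfer(m, pr$field)$reflectance,
               pr$field$reflectance %*% P, tolerance = 1e-12)

  # rank-2 disturbance, c = 2: corrected field equals projected lab
  v1 <- rnorm(40); v2 <- rnorm(40)
  dist2 <- function(lab) lab + outer(rnorm(nrow(lab)), v1) +
    outer(rnorm(nrow(lab)), v2)
  pr2 <- make_pair(seed = 9, transform = dist2)
  m2 <- fit_epo(pr2$field, pr2$lab, c = 2)
  P2 <- epo_projection(m2)
  expect_lt(max(abs(apply_transfer(m2, pr2$field)$reflectance -
                      pr2$lab$reflectance %*% P2)), 1e-8)

  # projection is symmetric, idempotent, rank p - c, annihilates V
  expect_equal(P2, t(P2), tolerance = 1e-10)
  expect_equal(P2 %*% P2, P2, tolerance = 1e-8)
  expect_equal(sum(diag(P2)), 40 - 2, tolerance = 1e-8)
  expect_lt(max(abs(P2 %*% m2$V)), 1e-10)

  expect_warning(fit_epo(pr2$field, pr2$lab, c = 30), "rank")
})

test_that("transfer tuning selects the true disturbance dimension", {
  # rank-2 disturbance (water scaling + per-location tilt) over minimal
  # instrument noise: the inner CV should concentrate on c = 2-3
  p <- quiet_params(n_locations = 30, rng_seed = 12L, field_tilt_sd = 0.01)
  dev <- device_profile("highres", 350, 2500, 1, noise_sd = 1e-3,
                        n_lab_replicates = 1, n_field_replicates = 1)
  soc <- generate_soc(p)
  lab <- generate_lab_spectra(soc, dev, p)
  set.seed(31)
  fld <- apply_field_disturbance(lab, runif(30, 15, 25), dev, p, soc = soc)
  samples <- sample_table(lab$meta$sample_id, soc,
                          runif(30, 0, 300), runif(30, 0, 300))
  tt <- tune_transfer(fld, lab, samples, "EPO",
                      cv_scheme(repetitions = 2, seed = 5L), A_max = 10)
  expect_gte(mean(tt$selection$epo_c %in% 2:3), 0.8)
  expect_true(all(c("epo_c", "plsr_ncomp") %in% names(tt$selection)))
  expect_equal(nrow(tt$selection), 10)
})

test_that("zero-disturbance pairs leave performance essentially unchanged", {
  sc <- small_scene(n = 20)
  ds <- assemble_datasets(sc)
  pp <- preprocess_spectra(ds$highres_lab, "MSC")
  j <- match(pp$meta$sample_id, sc$samples$sample_id)
  scheme <- cv_scheme(repetitions = 2, seed = 9L)
  base <- nested_cv(pp$reflectance, sc$samples[j, ], scheme, A_max = 10)
  tt <- tune_transfer(pp, pp, sc$samples[j, ], "LT", scheme, A_max = 10)
  r0 <- summarize_cv(base$predictions)$summary$median[1]
  r1 <- summarize_cv(tt$predictions)$summary$median[1]
  expect_lt(abs(r1 - r0) / r0, 0.2)
})
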