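test_that("splice correction removes additive inter-sensor steps", {
  wl <- 400:1200
  flat <- ifelse(wl < 1000, 0.5, 0.6)
  s <- spectrum_set(wl, matrix(flat, 1))
  out <- splice_correct(s, 1000)
  expect_equal(out$reflectance[1, ], rep(0.5, length(wl)), tolerance = 1e-12)

  # zero step -> identity
  s2 <- spectrum_set(wl, matrix(0.4 + 1e-5 * (wl - 400), 1))
  expect_equal(splice_correct(s2, 1000)$reflectance, s2$reflectance,
               tolerance = 1e-12)

  expect_error(splice_correct(s, 2000), "outside")
})

test_that("splice correction recovers offset-free noiseless generation", {
  p <- quiet_params()
  d_off <- device_profile("highres", 350, 2500, 1,
                          splice_points = c(1000, 1800),
                          splice_offsets = c(0.02, -0.01),
                          noise_sd = 0, n_lab_replicates = 1)
  d_clean <- quiet_highres()
  soc <- c(16, 21)
  withoff <- splice_correct(generate_lab_spectra(soc, d_off, p),
                            c(1000, 1800))
  clean <- generate_lab_spectra(soc, d_clean, p)
  expect_lt(max(abs(withoff$reflectance - clean$reflectance)), 1e-5)
})

test_that("range trimming drops edges and dead-band grids stay excluded", {
  p <- quiet_params()
  s <- generate_lab_spectra(20, quiet_highres(), p)
  tr <- trim_range(s, 400, 2200)
  expect_gte(min(tr$wavelengths), 400)
  expect_lte(max(tr$wavelengths), 2200)
  expect_equal(trim_range(s, 350, 2500)$wavelengths, s$wavelengths)
  expect_error(trim_range(s, 3000, 4000), "no wavelengths")

  lr <- generate_lab_spectra(20, device_profile("lowres", 350, 2200, 5,
                                                dead_bands = list(c(1000, 1100)),
                                                noise_sd = 0,
                                                n_lab_replicates = 1),
                             p)
  tlr <- trim_range(lr, 400, 2200)
  expect_false(any(tlr$wavelengths > 1000 & tlr$wavelengths < 1100))
})

test_that("outlier removal flags a grossly shifted replicate and spares clean groups", {
  set.seed(9)
  wl <- seq(400, 1000, by = 5)
  noise_sd <- 0.002
  base <- 0.5 - 0.1 * seq_along(wl) / length(wl)
  X <- matrix(rep(base, 18), 18, byrow = TRUE) +
    matrix(rnorm(18 * length(wl), 0, noise_sd), 18)
  X[5, ] <- X[5, ] + 10 * noise_sd  # one replicate shifted by 10x noise sd
  s <- spectrum_set(wl, X, data.frame(sample_id = "a",
                                      replicate_id = as.character(1:18)))
  out <- remove_outliers(s)
  expect_equal(out$report$n_removed, 1L)
  expect_false("5" %in% out$spectra$meta$replicate_id)

  # identical replicates: nothing removed
  si <- spectrum_set(wl, matrix(rep(base, 6), 6, byrow = TRUE),
                     data.frame(sample_id = "a",
                                replicate_id = as.character(1:6)))
  expect_equal(remove_outliers(si)$report$n_removed, 0L)

  # tiny groups pass through and are reported as skipped
  s3 <- spectrum_set(wl, X[1:2, ], data.frame(sample_id = "a",
                                              replicate_id = c("1", "2")))
  rep3 <- remove_outliers(s3)$report
  expect_true(rep3$skipped)
})

test_that("outlier decisions agree with a plain-loop reimplementation", {
  # independent oracle: same distance/threshold definitions written
  # directly, no shared code path
  oracle_flags <- function(X) {
    pc <- prcomp(X, center = TRUE)
    ev <- pc$sdev^2
    k <- max(1L, min(which(cumsum(ev) / sum(ev) >= 0.99)[1], nrow(X) - 2L))
    sc <- pc$x[, 1:k, drop = FALSE]
    ctr <- apply(sc, 2, median)
    scl <- pmax(apply(sc, 2, mad), 1e-6 * max(apply(sc, 2, mad), 1e-12))
    d2 <- colSums(((t(sc) - ctr) / scl)^2)
    use_full <- nrow(X) >= 2 * k + 2
    for (it in 1:3) {
      w <- as.numeric(d2 <= qchisq(0.975, k))
      if (sum(w) < 2) w <- as.numeric(rank(d2, ties.method = "first") <= 2)
      ctr <- colSums(sc * w) / sum(w)
      xc <- sweep(sc, 2, ctr)
      if (use_full) {
        cv <- crossprod(xc * w, xc) / max(sum(w) - 1, 1)
        ee <- eigen(cv, symmetric = TRUE)
        if (min(ee$values) < 1e-10 * max(ee$values, 1e-300)) {
          cv <- diag(pmax(diag(cv), 1e-12), k)
          ee <- eigen(cv, symmetric = TRUE)
        }
        inv <- ee$vectors %*% diag(1 / ee$values, k) %*% t(ee$vectors)
        d2 <- rowSums((xc %*% inv) * xc)
      } else {
        scl <- sqrt(colSums(xc^2 * w) / max(sum(w) - 1, 1))
        scl[scl < 1e-12] <- max(1e-12, 1e-6 * max(scl))
        d2 <- colSums((t(xc) / scl)^2)
      }
    }
    n <- length(d2)
    delta <- qchisq(0.975, k)
    ds <- sort(d2)
    gap <- pchisq(ds, k) - (seq_len(n) - 1) / n
    gap[ds < delta] <- -Inf
    an <- max(0, max(gap))
    acrit <- (0.24 - 0.003 * min(k, 10)) / sqrt(n)
    if (an <= acrit) return(rep(FALSE, n))
    thr <- ds[min(n, ceiling(n * (1 - an)))]
    fl <- d2 > max(delta, thr)
    if (all(fl)) fl[] <- FALSE
    fl
  }
  set.seed(31)
  wl <- seq(400, 600, by = 10)
  for (g in 1:20) {
    n <- sample(6:12, 1)
    X <- matrix(runif(1, 0.3, 0.6), n, length(wl)) +
      matrix(rnorm(n * length(wl), 0, 0.003), n)
    if (runif(1) < 0.5) X[1, ] <- X[1, ] + 0.05
    s <- spectrum_set(wl, X, data.frame(sample_id = "g",
                                        replicate_id = as.character(1:n)))
    got <- !(as.character(1:n) %in% remove_outliers(s)$spectra$meta$replicate_id)
    expect_equal(got, unname(oracle_flags(X)), info = paste("group", g))
  }
})

test_that("Savitzky-Golay derivative is exact on low-order polynomials", {
  wl <- seq(400, 2200, by = 1)
  cubic <- (wl / 1000)^3
  s <- spectrum_set(wl, matrix(cubic, 1))
  d <- savitzky_golay(s, window = 11, poly_order = 3, derivative_order = 1)
  expect_equal(d$reflectance[1, ], 3 * (d$wavelengths / 1000)^2 / 1000,
               tolerance = 1e-10)
  expect_equal(range(d$wavelengths), c(405, 2195))

  # constant spectrum -> zero derivative
  s0 <- spectrum_set(wl, matrix(0.5, 1, length(wl)))
  expect_lt(max(abs(savitzky_golay(s0)$reflectance)), 1e-12)

  # additive offsets vanish under the derivative
  s1 <- spectrum_set(wl, matrix(cubic + 0.123, 1))
  expect_equal(savitzky_golay(s1, 11, 3, 1)$reflectance,
               d$reflectance, tolerance = 1e-12)

  expect_error(savitzky_golay(s, window = 10), "odd")
  expect_error(savitzky_golay(spectrum_set(400:405, matrix(1:6 / 10, 1))),
               "shorter")
})

test_that("continuum removal divides by the upper convex hull", {
  wl <- seq(400, 600, by = 1)
  # linear spectrum is its own hull
  lin <- spectrum_set(wl, matrix(0.3 + 0.001 * (wl - 400), 1))
  expect_equal(continuum_removal(lin)$reflectance[1, ],
               rep(1, length(wl)), tolerance = 1e-12)

  # single Gaussian dip of depth 0.1 on a flat 0.5 baseline
  dip <- 0.5 - 0.1 * exp(-(wl - 500)^2 / (2 * 15^2))
  out <- continuum_removal(spectrum_set(wl, matrix(dip, 1)))
  expect_equal(min(out$reflectance), 0.4 / 0.5, tolerance = 1e-6)
  expect_equal(wl[which.min(out$reflectance)], 500)
  expect_true(all(out$reflectance > 0 & out$reflectance <= 1 + 1e-12))
  expect_equal(out$reflectance[1, c(1, length(wl))], c(1, 1))

  expect_error(continuum_removal(spectrum_set(wl, matrix(-1, 1, length(wl)))),
               "positive")
})

test_that("fast hull matches a brute-force O(n^2) oracle", {
  # oracle: a point is on the upper hull iff no chord between any other
  # two points passes strictly above it at its wavelength
  brute_hull <- function(x, y) {
    n <- length(x)
    on_hull <- vapply(seq_len(n), function(i) {
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        if (x[a] < x[i] && x[i] < x[b]) {
          yc <- y[a] + (y[b] - y[a]) * (x[i] - x[a]) / (x[b] - x[a])
          if (yc > y[i] + 1e-12) return(FALSE)
        }
      }
      TRUE
    }, TRUE)
    which(on_hull)
  }
  set.seed(4)
  for (rep in 1:100) {
    wl <- seq(0, 50, by = 1)
    y <- runif(length(wl), 0.2, 0.8)
    fast <- socspec:::upper_hull_idx(wl, y)
    expect_equal(fast, brute_hull(wl, y), info = paste("profile", rep))
  }
})

test_that("gap-segment derivative is exact on affine spectra", {
  wl <- seq(400, 2200, by = 1)
  m <- 2.5e-4
  s <- spectrum_set(wl, matrix(m * wl + 0.05, 1))
  d <- gap_segment_derivative(s, w = 11, s_seg = 10)
  expect_equal(d$reflectance[1, ], rep(m, ncol(d$reflectance)),
               tolerance = 1e-12)
  expect_equal(range(d$wavelengths), c(415, 2185))

  s0 <- spectrum_set(wl, matrix(0.4, 1, length(wl)))
  expect_true(all(gap_segment_derivative(s0)$reflectance == 0))
  expect_error(gap_segment_derivative(spectrum_set(400:420,
                                                   matrix(0.5, 1, 21))),
               "too short")
})

test_that("MSC normalizes scatter against the stored reference", {
  set.seed(2)
  wl <- seq(400, 700, by = 3)
  ref <- 0.5 - 0.1 * exp(-(wl - 550)^2 / (2 * 40^2))
  X <- rbind(ref, 0.1 + 2 * ref, 1.3 * ref - 0.05)
  s <- spectrum_set(wl, X)
  out <- msc(s, reference = ref)
  for (i in 1:3)
    expect_equal(out$reflectance[i, ], ref, tolerance = 1e-10)

  # additive offsets are removed exactly
  s2 <- spectrum_set(wl, X + 0.07)
  expect_equal(msc(s2, reference = ref)$reflectance,
               out$reflectance, tolerance = 1e-10)

  # idempotence under the same stored reference
  r1 <- msc(random_set(4, wl, seed = 8))
  stored <- attr(r1, "msc_reference")
  r2 <- msc(r1, reference = stored)
  expect_equal(r2$reflectance, r1$reflectance, tolerance = 1e-10)

  flat <- spectrum_set(wl, rbind(ref, rep(0.4, length(wl))))
  expect_error(msc(flat, reference = ref), "degenerate")
})

test_that("derivative operators never bridge the dead band", {
  p <- quiet_params()
  lr <- generate_lab_spectra(20, device_profile("lowres", 350, 2200, 5,
                                                dead_bands = list(c(1000, 1100)),
                                                noise_sd = 0,
                                                n_lab_replicates = 1), p)
  d <- savitzky_golay(lr, 11, 2, 1)
  # edges dropped on both sides of the gap, not just at the grid ends
  expect_false(any(d$wavelengths > 980 & d$wavelengths < 1130))
  g <- gap_segment_derivative(lr, 11, 10)
  expect_false(any(g$wavelengths > 920 & g$wavelengths < 1180))
})
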